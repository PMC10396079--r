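#' Validate a pipeline run configuration
#'
#' A run configuration is a plain list (or a YAML file of one) with fields:
#' `seed` (mandatory), `out_dir` (mandatory), `bases` (subset of
#' leaf/stem/shoot/lai, non-empty), `filter_threshold` (t/ha, default 1.0),
#' `mcmc` (list: `n_chains`, `n_burn`, `n_keep`), and either `simulate`
#' (list: `n_experiments`, `sigma_frac`, optional `master_seed`) or
#' `experiments` (list of lists with `obs`, `meta` and optional `weather`
#' file paths, all of which must exist at validation time).
#'
#' @param config list or path to a YAML file.
#' @return the normalized config list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::yaml.load_file(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  if (is.null(config$out_dir)) stop("config$out_dir is mandatory", call. = FALSE)
  config$bases <- config$bases %||% BASES
  if (length(config$bases) == 0)
    stop("config$bases must select at least one basis", call. = FALSE)
  if (!all(config$bases %in% BASES))
    stop("unknown basis in config$bases", call. = FALSE)
  config$filter_threshold <- config$filter_threshold %||% 1.0
  mc <- config$mcmc %||% list()
  config$mcmc <- list(n_chains = mc$n_chains %||% 4,
                      n_burn = mc$n_burn %||% 5000,
                      n_keep = mc$n_keep %||% 3000)
  if (is.null(config$simulate) && is.null(config$experiments))
    stop("config needs either $simulate or $experiments", call. = FALSE)
  if (!is.null(config$experiments)) {
    for (e in config$experiments)
      for (p in c(e$obs, e$meta, e$weather))
        if (!file.exists(p)) stop("input path does not exist: ", p,
                                  call. = FALSE)
  } else {
    config$simulate$n_experiments <- config$simulate$n_experiments %||% 3
    config$simulate$sigma_frac <- config$simulate$sigma_frac %||% 0.05
  }
  config
}

#' Run the full dilution-curve pipeline
#'
#' Executes, in order: data acquisition (simulation with known truths, or
#' loading CSV inputs), the low-biomass filter, per-experiment per-basis
#' curve fits, hybrid (pooled) fits per basis, cross-condition parameter
#' comparison, NNI computation with hybrid-vs-specific agreement and the
#' cross-basis crosswalk, covariate extraction with the driver correlation
#' matrix, and report rendering. Every stage's outputs are written as CSV
#' under `out_dir`, with a JSON run manifest; a rerun with the same config
#' reproduces every output byte-identically. Fit sub-seeds derive from the
#' master seed keyed by (experiment id, basis), so conditions never perturb
#' one another.
#'
#' @param config a [run_config()] list or YAML path.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- c("acquire", "filter", "fit", "hybrid", "compare", "nni",
              "drivers", "report")
  manifest <- list(package_version = as.character(utils::packageVersion("ncdilution")),
                   seed = cfg$seed, bases = cfg$bases,
                   filter_threshold = cfg$filter_threshold, mcmc = cfg$mcmc,
                   stages_planned = stages, stages_completed = character(0),
                   counts = list())
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      write_manifest()
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages_completed <<- c(manifest$stages_completed, name)
    res
  }

  truths <- NULL
  datasets <- run_stage("acquire", function() {
    if (!is.null(cfg$experiments)) {
      ds <- lapply(cfg$experiments, function(e)
        load_experiment(e$obs, e$meta, e$weather, quiet = TRUE))
      names(ds) <- vapply(ds, function(d) d$meta$experiment_id, character(1))
      ds
    } else {
      design <- default_gem_design(cfg$simulate$n_experiments,
                                   master_seed = cfg$simulate$master_seed %||%
                                     cfg$seed,
                                   sigma_frac = cfg$simulate$sigma_frac)
      sims <- simulate_gem_suite(design$truths, design$cfgs,
                                 master_seed = cfg$seed)
      truths <<- lapply(sims, `[[`, "truth")
      dir.create(file.path(out, "data"), showWarnings = FALSE)
      for (s in sims) write_experiment(s$dataset, file.path(out, "data"))
      jsonlite::write_json(
        lapply(truths, function(t) t[c("A1", "A2", "Bmax", "beta",
                                       "sigma_frac")]),
        file.path(out, "data", "truth.json"), auto_unbox = TRUE, digits = NA)
      lapply(sims, `[[`, "dataset")
    }
  })
  manifest$counts$experiments <- length(datasets)
  manifest$counts$observations_raw <-
    sum(vapply(datasets, function(d) nrow(d$observations), integer(1)))

  datasets <- run_stage("filter", function()
    lapply(datasets, filter_low_biomass, threshold = cfg$filter_threshold,
           quiet = TRUE))
  manifest$counts$observations_filtered <-
    sum(vapply(datasets, function(d) nrow(d$observations), integer(1)))

  fits <- run_stage("fit", function() {
    fits <- list()
    for (id in names(datasets)) for (b in cfg$bases) {
      fits[[paste(id, b, sep = "/")]] <- fit_dilution_curve(
        datasets[[id]], b,
        n_chains = cfg$mcmc$n_chains, n_burn = cfg$mcmc$n_burn,
        n_keep = cfg$mcmc$n_keep,
        seed = derive_seed(cfg$seed, paste(id, b, sep = "/")))
    }
    fits
  })
  fit_table <- do.call(rbind, lapply(fits, function(f) {
    s <- f$summary
    data.frame(experiment_id = f$experiment_id, basis = f$basis,
               A1_median = s$median[s$parameter == "A1"],
               A1_lo = s$q2.5[s$parameter == "A1"],
               A1_hi = s$q97.5[s$parameter == "A1"],
               A2_median = s$median[s$parameter == "A2"],
               A2_lo = s$q2.5[s$parameter == "A2"],
               A2_hi = s$q97.5[s$parameter == "A2"],
               converged = f$converged,
               rhat_A1 = f$diagnostics$rhat[["A1"]],
               rhat_A2 = f$diagnostics$rhat[["A2"]],
               stringsAsFactors = FALSE)
  }))
  write_csv_exact(fit_table, file.path(out, "fits.csv"))
  manifest$counts$fits <- nrow(fit_table)
  manifest$counts$fits_converged <- sum(fit_table$converged)

  hybrids <- run_stage("hybrid", function() {
    hy <- lapply(cfg$bases, function(b)
      fit_hybrid(datasets, b,
                 n_chains = cfg$mcmc$n_chains, n_burn = cfg$mcmc$n_burn,
                 n_keep = cfg$mcmc$n_keep,
                 seed = derive_seed(cfg$seed, paste("hybrid", b, sep = "/"))))
    names(hy) <- cfg$bases
    hy
  })
  hybrid_table <- do.call(rbind, lapply(hybrids, function(f) {
    s <- f$summary
    data.frame(basis = f$basis,
               A1_median = s$median[s$parameter == "A1"],
               A2_median = s$median[s$parameter == "A2"],
               converged = f$converged, stringsAsFactors = FALSE)
  }))
  write_csv_exact(hybrid_table, file.path(out, "hybrid_fits.csv"))

  run_stage("compare", function() {
    cmp_rows <- list()
    for (b in cfg$bases) {
      bf <- Filter(function(f) f$basis == b && f$converged, fits)
      if (length(bf) >= 2) {
        cmp <- suppressMessages(compare_parameters(bf))
        lt <- cmp$letters
        lt$basis <- b
        lt$cv_pct <- cmp$cv[lt$parameter]
        cmp_rows[[b]] <- lt
      }
    }
    if (length(cmp_rows) > 0)
      write_csv_exact(do.call(rbind, c(cmp_rows, make.row.names = FALSE)),
                      file.path(out, "parameter_comparison.csv"))
    NULL
  })

  run_stage("nni", function() {
    nni_rows <- list(); agree_rows <- list(); cross_rows <- list()
    for (id in names(datasets)) {
      ds <- datasets[[id]]
      curves <- list()
      for (b in cfg$bases) {
        f <- fits[[paste(id, b, sep = "/")]]
        if (!f$converged) next
        curves[[b]] <- as_nc_curve(f)
        spec_nni <- nni_series(ds, curves[[b]], b)
        nni_rows[[paste(id, b)]] <- spec_nni
        hf <- hybrids[[b]]
        if (hf$converged) {
          hyb_nni <- nni_series(ds, as_nc_curve(hf), b)
          ag <- agreement(hyb_nni$NNI, spec_nni$NNI)
          agree_rows[[paste(id, b)]] <- data.frame(
            experiment_id = id, basis = b, rmse = ag$rmse,
            nrmse_pct = ag$nrmse_pct, n = ag$n, stringsAsFactors = FALSE)
        }
      }
      if (all(c("leaf", "stem", "shoot") %in% names(curves))) {
        cw <- suppressWarnings(basis_crosswalk(ds, curves))
        cw$stats$experiment_id <- id
        cross_rows[[id]] <- cw$stats
      }
    }
    if (length(nni_rows) > 0)
      write_csv_exact(do.call(rbind, c(nni_rows, make.row.names = FALSE)),
                      file.path(out, "nni.csv"))
    if (length(agree_rows) > 0)
      write_csv_exact(do.call(rbind, c(agree_rows, make.row.names = FALSE)),
                      file.path(out, "nni_hybrid_agreement.csv"))
    if (length(cross_rows) > 0)
      write_csv_exact(do.call(rbind, c(cross_rows, make.row.names = FALSE)),
                      file.path(out, "nni_crosswalk.csv"))
    NULL
  })

  run_stage("drivers", function() {
    has_weather <- vapply(datasets, function(d) !is.null(d$weather),
                          logical(1))
    covars <- do.call(rbind, lapply(datasets[has_weather], extract_covariates))
    write_csv_exact(covars, file.path(out, "covariates.csv"))
    ft <- fit_table[fit_table$converged, , drop = FALSE]
    cor_rows <- list()
    for (b in cfg$bases) {
      fb <- ft[ft$basis == b, c("experiment_id", "A1_median", "A2_median")]
      names(fb) <- c("experiment_id", "A1", "A2")
      fb <- fb[fb$experiment_id %in% covars$experiment_id, , drop = FALSE]
      if (nrow(fb) >= 4) {
        cm <- correlate_drivers(fb, covars[covars$experiment_id %in%
                                             fb$experiment_id, ])
        cl <- cm$long
        cl$basis <- b
        cor_rows[[b]] <- cl
      }
    }
    if (length(cor_rows) > 0)
      write_csv_exact(do.call(rbind, c(cor_rows, make.row.names = FALSE)),
                      file.path(out, "correlation.csv"))
    manifest$counts$correlation_bases <<- length(cor_rows)
    NULL
  })

  manifest$counts$nni_bases <- length(cfg$bases)
  run_stage("report", function() render_report(out))
  write_manifest()
  invisible(manifest)
}

#' Render a plain-text run report from pipeline artifacts
#'
#' Summarizes the per-basis parameter tables (median and 95% credible
#' interval), convergence tally, grouping letters with CV, NNI agreement and
#' correlation tiers from the CSV artifacts in a pipeline output directory.
#' Missing artifacts are listed as absent rather than failing the report.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @param file output file (default `report.txt` inside `out_dir`; `NULL`
#'   for no file).
#' @return invisibly, the report lines.
#' @export
render_report <- function(out_dir, file = file.path(out_dir, "report.txt")) {
  lines <- c("Critical N dilution curve pipeline report",
             "=========================================")
  art <- function(name) file.path(out_dir, name)
  if (file.exists(art("fits.csv"))) {
    ft <- read.csv(art("fits.csv"), stringsAsFactors = FALSE)
    lines <- c(lines, "",
               sprintf("Fits: %d total, %d converged", nrow(ft),
                       sum(ft$converged)),
               "Per-fit curve parameters (median [95% CrI]):",
               sprintf("  %-18s %-6s A1 = %.3f [%.3f, %.3f]  A2 = %.3f [%.3f, %.3f]%s",
                       ft$experiment_id, ft$basis, ft$A1_median, ft$A1_lo,
                       ft$A1_hi, ft$A2_median, ft$A2_lo, ft$A2_hi,
                       ifelse(ft$converged, "", "  [excluded: not converged]")))
  } else lines <- c(lines, "", "fits.csv: absent")
  if (file.exists(art("hybrid_fits.csv"))) {
    ht <- read.csv(art("hybrid_fits.csv"), stringsAsFactors = FALSE)
    lines <- c(lines, "", "Hybrid (pooled) curves:",
               sprintf("  %-6s A1 = %.3f, A2 = %.3f%s", ht$basis,
                       ht$A1_median, ht$A2_median,
                       ifelse(ht$converged, "", "  [not converged]")))
  } else lines <- c(lines, "", "hybrid_fits.csv: absent")
  if (file.exists(art("parameter_comparison.csv"))) {
    pc <- read.csv(art("parameter_comparison.csv"), stringsAsFactors = FALSE)
    lines <- c(lines, "", "Cross-condition comparison (shared letters = not different at alpha):",
               sprintf("  %-6s %-18s %-3s median = %.3f letters = %s (CV %.1f%%)",
                       pc$basis, pc$fit_id, pc$parameter, pc$median,
                       pc$letters, pc$cv_pct))
  } else lines <- c(lines, "", "parameter_comparison.csv: absent")
  if (file.exists(art("nni_hybrid_agreement.csv"))) {
    na_ <- read.csv(art("nni_hybrid_agreement.csv"), stringsAsFactors = FALSE)
    lines <- c(lines, "", "Hybrid-vs-specific NNI agreement:",
               sprintf("  %-18s %-6s RMSE = %.4f, n-RMSE = %.2f%% (n = %d)",
                       na_$experiment_id, na_$basis, na_$rmse, na_$nrmse_pct,
                       na_$n))
  } else lines <- c(lines, "", "nni_hybrid_agreement.csv: absent")
  if (file.exists(art("nni_crosswalk.csv"))) {
    cw <- read.csv(art("nni_crosswalk.csv"), stringsAsFactors = FALSE)
    lines <- c(lines, "", "Organ-vs-shoot NNI crosswalk:",
               sprintf("  %-18s %-18s RMSE = %.4f, n-RMSE = %.2f%%",
                       cw$experiment_id, cw$comparison, cw$rmse, cw$nrmse_pct))
  } else lines <- c(lines, "", "nni_crosswalk.csv: absent")
  if (file.exists(art("correlation.csv"))) {
    co <- read.csv(art("correlation.csv"), stringsAsFactors = FALSE)
    sig <- co[!is.na(co$p) & co$p < 0.1, , drop = FALSE]
    lines <- c(lines, "", sprintf("Driver correlations: %d pairs, %d at P < 0.1:",
                                  nrow(co), nrow(sig)),
               if (nrow(sig) > 0)
                 sprintf("  [%s] %s ~ %s: r = %.3f (P = %.4f) %s", sig$basis,
                         sig$var1, sig$var2, sig$r, sig$p, sig$tier))
  } else lines <- c(lines, "", "correlation.csv: absent")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
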