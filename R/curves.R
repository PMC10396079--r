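#' A critical N dilution curve
#'
#' @param A1 critical N (% dry mass) at W = 1, > 0.
#' @param A2 dilution exponent, >= 0 (0 gives a flat curve).
#' @param basis organ basis the curve applies to.
#' @param provenance where the parameters came from: `"posterior-median"`,
#'   `"published-constant"` or `"truth"`.
#' @return object of class `nc_curve`.
#' @export
nc_curve <- function(A1, A2, basis = "shoot",
                     provenance = c("posterior-median", "published-constant",
                                    "truth")) {
  provenance <- match.arg(provenance)
  stopifnot(is.finite(A1), A1 > 0, is.finite(A2), A2 >= 0)
  basis <- match.arg(basis, BASES)
  structure(list(A1 = A1, A2 = A2, basis = basis, provenance = provenance),
            class = "nc_curve")
}

#' @export
print.nc_curve <- function(x, ...) {
  cat(sprintf("<nc_curve> %s basis (%s): Nc = %.4g * W^-%.4g\n",
              x$basis, x$provenance, x$A1, x$A2))
  invisible(x)
}

#' Evaluate a dilution curve
#'
#' `Nc = A1 * W^-A2`: the minimum N concentration needed for maximum growth
#' at biomass (or LAI) W, declining as the crop grows.
#'
#' @param curve an [nc_curve()].
#' @param W biomass (t/ha) or LAI, > 0; vectorized.
#' @return critical N concentration(s), % dry mass.
#' @examples
#' nc_value(nc_curve(3.06, 0.15, "leaf", "published-constant"), 1) # 3.06
#' @export
nc_value <- function(curve, W) {
  stopifnot(inherits(curve, "nc_curve"))
  if (any(!is.finite(W)) || any(W <= 0))
    stop("W must be positive", call. = FALSE)
  curve$A1 * W^(-curve$A2)
}

#' Extract the posterior-median curve from a fit
#'
#' @param fit an `nc_curvefit`.
#' @return an [nc_curve()] with `provenance = "posterior-median"`.
#' @export
as_nc_curve <- function(fit) {
  stopifnot(inherits(fit, "nc_curvefit"))
  s <- fit$summary
  nc_curve(s$median[s$parameter == "A1"], s$median[s$parameter == "A2"],
           fit$basis, "posterior-median")
}

#' Pointwise credible band of a fitted curve along W
#'
#' At each grid biomass, the curve is evaluated under every retained
#' posterior draw of (A1, A2) and the 2.5%, 50% and 97.5% quantiles are
#' taken; the band width (97.5% minus 2.5%) is the curve's uncertainty
#' measure along the biomass axis.
#'
#' @param fit a converged `nc_curvefit`.
#' @param w_grid positive ascending biomass (or LAI) grid.
#' @return data.frame of class `nc_width_profile` with columns
#'   `W, lower, median, upper, width`.
#' @export
credible_band <- function(fit, w_grid) {
  stopifnot(inherits(fit, "nc_curvefit"))
  if (!fit$converged)
    stop("refusing to build a credible band from a non-converged fit",
         call. = FALSE)
  if (any(w_grid <= 0) || is.unsorted(w_grid, strictly = TRUE))
    stop("w_grid must be positive and strictly ascending", call. = FALSE)
  pooled <- pool_draws(fit$posterior)
  a1 <- pooled[, "A1"]; a2 <- pooled[, "A2"]
  qs <- vapply(w_grid, function(w) {
    quantile(a1 * w^(-a2), c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  }, numeric(3))
  out <- data.frame(W = w_grid, lower = qs[1, ], median = qs[2, ],
                    upper = qs[3, ], width = qs[3, ] - qs[1, ])
  class(out) <- c("nc_width_profile", "data.frame")
  out
}

#' Fit a hybrid (pooled) dilution curve across experiments
#'
#' Pools every date group of every experiment into one model: each
#' experiment-date keeps its own plateau and slope nuisances, while a single
#' (A1, A2) is shared across all conditions — the universal curve usable
#' when condition-specific curves are unavailable.
#'
#' @param datasets list of `nc_experiment`s (already filtered), or a single
#'   one.
#' @param basis organ basis.
#' @param ... passed to [fit_dilution_curve()] / [sample_posterior()].
#' @return an `nc_curvefit` with `experiment_id = "hybrid"`.
#' @export
fit_hybrid <- function(datasets, basis, ...) {
  if (inherits(datasets, "nc_experiment")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1)
  groups <- unlist(lapply(datasets, make_date_groups, basis = basis),
                   recursive = FALSE)
  fit <- fit_dilution_curve(groups, basis, experiment_id = "hybrid", ...)
  fit
}

#' Coefficient of variation
#'
#' `CV = SD / mean x 100%` with the sample standard deviation.
#'
#' @param x numeric vector.
#' @return CV in percent.
#' @export
cv_percent <- function(x) sd(x) / mean(x) * 100

#' Compare curve parameters across fitted conditions
#'
#' For each curve parameter, every pair of converged fits is declared
#' different when the central `1 - alpha` interval of the difference of
#' their posterior draws excludes zero; a compact letter display is then
#' assigned over the non-difference graph (fits sharing a letter are
#' pairwise indistinguishable at level `alpha`), and the CV of the
#' posterior-median parameter across conditions quantifies the G x E x M
#' variation.
#'
#' @param fits list of `nc_curvefit`s; non-converged fits are dropped with a
#'   message.
#' @param alpha significance level (default 0.05).
#' @param params parameters compared (default `c("A1", "A2")`).
#' @return object of class `nc_comparison`: list with `letters` (data.frame
#'   fit_id x parameter with median and letter codes), `pairwise`
#'   (data.frame of difference intervals) and `cv` (named CV in % of the
#'   medians across fits).
#' @export
compare_parameters <- function(fits, alpha = 0.05, params = c("A1", "A2")) {
  keep <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!keep))
    message(sum(!keep), " non-converged fit(s) excluded from comparison")
  fits <- fits[keep]
  if (length(fits) < 2)
    stop("need >= 2 converged fits to compare", call. = FALSE)
  ids <- vapply(fits, `[[`, character(1), "experiment_id")
  ord <- order(ids)
  fits <- fits[ord]; ids <- ids[ord]
  n <- length(fits)
  pooled <- lapply(fits, function(f) pool_draws(f$posterior))
  probs <- c(alpha / 2, 1 - alpha / 2)

  pw <- list(); letters_df <- list()
  for (p in params) {
    med <- vapply(seq_len(n), function(j)
      median(pooled[[j]][, p]), numeric(1))
    diff_mat <- matrix(FALSE, n, n)  # TRUE = different
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      xi <- pooled[[i]][, p]; xj <- pooled[[j]][, p]
      m <- min(length(xi), length(xj))
      dq <- quantile(xi[seq_len(m)] - xj[seq_len(m)], probs, names = FALSE)
      different <- dq[1] > 0 || dq[2] < 0
      diff_mat[i, j] <- diff_mat[j, i] <- different
      pw[[length(pw) + 1]] <- data.frame(
        parameter = p, fit_a = ids[i], fit_b = ids[j],
        diff_lower = dq[1], diff_upper = dq[2], different = different,
        stringsAsFactors = FALSE)
    }
    letters_df[[p]] <- data.frame(
      fit_id = ids, parameter = p, median = med,
      letters = letter_display(diff_mat), stringsAsFactors = FALSE)
    names(letters_df[[p]]$letters) <- NULL
  }
  cv <- vapply(params, function(p) cv_percent(letters_df[[p]]$median),
               numeric(1))
  structure(
    list(letters = do.call(rbind, c(letters_df, make.row.names = FALSE)),
         pairwise = do.call(rbind, c(pw, make.row.names = FALSE)),
         cv = cv, alpha = alpha),
    class = "nc_comparison"
  )
}

# Greedy clique cover of the non-difference graph, deterministic in input
# order: each fit joins every existing letter group it is compatible with,
# or founds a new one.
letter_display <- function(diff_mat) {
  n <- nrow(diff_mat)
  groups <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(!diff_mat[i, groups[[g]]])) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  # prune redundant groups (subsets of another)
  keep <- rep(TRUE, length(groups))
  for (g in seq_along(groups)) for (h in seq_along(groups)) {
    if (g != h && keep[h] && all(groups[[g]] %in% groups[[h]]) &&
        length(groups[[g]]) < length(groups[[h]])) keep[g] <- FALSE
  }
  groups <- groups[keep]
  labels <- letters[seq_along(groups)]
  vapply(seq_len(n), function(i)
    paste(labels[vapply(groups, function(g) i %in% g, logical(1))],
          collapse = ""), character(1))
}

#' @export
print.nc_comparison <- function(x, ...) {
  cat(sprintf("<nc_comparison> %d fits, alpha = %g\n",
              length(unique(x$letters$fit_id)), x$alpha))
  print(x$letters, row.names = FALSE)
  cat("CV of medians (%):",
      paste(sprintf("%s %.2f", names(x$cv), x$cv), collapse = ", "), "\n")
  invisible(x)
}

#' Published dilution-curve constants
#'
#' Small registry of literature curves for side-by-side plotting, read from
#' the package's `curves.yaml`.
#'
#' @return data.frame with columns `label, basis, A1, A2, provenance`.
#' @export
published_curves <- function() {
  reg <- yaml::yaml.load_file(system.file("extdata", "published_curves.yaml",
                                          package = "ncdilution"))
  do.call(rbind, lapply(reg, function(e)
    data.frame(label = e$label, basis = e$basis, A1 = e$A1, A2 = e$A2,
               provenance = e$provenance, stringsAsFactors = FALSE)))
}
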