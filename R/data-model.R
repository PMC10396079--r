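#' Construct experiment metadata
#'
#' One record of trial-level information for a single genotype x environment x
#' management (G x E x M) condition: site, season, genotype, sowing density and
#' the nitrogen rate ladder.
#'
#' @param experiment_id character label, e.g. `"2012-XX-AK58"`.
#' @param site character site name.
#' @param year integer harvest year.
#' @param genotype character cultivar name.
#' @param density_plants_m2 sowing density (plants per square metre, > 0).
#' @param sowing_date,flowering_date calendar dates (`Date` or ISO-8601
#'   strings); flowering must fall strictly after sowing.
#' @param n_rates_kg_ha numeric vector of applied N rates (kg N per ha,
#'   non-negative, at least one distinct value).
#' @return an object of class `nc_meta` (a validated list).
#' @export
experiment_meta <- function(experiment_id, site, year, genotype,
                            density_plants_m2, sowing_date, flowering_date,
                            n_rates_kg_ha) {
  sowing_date <- as.Date(sowing_date)
  flowering_date <- as.Date(flowering_date)
  stopifnot(is.character(experiment_id), nchar(experiment_id) > 0)
  if (!is.finite(density_plants_m2) || density_plants_m2 <= 0)
    stop("density_plants_m2 must be a positive number", call. = FALSE)
  if (!(flowering_date > sowing_date))
    stop("flowering_date must be strictly after sowing_date", call. = FALSE)
  n_rates_kg_ha <- as.numeric(n_rates_kg_ha)
  if (length(n_rates_kg_ha) == 0 || any(!is.finite(n_rates_kg_ha)) ||
      any(n_rates_kg_ha < 0))
    stop("n_rates_kg_ha must be non-empty and non-negative", call. = FALSE)
  if (length(unique(n_rates_kg_ha)) < 1)
    stop("n_rates_kg_ha must contain at least one distinct rate", call. = FALSE)
  structure(
    list(experiment_id = experiment_id, site = site, year = as.integer(year),
         genotype = genotype, density_plants_m2 = density_plants_m2,
         sowing_date = sowing_date, flowering_date = flowering_date,
         n_rates_kg_ha = n_rates_kg_ha),
    class = "nc_meta"
  )
}

#' @export
print.nc_meta <- function(x, ...) {
  cat(sprintf("<nc_meta> %s: %s %d, %s, %.0f plants/m2, N rates {%s} kg/ha\n",
              x$experiment_id, x$site, x$year, x$genotype,
              x$density_plants_m2,
              paste(x$n_rates_kg_ha, collapse = ", ")))
  invisible(x)
}

validate_observations <- function(obs) {
  missing_cols <- setdiff(OBS_COLUMNS, names(obs))
  if (length(missing_cols) > 0)
    stop("observation table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- c("biomass_t_ha", "lai", "n_conc_pct",
                "shoot_biomass_t_ha", "shoot_n_conc_pct")
  for (cl in num_cols) obs[[cl]] <- suppressWarnings(as.numeric(obs[[cl]]))
  bad <- !(obs$organ %in% c("leaf", "stem", "shoot")) |
    !is.finite(obs$biomass_t_ha) | obs$biomass_t_ha <= 0 |
    !is.finite(obs$n_conc_pct) | obs$n_conc_pct <= 0 | obs$n_conc_pct >= 10 |
    !is.finite(obs$shoot_biomass_t_ha) | obs$shoot_biomass_t_ha <= 0 |
    !is.finite(obs$shoot_n_conc_pct) | obs$shoot_n_conc_pct <= 0 |
    obs$shoot_n_conc_pct >= 10 |
    (!is.na(obs$lai) & obs$lai <= 0)
  list(valid = obs[!bad, , drop = FALSE], rejected = obs[bad, , drop = FALSE])
}

#' Assemble a validated experiment dataset
#'
#' Binds trial metadata, the per-date per-treatment organ observations and an
#' optional daily weather series into the container all downstream stages
#' consume. Observation rows failing row-level validation (non-positive
#' biomass, N concentration outside (0, 10) % ...) are dropped and reported.
#'
#' @param meta an [experiment_meta()] object.
#' @param observations data.frame with columns `experiment_id, date,
#'   treatment_id, organ, biomass_t_ha, lai, n_conc_pct, shoot_biomass_t_ha,
#'   shoot_n_conc_pct, replicate`. `lai` may be `NA` on non-leaf rows.
#' @param weather optional data.frame with columns `date, tmax_c, tmin_c,
#'   rain_mm` (daily, contiguous over sowing to flowering).
#' @param quiet suppress the rejected-row report.
#' @return object of class `nc_experiment`: list with elements `meta`,
#'   `observations` (with a chronological `date_index` column added) and
#'   `weather`. Rejected rows are kept in `attr(, "rejected")`.
#' @export
experiment_dataset <- function(meta, observations, weather = NULL,
                               quiet = FALSE) {
  stopifnot(inherits(meta, "nc_meta"))
  chk <- validate_observations(observations)
  obs <- chk$valid
  if (nrow(obs) == 0)
    stop("no valid observation rows remain for experiment '",
         meta$experiment_id, "'", call. = FALSE)
  if (!quiet && nrow(chk$rejected) > 0)
    message(nrow(chk$rejected), " observation row(s) rejected by validation ",
            "(rows: ", paste(rownames(chk$rejected), collapse = ", "), ")")
  obs$date <- as.Date(obs$date)
  obs$date_index <- match(obs$date, sort(unique(obs$date)))
  dup <- duplicated(obs[, c("date_index", "treatment_id", "organ", "replicate")])
  if (any(dup))
    stop("duplicated (date, treatment, organ, replicate) observation(s)",
         call. = FALSE)
  n_pre_flower <- length(unique(obs$date[obs$date < meta$flowering_date]))
  if (n_pre_flower < 5)
    warning("only ", n_pre_flower, " distinct sampling date(s) before ",
            "flowering; at least 5 are recommended", call. = FALSE)
  if (!is.null(weather)) {
    miss <- setdiff(WEATHER_COLUMNS, names(weather))
    if (length(miss) > 0)
      stop("weather table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    weather$date <- as.Date(weather$date)
    if (any(weather$tmax_c < weather$tmin_c))
      stop("weather has days with tmax_c < tmin_c", call. = FALSE)
  }
  structure(
    list(meta = meta, observations = obs, weather = weather),
    rejected = chk$rejected,
    class = "nc_experiment"
  )
}

#' @export
print.nc_experiment <- function(x, ...) {
  o <- x$observations
  cat(sprintf(
    "<nc_experiment> %s: %d observations, %d dates, %d treatments%s\n",
    x$meta$experiment_id, nrow(o), length(unique(o$date_index)),
    length(unique(o$treatment_id)),
    if (is.null(x$weather)) "" else sprintf(", %d weather days",
                                            nrow(x$weather))))
  invisible(x)
}

parse_meta_table <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    m <- yaml::yaml.load_file(path)
    rates <- m$n_rates_kg_ha
    if (is.character(rates)) rates <- as.numeric(strsplit(rates, ";")[[1]])
  } else {
    tab <- read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(META_COLUMNS, names(tab))
    if (length(miss) > 0)
      stop("metadata file missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    m <- as.list(tab[1, ])
    rates <- as.numeric(strsplit(as.character(m$n_rates_kg_ha), ";")[[1]])
  }
  experiment_meta(m$experiment_id, m$site, m$year, m$genotype,
                  as.numeric(m$density_plants_m2), m$sowing_date,
                  m$flowering_date, rates)
}

#' Read an experiment from CSV files
#'
#' @param obs_path path to the observations CSV (see [experiment_dataset()]
#'   for the column schema).
#' @param meta_path path to the metadata CSV (one row) or YAML file.
#' @param weather_path optional path to the daily weather CSV
#'   (`date, tmax_c, tmin_c, rain_mm`).
#' @param quiet suppress the rejected-row report.
#' @return an `nc_experiment`.
#' @export
load_experiment <- function(obs_path, meta_path, weather_path = NULL,
                            quiet = FALSE) {
  for (p in c(obs_path, meta_path, weather_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  obs <- read.csv(obs_path, stringsAsFactors = FALSE)
  meta <- parse_meta_table(meta_path)
  weather <- if (!is.null(weather_path))
    read.csv(weather_path, stringsAsFactors = FALSE)
  experiment_dataset(meta, obs, weather, quiet = quiet)
}

# Format numerics at 17 significant digits so that load -> write -> load is
# an exact round trip at double precision.
write_csv_exact <- function(df, path) {
  for (cl in names(df)) {
    if (is.numeric(df[[cl]]) && !is.integer(df[[cl]])) {
      s <- sprintf("%.17g", df[[cl]])
      s[is.na(df[[cl]])] <- NA
      df[[cl]] <- s
    }
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write an experiment back to CSV files
#'
#' Inverse of [load_experiment()]: numeric fields survive a write/read cycle
#' bit-exactly.
#'
#' @param ds an `nc_experiment`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem, defaults to the experiment id.
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(ds, dir, stem = ds$meta$experiment_id) {
  stopifnot(inherits(ds, "nc_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- ds$observations
  obs$date <- format(obs$date, "%Y-%m-%d")
  obs$date_index <- NULL
  obs_path <- file.path(dir, paste0(stem, "_observations.csv"))
  write_csv_exact(obs[, OBS_COLUMNS], obs_path)
  m <- ds$meta
  meta_df <- data.frame(
    experiment_id = m$experiment_id, site = m$site, year = m$year,
    genotype = m$genotype, density_plants_m2 = m$density_plants_m2,
    sowing_date = format(m$sowing_date, "%Y-%m-%d"),
    flowering_date = format(m$flowering_date, "%Y-%m-%d"),
    n_rates_kg_ha = paste(sprintf("%.17g", m$n_rates_kg_ha), collapse = ";"),
    stringsAsFactors = FALSE
  )
  meta_path <- file.path(dir, paste0(stem, "_metadata.csv"))
  write_csv_exact(meta_df, meta_path)
  paths <- c(observations = obs_path, metadata = meta_path)
  if (!is.null(ds$weather)) {
    w <- ds$weather
    w$date <- format(w$date, "%Y-%m-%d")
    weather_path <- file.path(dir, paste0(stem, "_weather.csv"))
    write_csv_exact(w[, WEATHER_COLUMNS], weather_path)
    paths <- c(paths, weather = weather_path)
  }
  invisible(paths)
}

#' Drop early low-biomass samplings
#'
#' Observations taken while the crop is still establishing carry N
#' concentrations that do not yet follow the dilution process; the standard
#' screen removes every observation whose *shoot* biomass is below a
#' threshold, for all organ bases alike.
#'
#' @param ds an `nc_experiment`.
#' @param threshold shoot biomass threshold in t/ha (default 1.0);
#'   observations with `shoot_biomass_t_ha >= threshold` are retained, so the
#'   boundary value itself is kept.
#' @param quiet suppress the removed-row count message.
#' @return the filtered `nc_experiment`.
#' @export
filter_low_biomass <- function(ds, threshold = 1.0, quiet = FALSE) {
  stopifnot(inherits(ds, "nc_experiment"))
  if (!is.finite(threshold) || threshold < 0)
    stop("threshold must be a non-negative number", call. = FALSE)
  keep <- ds$observations$shoot_biomass_t_ha >= threshold
  if (!any(keep))
    stop("low-biomass filter removed every observation (threshold = ",
         threshold, " t/ha); review the threshold", call. = FALSE)
  if (!quiet && sum(!keep) > 0)
    message(sum(!keep), " observation(s) below ", threshold,
            " t/ha shoot biomass removed")
  ds$observations <- ds$observations[keep, , drop = FALSE]
  ds
}

# Per-basis (W, N) extraction implementing the basis pairing rule:
# leaf/stem/shoot pair organ biomass with the same organ's N concentration;
# the LAI basis pairs LAI (taken on leaf rows) with *shoot* N concentration.
basis_pairs <- function(ds, basis) {
  basis <- match.arg(basis, BASES)
  o <- ds$observations
  if (basis == "lai") {
    rows <- o[o$organ == "leaf" & !is.na(o$lai), , drop = FALSE]
    if (nrow(rows) == 0) stop("no LAI observations present", call. = FALSE)
    data.frame(experiment_id = rows$experiment_id, date = rows$date,
               date_index = rows$date_index, treatment_id = rows$treatment_id,
               replicate = rows$replicate, W = rows$lai,
               N = rows$shoot_n_conc_pct, shoot_W = rows$shoot_biomass_t_ha,
               stringsAsFactors = FALSE)
  } else {
    rows <- o[o$organ == basis, , drop = FALSE]
    if (nrow(rows) == 0)
      stop("no observations for basis '", basis, "'", call. = FALSE)
    data.frame(experiment_id = rows$experiment_id, date = rows$date,
               date_index = rows$date_index, treatment_id = rows$treatment_id,
               replicate = rows$replicate, W = rows$biomass_t_ha,
               N = rows$n_conc_pct, shoot_W = rows$shoot_biomass_t_ha,
               stringsAsFactors = FALSE)
  }
}

#' Group the (biomass, N concentration) pairs of one basis by sampling date
#'
#' Each sampling date contributes one biomass-response group: the set of
#' (W, N%) pairs across N treatments at that date, which is the unit on which
#' the linear-plus-plateau change-point model is fitted. Groups with fewer
#' than three pairs cannot identify a slope, a plateau and a critical point
#' and are dropped with a warning.
#'
#' @param ds an `nc_experiment`, already passed through
#'   [filter_low_biomass()].
#' @param basis one of `"leaf"`, `"stem"`, `"shoot"`, `"lai"`.
#' @param use `"replicates"` fits every replicate plot as its own point
#'   (default); `"means"` averages replicates per (date, treatment) first.
#' @return a list of `nc_date_group` objects, each a list with elements
#'   `date_index`, `basis`, `experiment_id`, `W`, `N`.
#' @export
make_date_groups <- function(ds, basis, use = c("replicates", "means")) {
  use <- match.arg(use)
  pairs <- basis_pairs(ds, basis)
  if (use == "means") {
    agg <- stats::aggregate(cbind(W, N) ~ experiment_id + date_index +
                              treatment_id, data = pairs, FUN = mean)
    pairs <- agg
  }
  groups <- lapply(split(pairs, pairs$date_index), function(g) {
    structure(list(date_index = g$date_index[1], basis = basis,
                   experiment_id = g$experiment_id[1], W = g$W, N = g$N),
              class = "nc_date_group")
  })
  sizes <- vapply(groups, function(g) length(g$W), integer(1))
  if (any(sizes < 3))
    warning(sum(sizes < 3), " date group(s) with fewer than 3 pairs dropped",
            call. = FALSE)
  groups <- groups[sizes >= 3]
  if (length(groups) == 0)
    stop("no date group retains >= 3 (W, N) pairs for basis '", basis, "'",
         call. = FALSE)
  unname(groups)
}

#' @export
print.nc_date_group <- function(x, ...) {
  cat(sprintf("<nc_date_group> %s date %d (%s): %d pairs, W in [%.3g, %.3g]\n",
              x$experiment_id, x$date_index, x$basis, length(x$W),
              min(x$W), max(x$W)))
  invisible(x)
}
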