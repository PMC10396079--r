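#' Accumulated growing degree days
#'
#' `AGDD = sum over days of (Tmax + Tmin)/2 - Tbase`, with wheat's base
#' temperature of 0 degrees C by default. Days whose mean falls below the
#' base contribute zero when `clamp = TRUE` (the standard agronomic
#' convention for winter crops; set `clamp = FALSE` for the literal unclamped
#' sum).
#'
#' @param weather data.frame with daily `date, tmax_c, tmin_c` (and
#'   `rain_mm`) rows.
#' @param start,end dates bounding the accumulation window (inclusive).
#' @param t_base base temperature, degrees C (default 0).
#' @param clamp clamp negative daily contributions to zero (default TRUE).
#' @return AGDD in degree C days.
#' @export
compute_agdd <- function(weather, start, end, t_base = 0, clamp = TRUE) {
  start <- as.Date(start); end <- as.Date(end)
  if (start > end) stop("start must not be after end", call. = FALSE)
  wdate <- as.Date(weather$date)
  wanted <- seq(start, end, by = "1 day")
  idx <- match(wanted, wdate)
  if (anyNA(idx)) {
    gaps <- wanted[is.na(idx)]
    stop("weather series does not cover ", length(gaps), " day(s) in range ",
         "(first gap: ", format(gaps[1]), ")", call. = FALSE)
  }
  gdd <- (weather$tmax_c[idx] + weather$tmin_c[idx]) / 2 - t_base
  if (clamp) gdd <- pmax(gdd, 0)
  sum(gdd)
}

#' Per-experiment G x E x M covariates
#'
#' The drivers correlated with the fitted curve parameters: maximum shoot
#' biomass (DMmax) and maximum shoot N concentration (Nmax) observed during
#' the vegetative period, the vegetative period duration in days (VPD,
#' sowing to flowering), accumulated growing degree days (AGDD) and its
#' daily average, total rainfall over the period, and sowing density.
#'
#' @param ds an `nc_experiment` with its weather series attached.
#' @return one-row data.frame with columns `experiment_id, DMmax, Nmax, VPD,
#'   AGDD, GDD_daily, rainfall_total, density`.
#' @export
extract_covariates <- function(ds) {
  stopifnot(inherits(ds, "nc_experiment"))
  if (is.null(ds$weather))
    stop("dataset has no weather series attached", call. = FALSE)
  m <- ds$meta
  o <- ds$observations
  pre <- o[o$date < m$flowering_date, , drop = FALSE]
  if (nrow(pre) == 0 || !any(!is.na(pre$shoot_biomass_t_ha)))
    stop("no shoot observations before flowering", call. = FALSE)
  vpd <- as.numeric(m$flowering_date - m$sowing_date)
  # accumulate over exactly VPD days: sowing up to the day before flowering
  agdd <- compute_agdd(ds$weather, m$sowing_date, m$flowering_date - 1)
  wdate <- as.Date(ds$weather$date)
  in_window <- wdate >= m$sowing_date & wdate < m$flowering_date
  data.frame(
    experiment_id = m$experiment_id,
    DMmax = max(pre$shoot_biomass_t_ha),
    Nmax = max(pre$shoot_n_conc_pct),
    VPD = vpd,
    AGDD = agdd,
    GDD_daily = agdd / vpd,
    rainfall_total = sum(ds$weather$rain_mm[in_window]),
    density = m$density_plants_m2,
    stringsAsFactors = FALSE
  )
}

sig_tier <- function(p) {
  if (!is.finite(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else if (p < 0.1) "." else ""
}

#' Correlation matrix of curve parameters and trial drivers
#'
#' Pairwise Pearson correlations (two-sided t test on n - 2 degrees of
#' freedom) between per-experiment posterior-median curve parameters and the
#' covariates, with significance tiers at the 0.1 / 0.05 / 0.01 / 0.001
#' levels (marked `.`, `*`, `**`, `***`). Pairs involving a constant
#' variable are flagged undefined instead of failing the whole matrix.
#'
#' @param params data.frame with `experiment_id` plus one column per curve
#'   parameter (e.g. `A1`, `A2`), one row per experiment.
#' @param covars data.frame of [extract_covariates()] rows.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return object of class `nc_cormat`: list with `long` (data.frame `var1,
#'   var2, r, p, n, tier`), `r` and `p` (symmetric matrices), `method`.
#' @export
correlate_drivers <- function(params, covars, method = c("pearson",
                                                         "spearman")) {
  method <- match.arg(method)
  stopifnot("experiment_id" %in% names(params),
            "experiment_id" %in% names(covars))
  merged <- merge(params, covars, by = "experiment_id")
  if (nrow(merged) < nrow(params) || nrow(merged) < nrow(covars))
    stop("experiment ids do not fully match between params and covars",
         call. = FALSE)
  if (nrow(merged) < 4)
    stop("need >= 4 matched experiments for a correlation p-value",
         call. = FALSE)
  merged <- merged[order(merged$experiment_id), , drop = FALSE]
  vars <- setdiff(names(merged), "experiment_id")
  nv <- length(vars)
  r <- p <- matrix(NA_real_, nv, nv, dimnames = list(vars, vars))
  diag(r) <- 1; diag(p) <- 0
  long <- list()
  for (i in seq_len(nv - 1)) for (j in (i + 1):nv) {
    x <- merged[[vars[i]]]; y <- merged[[vars[j]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 4 && sd(x[ok]) > 0 && sd(y[ok]) > 0) {
      ct <- cor.test(x[ok], y[ok], method = method, exact = FALSE)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
    long[[length(long) + 1]] <- data.frame(
      var1 = vars[i], var2 = vars[j], r = r[i, j], p = p[i, j],
      n = sum(ok), tier = sig_tier(p[i, j]), stringsAsFactors = FALSE)
  }
  structure(list(long = do.call(rbind, long), r = r, p = p, method = method,
                 n = nrow(merged)),
            class = "nc_cormat")
}

#' @export
print.nc_cormat <- function(x, ...) {
  cat(sprintf("<nc_cormat> %s correlations over %d experiments, %d variables\n",
              x$method, x$n, ncol(x$r)))
  sig <- x$long[x$long$tier %in% c("*", "**", "***"), , drop = FALSE]
  if (nrow(sig) > 0) {
    cat("significant pairs (P < 0.05):\n")
    print(sig, row.names = FALSE, digits = 3)
  } else cat("no pairs significant at P < 0.05\n")
  invisible(x)
}
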