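#' Linear-plus-plateau biomass response to N concentration
#'
#' At a given sampling date, biomass (or LAI) W rises linearly with plant N
#' concentration up to the critical concentration Nc, beyond which extra N is
#' luxury uptake and W stays at the date's maximum Bmax:
#' `W = Bmax * (1 - beta * (Nc - N))` for `N < Nc`, else `Bmax`, clipped
#' below at zero.
#'
#' @param N N concentration (% dry mass); vectorized.
#' @param Bmax plateau biomass (t/ha, or LAI units), > 0.
#' @param beta relative biomass loss per unit N% deficit, >= 0.
#' @param Nc critical N concentration (% dry mass), > 0.
#' @return expected W, same length as `N`.
#' @examples
#' linear_plus_plateau(2, Bmax = 5, beta = 0.4, Nc = 3) # 3
#' @export
linear_plus_plateau <- function(N, Bmax, beta, Nc) {
  stopifnot(Bmax > 0, beta >= 0, Nc > 0)
  w <- ifelse(N < Nc, Bmax * (1 - beta * (Nc - N)), Bmax)
  pmax(w, 0)
}

#' Ground truth for one simulated experiment
#'
#' @param A1 true dilution-curve intercept: critical N (%) at W = 1; must lie
#'   in the prior range (0, 12).
#' @param A2 true dilution exponent, in (0, 5).
#' @param Bmax per-date plateau biomass (t/ha), strictly increasing over
#'   sampling dates.
#' @param beta per-date linear-limb slope (recycled if scalar), > 0.
#' @param sigma_frac observation noise SD as a fraction of the date's Bmax
#'   (default 0.05, i.e. 5% noise).
#' @return an object of class `nc_truth` carrying, in addition, the implied
#'   per-date critical concentrations `Nc = A1 * Bmax^-A2`.
#' @export
truth_record <- function(A1, A2, Bmax, beta = 0.6, sigma_frac = 0.05) {
  stopifnot(A1 > 0, A1 < 12, A2 >= 0, A2 < 5, all(Bmax > 0),
            all(beta > 0), sigma_frac >= 0)
  if (length(Bmax) > 1 && any(diff(Bmax) <= 0))
    stop("Bmax must be strictly increasing over dates", call. = FALSE)
  beta <- rep_len(beta, length(Bmax))
  Nc <- A1 * Bmax^(-A2)
  structure(list(A1 = A1, A2 = A2, Bmax = Bmax, beta = beta,
                 sigma_frac = sigma_frac, Nc = Nc),
            class = "nc_truth")
}

#' @export
print.nc_truth <- function(x, ...) {
  cat(sprintf("<nc_truth> A1 = %.3g, A2 = %.3g, %d dates, Bmax %.3g..%.3g\n",
              x$A1, x$A2, length(x$Bmax), min(x$Bmax), max(x$Bmax)))
  invisible(x)
}

#' Simulation design for one trial
#'
#' Encodes the layout a wheat N-rate trial of this kind uses: several
#' sampling dates before flowering, a ladder of N rates from nil to luxury
#' supply, replicate plots, and a winter-season daily weather generator.
#'
#' @param experiment_id character label.
#' @param n_dates number of sampling dates (>= 2; trials of this design
#'   sample at least 5 times before flowering).
#' @param n_rates number of N treatments (>= 3).
#' @param replicates replicate plots per treatment (>= 1).
#' @param n_quantiles achieved-N placement as multiples of the date's
#'   critical concentration; default `c(0.6, 0.8, 0.95, 1.05, 1.2, 1.4)` when
#'   `n_rates == 6`, otherwise evenly spaced on \[0.6, 1.4\] so both limbs of
#'   the plateau are always populated.
#' @param max_rate_kg_ha largest applied N rate (kg N/ha, default 300).
#' @param seed integer RNG seed; recorded in the output manifest.
#' @param site,year,genotype,density_plants_m2 trial metadata.
#' @param sowing_date sowing date; flowering is placed `season_days` later.
#' @param season_days vegetative period length in days (default 180).
#' @param weather list of weather-generator parameters: `tmean_c` (season
#'   mean of daily mean temperature), `tamp_c` (seasonal amplitude),
#'   `trange_c` (diurnal range), `rain_prob`, `rain_mean_mm`.
#' @param leaf_frac leaf share of shoot biomass at the first and last date;
#'   declines linearly in between (default 0.55 to 0.30, so stem dominates
#'   late).
#' @param leaf_n_offset leaf N concentration sits this many % points above
#'   shoot N (default 0.8); stem N is solved so the biomass-weighted organ
#'   mean reproduces shoot N exactly.
#' @param sla specific leaf area converting leaf biomass to LAI
#'   (default 2.0 ha/t).
#' @return an object of class `nc_sim_config`.
#' @export
sim_config <- function(experiment_id = "SIM-01", n_dates = 7, n_rates = 6,
                       replicates = 3, n_quantiles = NULL,
                       max_rate_kg_ha = 300, seed = 1,
                       site = "Nanjing", year = 2013, genotype = "SIMW-1",
                       density_plants_m2 = 225,
                       sowing_date = "2012-10-25", season_days = 180,
                       weather = list(tmean_c = 9, tamp_c = 8, trange_c = 9,
                                      rain_prob = 0.3, rain_mean_mm = 6),
                       leaf_frac = c(0.55, 0.30), leaf_n_offset = 0.8,
                       sla = 2.0) {
  stopifnot(n_dates >= 2, n_rates >= 3, replicates >= 1)
  if (is.null(n_quantiles)) {
    n_quantiles <- if (n_rates == 6) c(0.6, 0.8, 0.95, 1.05, 1.2, 1.4)
    else seq(0.6, 1.4, length.out = n_rates)
  }
  stopifnot(length(n_quantiles) == n_rates, any(n_quantiles < 1),
            any(n_quantiles > 1))
  structure(
    list(experiment_id = experiment_id, n_dates = n_dates, n_rates = n_rates,
         replicates = replicates, n_quantiles = n_quantiles,
         max_rate_kg_ha = max_rate_kg_ha, seed = as.integer(seed),
         site = site, year = year, genotype = genotype,
         density_plants_m2 = density_plants_m2,
         sowing_date = as.Date(sowing_date), season_days = season_days,
         weather = weather, leaf_frac = leaf_frac,
         leaf_n_offset = leaf_n_offset, sla = sla),
    class = "nc_sim_config"
  )
}

#' Default per-date plateau trajectory
#'
#' Exponential growth of shoot biomass over the vegetative period, the usual
#' shape between tillering and flowering.
#'
#' @param n_dates number of sampling dates.
#' @param from,to shoot biomass at the first and last sampling (t/ha).
#' @return strictly increasing numeric vector of length `n_dates`.
#' @export
default_bmax <- function(n_dates, from = 1.5, to = 12) {
  exp(seq(log(from), log(to), length.out = n_dates))
}

simulate_weather <- function(cfg) {
  n <- cfg$season_days
  wp <- cfg$weather
  doy <- seq_len(n)
  # winter wheat season: coolest near mid-season
  tmean <- wp$tmean_c - wp$tamp_c * cos(2 * pi * (doy - n / 2) / 365 + pi) +
    rnorm(n, 0, 1.5)
  tmax <- tmean + wp$trange_c / 2
  tmin <- tmean - wp$trange_c / 2
  rain <- ifelse(runif(n) < wp$rain_prob, rgamma(n, 1.2, 1.2 / wp$rain_mean_mm), 0)
  data.frame(
    date = seq(cfg$sowing_date, by = "1 day", length.out = n),
    tmax_c = round(tmax, 2), tmin_c = round(tmin, 2),
    rain_mm = round(rain, 2), stringsAsFactors = FALSE
  )
}

#' Simulate one trial with a known ground-truth dilution curve
#'
#' For each sampling date and treatment an achieved shoot N concentration is
#' placed at the configured multiple of the date's true critical
#' concentration; expected shoot biomass follows the linear-plus-plateau
#' response, replicate plots add Gaussian noise with SD proportional to the
#' date's plateau. Leaf and stem biomass partition the shoot (declining leaf
#' share), organ N concentrations are set so their biomass-weighted mean
#' equals shoot N, and LAI is leaf biomass times a specific leaf area.
#' Identical `(truth, cfg)` (the seed lives in `cfg`) give identical output.
#'
#' @param truth an [truth_record()]; `length(truth$Bmax)` must equal
#'   `cfg$n_dates`.
#' @param cfg an [sim_config()].
#' @return list with elements `dataset` (a validated `nc_experiment` with
#'   weather attached) and `truth` (echoed, with the achieved-N design in
#'   `attr(, "design")`).
#' @export
simulate_experiment <- function(truth, cfg) {
  stopifnot(inherits(truth, "nc_truth"), inherits(cfg, "nc_sim_config"))
  if (length(truth$Bmax) != cfg$n_dates)
    stop("length(truth$Bmax) must equal cfg$n_dates", call. = FALSE)
  set.seed(cfg$seed)
  weather <- simulate_weather(cfg)
  flowering <- cfg$sowing_date + cfg$season_days
  # sampling dates spread over the second half of the vegetative period
  offs <- round(seq(0.45, 0.98, length.out = cfg$n_dates) * cfg$season_days)
  dates <- cfg$sowing_date + offs
  rates <- round(seq(0, cfg$max_rate_kg_ha, length.out = cfg$n_rates))
  lf <- seq(cfg$leaf_frac[1], cfg$leaf_frac[2], length.out = cfg$n_dates)

  rows <- vector("list", cfg$n_dates * cfg$n_rates * cfg$replicates)
  design <- vector("list", cfg$n_dates * cfg$n_rates)
  k <- 0L; d <- 0L
  for (i in seq_len(cfg$n_dates)) {
    Nc_i <- truth$Nc[i]; Bmax_i <- truth$Bmax[i]; beta_i <- truth$beta[i]
    for (r in seq_len(cfg$n_rates)) {
      N_ach <- cfg$n_quantiles[r] * Nc_i
      W_exp <- linear_plus_plateau(N_ach, Bmax_i, beta_i, Nc_i)
      if (W_exp <= 0)
        stop("degenerate design: expected biomass non-positive at date ", i,
             ", treatment ", r, call. = FALSE)
      d <- d + 1L
      design[[d]] <- data.frame(date_index = i, treatment_id = paste0("N", r),
                                n_rate = rates[r], achieved_n = N_ach,
                                expected_w = W_exp)
      for (rep_j in seq_len(cfg$replicates)) {
        noise <- if (truth$sigma_frac > 0)
          rnorm(1, 0, truth$sigma_frac * Bmax_i) else 0
        shoot_W <- max(W_exp + noise, 1e-3)
        leaf_W <- lf[i] * shoot_W
        stem_W <- shoot_W - leaf_W
        leaf_N <- N_ach + cfg$leaf_n_offset
        stem_N <- max((N_ach - lf[i] * leaf_N) / (1 - lf[i]), 0.05)
        lai <- leaf_W * cfg$sla
        base <- data.frame(
          experiment_id = cfg$experiment_id,
          date = format(dates[i], "%Y-%m-%d"),
          treatment_id = paste0("N", r),
          organ = c("leaf", "stem", "shoot"),
          biomass_t_ha = c(leaf_W, stem_W, shoot_W),
          lai = c(lai, NA, NA),
          n_conc_pct = c(leaf_N, stem_N, N_ach),
          shoot_biomass_t_ha = shoot_W,
          shoot_n_conc_pct = N_ach,
          replicate = rep_j,
          stringsAsFactors = FALSE
        )
        k <- k + 1L
        rows[[k]] <- base
      }
    }
  }
  obs <- do.call(rbind, rows)
  meta <- experiment_meta(cfg$experiment_id, cfg$site, cfg$year, cfg$genotype,
                          cfg$density_plants_m2, cfg$sowing_date, flowering,
                          rates)
  ds <- experiment_dataset(meta, obs, weather, quiet = TRUE)
  attr(truth, "design") <- do.call(rbind, design)
  list(dataset = ds, truth = truth)
}

#' Simulate a suite of G x E x M experiments
#'
#' Each experiment draws its own sub-seed from the master seed keyed by its
#' id, so the output of one experiment never depends on which others are in
#' the list or on their order.
#'
#' @param truths list of [truth_record()]s.
#' @param cfgs list of [sim_config()]s of the same length, with distinct
#'   `experiment_id`s.
#' @param master_seed integer master seed overriding each config's own seed
#'   via [derive_seed()]; `NULL` keeps the configs' seeds.
#' @return named list (by experiment id) of `list(dataset, truth)`; the
#'   simulation manifest (ids, seeds, truths) is in `attr(, "manifest")`.
#' @export
simulate_gem_suite <- function(truths, cfgs, master_seed = NULL) {
  stopifnot(length(truths) == length(cfgs), length(truths) > 0)
  ids <- vapply(cfgs, function(c) c$experiment_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate experiment_id in simulation configs", call. = FALSE)
  out <- vector("list", length(cfgs))
  for (j in seq_along(cfgs)) {
    cfg <- cfgs[[j]]
    if (!is.null(master_seed))
      cfg$seed <- derive_seed(master_seed, cfg$experiment_id)
    out[[j]] <- simulate_experiment(truths[[j]], cfg)
  }
  names(out) <- ids
  manifest <- data.frame(
    experiment_id = ids,
    seed = vapply(seq_along(cfgs), function(j) {
      if (is.null(master_seed)) cfgs[[j]]$seed
      else derive_seed(master_seed, ids[j])
    }, numeric(1)),
    A1_true = vapply(truths, function(t) t$A1, numeric(1)),
    A2_true = vapply(truths, function(t) t$A2, numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "manifest") <- manifest
  out
}

#' Default 14-condition G x E x M design
#'
#' A ready-made suite emulating a multi-site wheat programme: 14 conditions
#' across 5 sites and 5 genotypes with varying sowing density, season length,
#' sampling intensity (5-8 dates) and N ladders (one sparse 3-rate trial, one
#' dense 13-treatment trial), with true curve intercepts spanning A1 in
#' \[2.8, 4.6\] and exponents A2 in \[0.25, 0.45\].
#'
#' @param n_experiments number of conditions (default 14).
#' @param master_seed seed for drawing the condition-level truths.
#' @param sigma_frac observation noise fraction passed to every truth.
#' @return list with elements `truths` and `cfgs`, ready for
#'   [simulate_gem_suite()].
#' @export
default_gem_design <- function(n_experiments = 14, master_seed = 20120901,
                               sigma_frac = 0.05) {
  set.seed(derive_seed(master_seed, "gem-design"))
  sites <- c("Yizheng", "Rugao", "Xinxiang", "Xuzhou", "Sihong")
  genotypes <- c("JM22", "XM30", "NM13", "AK58", "YM16")
  truths <- vector("list", n_experiments)
  cfgs <- vector("list", n_experiments)
  for (j in seq_len(n_experiments)) {
    A1 <- runif(1, 2.8, 4.6)
    A2 <- runif(1, 0.25, 0.45)
    n_dates <- if (j == 2) 7L else sample(5:8, 1)
    n_rates <- if (j == 2) 13L else if (j == 5) 3L else sample(5:6, 1)
    density <- round(runif(1, 150, 330))
    to <- runif(1, 9, 13)
    # keep the deepest deficit (0.6 x Nc at the first, N-richest date) above
    # zero biomass: beta * 0.4 * Nc_1 < 1
    nc1 <- A1 * 1.5^(-A2)
    beta_hi <- min(0.8, 0.85 / (0.4 * nc1))
    truths[[j]] <- truth_record(A1, A2,
                                Bmax = default_bmax(n_dates, from = 1.5, to = to),
                                beta = runif(1, min(0.4, beta_hi * 0.7), beta_hi),
                                sigma_frac = sigma_frac)
    yr <- 2011 + (j - 1) %% 3
    cfgs[[j]] <- sim_config(
      experiment_id = sprintf("%d-%s-%s", yr, substr(sites[(j - 1) %% 5 + 1], 1, 2),
                              genotypes[(j - 1) %% 5 + 1]),
      n_dates = n_dates, n_rates = n_rates, replicates = 3,
      seed = j, site = sites[(j - 1) %% 5 + 1], year = yr,
      genotype = genotypes[(j - 1) %% 5 + 1], density_plants_m2 = density,
      sowing_date = sprintf("%d-10-%02d", yr - 1, 15 + (j %% 10)),
      season_days = round(runif(1, 170, 195))
    )
  }
  list(truths = truths, cfgs = cfgs)
}

#' Exact critical point of a noise-free date group
#'
#' On noise-free simulated data the plateau level is the maximum observed W
#' and the critical concentration is where the line through the sub-critical
#' points meets that plateau; this closed-form interpolation recovers the
#' generating `(Bmax, Nc)` exactly and serves as a construction check.
#'
#' @param W,N paired observations for one date (>= 2 points on the linear
#'   limb and >= 1 on the plateau).
#' @return list with `Bmax` and `Nc`.
#' @export
exact_critical_point <- function(W, N) {
  Bmax <- max(W)
  on_plateau <- abs(W - Bmax) < 1e-9 * max(1, Bmax)
  lin <- !on_plateau
  if (sum(lin) < 2)
    stop("need at least two points below the plateau", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, N[lin]), W[lin])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  list(Bmax = Bmax, Nc = as.numeric((Bmax - a) / b))
}
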