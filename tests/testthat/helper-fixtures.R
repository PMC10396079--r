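# Shared fixture builders. Everything is generated in code; no data files.

# A small hand-written observation table: 2 dates x 2 treatments, all organs.
tiny_obs <- function() {
  grid <- expand.grid(date = c("2013-03-01", "2013-03-20"),
                      treatment_id = c("N1", "N2"),
                      stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    shoot_w <- 2 + i; shoot_n <- 3.2 - 0.2 * i
    leaf_w <- 0.5 * shoot_w; stem_w <- shoot_w - leaf_w
    data.frame(
      experiment_id = "TINY", date = grid$date[i],
      treatment_id = grid$treatment_id[i],
      organ = c("leaf", "stem", "shoot"),
      biomass_t_ha = c(leaf_w, stem_w, shoot_w),
      lai = c(leaf_w * 2, NA, NA),
      n_conc_pct = c(shoot_n + 0.6, shoot_n - 0.6, shoot_n),
      shoot_biomass_t_ha = shoot_w, shoot_n_conc_pct = shoot_n,
      replicate = 1L, stringsAsFactors = FALSE
    )
  }))
}

tiny_meta <- function() {
  experiment_meta("TINY", "Rugao", 2013, "NM13", 225,
                  "2012-10-25", "2013-04-20", c(0, 150, 300))
}

tiny_weather <- function(n = 180, tmean = 8) {
  data.frame(date = format(seq(as.Date("2012-10-25"), by = "1 day",
                               length.out = n), "%Y-%m-%d"),
             tmax_c = tmean + 5, tmin_c = tmean - 5, rain_mm = 1.5,
             stringsAsFactors = FALSE)
}

tiny_dataset <- function(weather = NULL) {
  suppressWarnings(experiment_dataset(tiny_meta(), tiny_obs(), weather,
                                      quiet = TRUE))
}

# Standard simulated experiment used across fitting tests.
sim_standard <- function(seed = 11, n_dates = 8, n_rates = 6, replicates = 3,
                         A1 = 3.5, A2 = 0.35, sigma_frac = 0.05) {
  tr <- truth_record(A1, A2, Bmax = default_bmax(n_dates, 1.5, 12),
                     beta = 0.6, sigma_frac = sigma_frac)
  cfg <- sim_config(paste0("SIM-", seed), n_dates = n_dates,
                    n_rates = n_rates, replicates = replicates, seed = seed)
  simulate_experiment(tr, cfg)
}

# Reduced-scale MCMC arguments for tests that do not assert convergence.
fast_mcmc <- list(n_chains = 2, n_burn = 1200, n_keep = 800)

# Two-group toy model with all nuisances pinned, for oracle comparisons.
toy_fixed_spec <- function() {
  g1 <- structure(list(date_index = 1L, basis = "shoot",
                       experiment_id = "toy",
                       W = c(2.2, 3.1, 3.9, 4.0), N = c(1.8, 2.4, 3.0, 3.4)),
                  class = "nc_date_group")
  g2 <- structure(list(date_index = 2L, basis = "shoot",
                       experiment_id = "toy",
                       W = c(4.1, 6.2, 7.6, 8.0), N = c(1.2, 1.7, 2.2, 2.6)),
                  class = "nc_date_group")
  model_spec(list(g1, g2), noise = "constant",
             fixed = list(bmax = c(4.0, 8.0), beta = c(0.5, 0.5),
                          sigma = 0.4))
}

# Build a synthetic nc_posterior object directly from a draws array.
fake_posterior <- function(draws, par_names = dimnames(draws)[[3]]) {
  structure(list(draws = draws, par_names = par_names,
                 acceptance = NULL, n_burn = 0, n_keep = dim(draws)[1],
                 n_chains = dim(draws)[2], seed = NA,
                 lower = rep(-Inf, dim(draws)[3]),
                 upper = rep(Inf, dim(draws)[3])),
            class = "nc_posterior")
}

# Build a synthetic converged curve fit with given A1/A2 draws.
fake_fit <- function(id, a1_draws, a2_draws, basis = "shoot",
                     converged = TRUE) {
  n <- length(a1_draws)
  half <- n %/% 2
  draws <- array(c(a1_draws, a2_draws), dim = c(half, 2, 2),
                 dimnames = list(NULL, c("chain1", "chain2"), c("A1", "A2")))
  post <- fake_posterior(draws)
  structure(list(experiment_id = id, basis = basis, posterior = post,
                 summary = summarize_posterior(post), converged = converged,
                 diagnostics = list()),
            class = "nc_curvefit")
}
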