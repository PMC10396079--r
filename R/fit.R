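#' Specify the hierarchical dilution model for a set of date groups
#'
#' The model shares one dilution curve `Nc_i = A1 * Bmax_i^-A2` across all
#' date groups while each group keeps its own nuisance parameters: plateau
#' `Bmax_i`, linear-limb slope `beta_i`, and a common observation noise SD
#' `sigma`. Biomass W is Gaussian about the linear-plus-plateau response to
#' N concentration. All priors are uniform: A1 on \[0, 12\], A2 on \[0, 5\]
#' by default, `Bmax_i` on (0, 2 x max W in group), `beta_i` on (0, 5) and
#' `sigma` on (0, max W across groups).
#'
#' @param groups list of `nc_date_group`s (see [make_date_groups()]); each
#'   must hold at least 3 pairs.
#' @param prior_a1,prior_a2 numeric length-2 prior bounds.
#' @param prior_beta prior bounds shared by all `beta_i`.
#' @param prior_bmax optional list of per-group bounds; default
#'   `c(1e-6, 2 * max(W))` per group.
#' @param noise observation-noise model: `"proportional"` (default; SD =
#'   `sigma * Bmax_i`, so `sigma` is a relative error and measurement
#'   scatter grows with the crop — the usual behaviour of biomass
#'   sampling) or `"constant"` (SD = `sigma` in W units across all dates).
#' @param prior_sigma noise bounds; default `c(1e-4, 1)` (relative) for
#'   proportional noise, `c(1e-6, max(W))` for constant.
#' @param fixed optional named list pinning nuisance parameters for reduced
#'   models: elements `bmax`, `beta` (vectors, one per group) and/or `sigma`
#'   (scalar). Fixed parameters are excluded from sampling.
#' @return object of class `nc_model_spec` with the parameter layout
#'   (`par_names`, `lower`, `upper`) used by the sampler.
#' @export
model_spec <- function(groups, prior_a1 = c(0, 12), prior_a2 = c(0, 5),
                       prior_beta = c(0, 5), prior_bmax = NULL,
                       noise = c("proportional", "constant"),
                       prior_sigma = NULL, fixed = NULL) {
  noise <- match.arg(noise)
  stopifnot(is.list(groups), length(groups) > 0)
  for (g in groups) {
    if (!all(c("W", "N") %in% names(g)) || length(g$W) < 3)
      stop("every date group must carry >= 3 (W, N) pairs", call. = FALSE)
    if (length(g$W) != length(g$N))
      stop("group W and N lengths differ", call. = FALSE)
  }
  k <- length(groups)
  wmax <- vapply(groups, function(g) max(g$W), numeric(1))
  if (is.null(prior_bmax)) prior_bmax <- lapply(wmax, function(w) c(1e-6, 2 * w))
  if (is.null(prior_sigma))
    prior_sigma <- if (noise == "proportional") c(1e-4, 1)
    else c(1e-6, max(wmax))
  par_names <- c("A1", "A2", paste0("Bmax_", seq_len(k)),
                 paste0("beta_", seq_len(k)), "sigma")
  lower <- c(prior_a1[1], prior_a2[1],
             vapply(prior_bmax, `[`, numeric(1), 1),
             rep(prior_beta[1] + 1e-6, k), prior_sigma[1])
  upper <- c(prior_a1[2], prior_a2[2],
             vapply(prior_bmax, `[`, numeric(1), 2),
             rep(prior_beta[2], k), prior_sigma[2])
  if (!is.null(fixed)) {
    if (!is.null(fixed$bmax)) {
      stopifnot(length(fixed$bmax) == k)
      lower[2 + seq_len(k)] <- upper[2 + seq_len(k)] <- fixed$bmax
    }
    if (!is.null(fixed$beta)) {
      stopifnot(length(fixed$beta) == k)
      lower[2 + k + seq_len(k)] <- upper[2 + k + seq_len(k)] <- fixed$beta
    }
    if (!is.null(fixed$sigma))
      lower[2 * k + 3] <- upper[2 * k + 3] <- fixed$sigma
  }
  if (any(upper < lower)) stop("prior upper bound below lower bound", call. = FALSE)
  structure(
    list(groups = groups, k = k, par_names = par_names,
         lower = lower, upper = upper, fixed = fixed, noise = noise),
    class = "nc_model_spec"
  )
}

#' @export
print.nc_model_spec <- function(x, ...) {
  cat(sprintf("<nc_model_spec> %d date groups, %d observations, %d parameters\n",
              x$k, sum(vapply(x$groups, function(g) length(g$W), integer(1))),
              length(x$par_names)))
  invisible(x)
}

#' Log posterior density of the dilution model
#'
#' Reference R implementation (the sampler carries its own compiled copy):
#' flat log prior inside the support, `-Inf` outside, plus the sum over all
#' observations of the Gaussian log likelihood of W about the
#' linear-plus-plateau response.
#'
#' @param params numeric vector in the layout of `spec$par_names`:
#'   `A1, A2, Bmax_1..k, beta_1..k, sigma`.
#' @param spec an [model_spec()].
#' @return scalar log density (up to the flat-prior constant).
#' @export
log_posterior <- function(params, spec) {
  stopifnot(inherits(spec, "nc_model_spec"))
  if (length(params) != length(spec$par_names))
    stop("params must have length ", length(spec$par_names), call. = FALSE)
  if (any(params < spec$lower - 1e-12) || any(params > spec$upper + 1e-12))
    return(-Inf)
  k <- spec$k
  A1 <- params[1]; A2 <- params[2]
  bmax <- params[2 + seq_len(k)]
  beta <- params[2 + k + seq_len(k)]
  sigma <- params[2 * k + 3]
  ll <- 0
  for (i in seq_len(k)) {
    g <- spec$groups[[i]]
    mu <- linear_plus_plateau(g$N, bmax[i], beta[i], A1 * bmax[i]^(-A2))
    sd_i <- if (spec$noise == "proportional") sigma * bmax[i] else sigma
    ll <- ll + sum(dnorm(g$W, mu, sd_i, log = TRUE))
  }
  ll
}

#' Draw from the posterior by adaptive Metropolis-within-Gibbs MCMC
#'
#' Runs `n_chains` independent chains from overdispersed uniform starts, with
#' per-parameter Gaussian random-walk proposals whose scales adapt during
#' burn-in (diminishing adaptation toward 0.44 acceptance). Deterministic
#' given `seed`. The survey-scale configuration this model family was
#' published with (about 100,000 burn-in and 30,000 retained draws) is
#' available by raising `n_burn`/`n_keep`; the defaults are a test scale that
#' passes the same convergence checks on simulated trials.
#'
#' @param spec an [model_spec()].
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param n_burn burn-in iterations per chain (default 5000).
#' @param n_keep retained iterations per chain (default 3000).
#' @param seed integer RNG seed.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @return object of class `nc_posterior`: list with `draws` (array
#'   `n_keep x n_chains x n_par`), `par_names`, `acceptance`, `n_burn`,
#'   `n_keep`, `seed`.
#' @export
sample_posterior <- function(spec, n_chains = 4, n_burn = 5000,
                             n_keep = 3000, seed = 1, thin = 1) {
  stopifnot(inherits(spec, "nc_model_spec"), n_chains >= 1,
            n_burn > 0, n_keep > 0)
  set.seed(seed)
  n_par <- length(spec$par_names)
  gW <- lapply(spec$groups, `[[`, "W")
  gN <- lapply(spec$groups, `[[`, "N")
  draws <- array(NA_real_, dim = c(n_keep, n_chains, n_par),
                 dimnames = list(NULL, paste0("chain", seq_len(n_chains)),
                                 spec$par_names))
  acceptance <- matrix(NA_real_, n_chains, n_par)
  k <- spec$k
  wmax <- vapply(spec$groups, function(g) max(g$W), numeric(1))
  for (ch in seq_len(n_chains)) {
    width <- spec$upper - spec$lower
    # overdispersed but plausible starts: plateaus near the observed group
    # maxima, moderate slopes and noise, curve parameters spread over the
    # agronomically occupied part of the prior box
    init <- numeric(n_par)
    init[1] <- runif(1, 1.5, 7)
    init[2] <- runif(1, 0.05, 1.0)
    init[2 + seq_len(k)] <- wmax * runif(k, 0.9, 1.3)
    init[2 + k + seq_len(k)] <- runif(k, 0.3, 1.2)
    init[2 * k + 3] <- if (spec$noise == "proportional") runif(1, 0.02, 0.25)
    else mean(wmax) * runif(1, 0.03, 0.3)
    init <- pmin(pmax(init, spec$lower + 1e-3 * width), spec$upper - 1e-3 * width)
    init[width == 0] <- spec$lower[width == 0]
    res <- mcmc_lpp_chain(gW, gN, spec$lower, spec$upper, init,
                          as.integer(n_burn), as.integer(n_keep),
                          as.integer(thin),
                          as.integer(spec$noise == "proportional"))
    if (any(!is.finite(res$draws)))
      stop("numerical overflow in likelihood while sampling chain ", ch,
           call. = FALSE)
    draws[, ch, ] <- res$draws
    acceptance[ch, ] <- res$acceptance
  }
  structure(
    list(draws = draws, par_names = spec$par_names, acceptance = acceptance,
         n_burn = n_burn, n_keep = n_keep, n_chains = n_chains, seed = seed,
         lower = spec$lower, upper = spec$upper),
    class = "nc_posterior"
  )
}

#' @export
print.nc_posterior <- function(x, ...) {
  cat(sprintf("<nc_posterior> %d chains x %d retained draws, %d parameters\n",
              x$n_chains, x$n_keep, length(x$par_names)))
  invisible(x)
}

# Pool chains into one matrix (iterations * chains) x parameters.
pool_draws <- function(post) {
  d <- post$draws
  matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2],
         dimnames = list(NULL, post$par_names))
}

#' Split-chain Gelman-Rubin statistic
#'
#' Each chain is halved, and the classic potential-scale-reduction factor is
#' computed over the resulting half-chains, which also flags non-stationarity
#' within a chain.
#'
#' @param x matrix of draws, iterations x chains.
#' @return scalar split-R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Multi-chain effective sample size
#'
#' Autocorrelation-based ESS combining chains: per-lag autocorrelations are
#' averaged across chains, corrected for between-chain variance, and summed
#' by Geyer's initial-monotone-positive-sequence rule.
#'
#' @param x matrix of draws, iterations x chains.
#' @return scalar effective sample size.
#' @export
ess_multichain <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(n * m)
  chain_var <- apply(x, 2, var)
  W <- mean(chain_var)
  if (W <= 0) return(n * m)
  varplus <- (n - 1) / n * W + (if (m > 1) var(colMeans(x)) else 0)
  max_lag <- min(n - 2, 1000)
  acfs <- sapply(seq_len(m), function(ch)
    acf(x[, ch], lag.max = max_lag, plot = FALSE,
        demean = TRUE)$acf[-1] * chain_var[ch])
  acfs <- matrix(acfs, nrow = max_lag)
  rho <- 1 - (W - rowMeans(acfs)) / varplus
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 1
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  max(n * m / tau, 1)
}

#' Convergence verdict for a posterior
#'
#' Operationalizes the screening rule that non-convergent curve fits are
#' excluded: a fit converges iff the split-R-hat of both curve parameters is
#' below the threshold and their effective sample size reaches the floor.
#'
#' @param post an `nc_posterior`.
#' @param rhat_threshold split-R-hat threshold (default 1.1).
#' @param ess_floor minimum effective sample size (default 400).
#' @param params parameters screened (default `c("A1", "A2")`).
#' @return list with `converged` (logical), `rhat` and `ess` (named numeric).
#' @export
check_convergence <- function(post, rhat_threshold = 1.1, ess_floor = 400,
                              params = c("A1", "A2")) {
  stopifnot(inherits(post, "nc_posterior"))
  if (post$n_chains < 2)
    stop("convergence diagnostics require >= 2 chains", call. = FALSE)
  params <- intersect(params, post$par_names)
  rhat <- vapply(params, function(p) split_rhat(post$draws[, , p]), numeric(1))
  ess <- vapply(params, function(p) ess_multichain(post$draws[, , p]),
                numeric(1))
  list(converged = all(rhat < rhat_threshold) && all(ess >= ess_floor),
       rhat = rhat, ess = ess,
       rhat_threshold = rhat_threshold, ess_floor = ess_floor)
}

#' Posterior summary table
#'
#' Median, central 95% credible interval and coefficient of variation
#' (CV = SD / mean x 100%) per parameter over the pooled chains.
#'
#' @param post an `nc_posterior`.
#' @return data.frame with columns `parameter, median, q2.5, q97.5, mean, sd,
#'   cv_pct`.
#' @export
summarize_posterior <- function(post) {
  stopifnot(inherits(post, "nc_posterior"))
  pooled <- pool_draws(post)
  qs <- t(apply(pooled, 2, quantile, probs = c(0.025, 0.5, 0.975),
                names = FALSE, type = 7))
  data.frame(
    parameter = post$par_names,
    median = qs[, 2], q2.5 = qs[, 1], q97.5 = qs[, 3],
    mean = colMeans(pooled), sd = apply(pooled, 2, sd),
    cv_pct = cv_percent_vec(pooled),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

cv_percent_vec <- function(m) apply(m, 2, function(x) sd(x) / mean(x) * 100)

#' Fit one organ-specific dilution curve
#'
#' High-level wrapper: builds the date groups for a basis, specifies the
#' hierarchical model, samples, screens convergence and summarizes. A fit
#' that fails the convergence screen is returned with `converged = FALSE`
#' and is excluded from all downstream comparisons.
#'
#' @param ds an `nc_experiment` (already low-biomass filtered) or a
#'   pre-built list of date groups.
#' @param basis organ basis, one of `"leaf"`, `"stem"`, `"shoot"`, `"lai"`.
#' @param experiment_id label for the fit; defaults to the dataset's id.
#' @param ... passed to [sample_posterior()] (`n_chains`, `n_burn`,
#'   `n_keep`, `seed`, ...).
#' @param spec_args optional list of arguments forwarded to [model_spec()].
#' @return object of class `nc_curvefit`: list with `experiment_id`,
#'   `basis`, `posterior`, `summary`, `converged`, `diagnostics`.
#' @export
fit_dilution_curve <- function(ds, basis, experiment_id = NULL, ...,
                               spec_args = list()) {
  groups <- if (inherits(ds, "nc_experiment")) make_date_groups(ds, basis)
  else ds
  if (is.null(experiment_id)) {
    experiment_id <- if (inherits(ds, "nc_experiment")) ds$meta$experiment_id
    else groups[[1]]$experiment_id %||% "fit"
  }
  spec <- do.call(model_spec, c(list(groups = groups), spec_args))
  post <- sample_posterior(spec, ...)
  diag <- check_convergence(post)
  structure(
    list(experiment_id = experiment_id, basis = basis, posterior = post,
         summary = summarize_posterior(post), converged = diag$converged,
         diagnostics = diag),
    class = "nc_curvefit"
  )
}

#' @export
print.nc_curvefit <- function(x, ...) {
  s <- x$summary
  a1 <- s[s$parameter == "A1", ]; a2 <- s[s$parameter == "A2", ]
  cat(sprintf(paste0("<nc_curvefit> %s / %s basis: A1 = %.3f [%.3f, %.3f], ",
                     "A2 = %.3f [%.3f, %.3f], %sconverged\n"),
              x$experiment_id, x$basis, a1$median, a1$q2.5, a1$q97.5,
              a2$median, a2$q2.5, a2$q97.5,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Brute-force grid posterior over (A1, A2) with fixed nuisances
#'
#' Independent oracle for the sampler: with every `Bmax_i`, `beta_i` and
#' `sigma` pinned, the posterior over the two curve parameters is evaluated
#' on a regular grid covering the prior box and normalized by summation;
#' marginal medians and central 95% intervals come from the interpolated
#' discrete CDF.
#'
#' @param spec an [model_spec()] whose `fixed` pins `bmax`, `beta` and
#'   `sigma` (see [model_spec()]).
#' @param n_grid grid resolution per axis (default 201).
#' @return list with `a1`, `a2` (grid midpoints), `posterior` (normalized
#'   matrix, a1 x a2), `marg_a1`, `marg_a2`, and `summary` (data.frame of
#'   median and 95% interval per parameter).
#' @export
grid_posterior_oracle <- function(spec, n_grid = 201) {
  stopifnot(inherits(spec, "nc_model_spec"))
  k <- spec$k
  fixed_idx <- 2 + seq_len(2 * k + 1)
  if (any(spec$upper[fixed_idx] != spec$lower[fixed_idx]))
    stop("grid oracle requires all nuisance parameters fixed ",
         "(model_spec(fixed = list(bmax=, beta=, sigma=)))", call. = FALSE)
  bmax <- spec$lower[2 + seq_len(k)]
  beta <- spec$lower[2 + k + seq_len(k)]
  sigma <- spec$lower[2 * k + 3]
  a1 <- seq(spec$lower[1], spec$upper[1], length.out = n_grid + 1)
  a1 <- (a1[-1] + a1[-length(a1)]) / 2  # cell midpoints
  a2 <- seq(spec$lower[2], spec$upper[2], length.out = n_grid + 1)
  a2 <- (a2[-1] + a2[-length(a2)]) / 2
  ll <- matrix(0, n_grid, n_grid)
  for (i in seq_len(k)) {
    g <- spec$groups[[i]]
    sd_i <- if (spec$noise == "proportional") sigma * bmax[i] else sigma
    nc_grid <- outer(a1, bmax[i]^(-a2))  # a1 rows x a2 columns
    for (j in seq_along(g$W)) {
      mu <- ifelse(g$N[j] < nc_grid,
                   pmax(bmax[i] * (1 - beta[i] * (nc_grid - g$N[j])), 0),
                   bmax[i])
      ll <- ll + dnorm(g$W[j], mu, sd_i, log = TRUE)
    }
  }
  ll <- ll - max(ll)
  post <- exp(ll)
  post <- post / sum(post)
  mode_idx <- which(post == max(post), arr.ind = TRUE)[1, ]
  if (any(mode_idx == 1) || mode_idx[1] == n_grid || mode_idx[2] == n_grid)
    if (sum(vapply(spec$groups, function(g) length(g$W), integer(1))) > 0 &&
        max(post) > 10 / (n_grid^2))
      warning("posterior mode on a boundary grid cell; increase n_grid or ",
              "check the priors", call. = FALSE)
  marg_a1 <- rowSums(post)
  marg_a2 <- colSums(post)
  summ <- rbind(grid_quantiles(a1, marg_a1), grid_quantiles(a2, marg_a2))
  summ <- data.frame(parameter = c("A1", "A2"), summ,
                     row.names = NULL, stringsAsFactors = FALSE)
  list(a1 = a1, a2 = a2, posterior = post, marg_a1 = marg_a1,
       marg_a2 = marg_a2, summary = summ)
}

# Quantiles of a discrete marginal by linear interpolation of the CDF at
# cell midpoints (half the cell's mass lies left of its midpoint).
grid_quantiles <- function(x, w, probs = c(0.025, 0.5, 0.975)) {
  cdf <- (cumsum(w) - w / 2) / sum(w)
  q <- vapply(probs, function(p) {
    j <- which(cdf >= p)[1]
    if (j == 1) return(x[1])
    x[j - 1] + (x[j] - x[j - 1]) * (p - cdf[j - 1]) / (cdf[j] - cdf[j - 1])
  }, numeric(1))
  data.frame(q2.5 = q[1], median = q[2], q97.5 = q[3])
}
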