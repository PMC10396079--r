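test_that("log posterior is -Inf outside the prior box", {
  spec <- model_spec(make_date_groups(
    filter_low_biomass(sim_standard(seed = 2, n_dates = 5)$dataset,
                       quiet = TRUE), "shoot"))
  k <- spec$k
  inside <- c(3.5, 0.35, vapply(spec$groups, function(g) max(g$W), 1),
              rep(0.6, k), 0.4)
  expect_true(is.finite(log_posterior(inside, spec)))
  a1_out <- inside; a1_out[1] <- 13
  expect_identical(log_posterior(a1_out, spec), -Inf)
  a2_out <- inside; a2_out[2] <- 5.5
  expect_identical(log_posterior(a2_out, spec), -Inf)
  expect_error(log_posterior(inside[-1], spec), "length")
})

test_that("log posterior matches an independently coded direct sum", {
  g1 <- structure(list(date_index = 1L, basis = "shoot", experiment_id = "t",
                       W = c(2.1, 2.9, 3.2), N = c(1.9, 2.6, 3.1)),
                  class = "nc_date_group")
  spec <- model_spec(list(g1), noise = "constant")
  # independent oracle: plain arithmetic, no package helpers
  oracle <- function(p) {
    A1 <- p[1]; A2 <- p[2]; Bmax <- p[3]; beta <- p[4]; sigma <- p[5]
    nc <- A1 * Bmax^(-A2)
    ll <- 0
    for (j in 1:3) {
      mu <- if (g1$N[j] < nc) max(Bmax * (1 - beta * (nc - g1$N[j])), 0)
      else Bmax
      ll <- ll + (-0.5 * log(2 * pi) - log(sigma) -
                    (g1$W[j] - mu)^2 / (2 * sigma^2))
    }
    ll
  }
  p_a <- c(3.2, 0.3, 3.3, 0.7, 0.3)
  p_b <- c(2.7, 0.1, 3.0, 0.4, 0.5)
  expect_equal(log_posterior(p_a, spec) - log_posterior(p_b, spec),
               oracle(p_a) - oracle(p_b), tolerance = 1e-10)
  # a single observation exactly on the plateau: pure Gaussian density at 0
  g_one <- structure(list(date_index = 1L, basis = "shoot",
                          experiment_id = "t", W = c(4, 4, 4), N = c(5, 5, 5)),
                     class = "nc_date_group")
  spec1 <- model_spec(list(g_one), noise = "constant")
  p <- c(3, 0.2, 4, 0.5, 0.7)
  expect_equal(log_posterior(p, spec1), 3 * dnorm(0, 0, 0.7, log = TRUE),
               tolerance = 1e-12)
})

test_that("sampling is deterministic given a seed and respects the prior box", {
  spec <- toy_fixed_spec()
  p1 <- do.call(sample_posterior, c(list(spec = spec, seed = 3), fast_mcmc))
  p2 <- do.call(sample_posterior, c(list(spec = spec, seed = 3), fast_mcmc))
  expect_identical(p1$draws, p2$draws)
  p3 <- do.call(sample_posterior, c(list(spec = spec, seed = 4), fast_mcmc))
  expect_false(identical(p1$draws, p3$draws))
  expect_true(all(p1$draws[, , "A1"] >= 0 & p1$draws[, , "A1"] <= 12))
  expect_true(all(p1$draws[, , "A2"] >= 0 & p1$draws[, , "A2"] <= 5))
  # fixed nuisances never move
  expect_true(all(p1$draws[, , "sigma"] == 0.4))
  expect_true(all(p1$draws[, , "Bmax_1"] == 4.0))
})

test_that("posterior summaries match an independent quantile oracle", {
  set.seed(8)
  draws <- array(rnorm(4000 * 2 * 2, mean = c(3, 0.4), sd = 0.3),
                 dim = c(4000, 2, 2),
                 dimnames = list(NULL, NULL, c("A1", "A2")))
  post <- fake_posterior(draws)
  s <- summarize_posterior(post)
  # oracle: manual type-7 quantile on the pooled sorted vector
  q7 <- function(x, p) {
    x <- sort(x); n <- length(x); h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  pooled_a1 <- as.vector(draws[, , "A1"])
  expect_equal(s$median[s$parameter == "A1"], q7(pooled_a1, 0.5),
               tolerance = 1e-9)
  expect_equal(s$q2.5[s$parameter == "A1"], q7(pooled_a1, 0.025),
               tolerance = 1e-9)
  expect_equal(s$q97.5[s$parameter == "A1"], q7(pooled_a1, 0.975),
               tolerance = 1e-9)
  expect_equal(s$cv_pct[s$parameter == "A1"],
               sd(pooled_a1) / mean(pooled_a1) * 100, tolerance = 1e-12)
  # degenerate point mass
  d0 <- array(2.5, dim = c(100, 2, 1), dimnames = list(NULL, NULL, "A1"))
  s0 <- summarize_posterior(fake_posterior(d0))
  expect_equal(unlist(s0[1, c("median", "q2.5", "q97.5", "cv_pct")]),
               c(median = 2.5, q2.5 = 2.5, q97.5 = 2.5, cv_pct = 0))
  # simple quantile definition check
  d4 <- array(rep(c(1, 2, 3, 4), 2), dim = c(4, 2, 1),
              dimnames = list(NULL, NULL, "A1"))
  expect_equal(summarize_posterior(fake_posterior(d4))$median, 2.5)
})

test_that("convergence screening separates mixed from offset chains", {
  set.seed(5)
  good <- array(rnorm(2000 * 2 * 2), dim = c(2000, 2, 2),
                dimnames = list(NULL, NULL, c("A1", "A2")))
  verdict <- check_convergence(fake_posterior(good))
  expect_true(verdict$converged)
  expect_lt(max(verdict$rhat), 1.05)
  bad <- good
  bad[, 2, ] <- bad[, 2, ] + 10  # one chain offset by a large constant
  verdict_bad <- check_convergence(fake_posterior(bad))
  expect_false(verdict_bad$converged)
  expect_gt(max(verdict_bad$rhat), 2)
  # single chain refused
  one <- good[, 1, , drop = FALSE]
  expect_error(check_convergence(fake_posterior(one)), "2 chains")
})

test_that("ESS estimator tracks known autocorrelation structure", {
  set.seed(10)
  n <- 4000; m <- 4
  white <- matrix(rnorm(n * m), n, m)
  expect_equal(ess_multichain(white), n * m, tolerance = 0.25)
  rho <- 0.9
  ar1 <- sapply(1:m, function(j)
    as.numeric(stats::filter(rnorm(n), rho, "recursive")))
  theory <- n * m * (1 - rho) / (1 + rho)
  expect_equal(ess_multichain(ar1), theory, tolerance = 0.35)
  # cross-check against coda on the same chains
  coda_ess <- sum(coda::effectiveSize(
    coda::mcmc.list(lapply(seq_len(m), function(j) coda::mcmc(ar1[, j])))))
  expect_equal(ess_multichain(ar1), coda_ess, tolerance = 0.35)
})

test_that("a low-noise recovery fit converges and brackets the truth", {
  sim <- sim_standard(seed = 31, sigma_frac = 0.02)
  ds <- filter_low_biomass(sim$dataset, quiet = TRUE)
  fit <- fit_dilution_curve(ds, "shoot", seed = 101)
  expect_true(fit$converged)
  s <- fit$summary
  expect_lt(abs(s$median[s$parameter == "A1"] - 3.5) / 3.5, 0.1)
  expect_lt(abs(s$median[s$parameter == "A2"] - 0.35) / 0.35, 0.25)
  expect_true(s$q2.5[s$parameter == "A1"] < 3.5 &&
                3.5 < s$q97.5[s$parameter == "A1"])
})
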