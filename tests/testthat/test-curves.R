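test_that("curve evaluation matches the power law and its limits", {
  leaf_pub <- nc_curve(3.06, 0.15, "leaf", "published-constant")
  expect_equal(nc_value(leaf_pub, 1), 3.06)
  # high-precision independent evaluation at W = 8
  expect_equal(nc_value(leaf_pub, 8), 3.06 * exp(-0.15 * log(8)),
               tolerance = 1e-12)
  expect_equal(round(nc_value(leaf_pub, 8), 3), 2.240)
  flat <- nc_curve(2.7, 0, "shoot")
  expect_equal(nc_value(flat, c(0.5, 1, 50)), rep(2.7, 3))
  expect_error(nc_value(leaf_pub, 0), "positive")
  expect_error(nc_value(leaf_pub, -2), "positive")
})

test_that("the curve is monotone non-increasing in W", {
  w <- sort(runif(50, 0.1, 20))
  strict <- nc_curve(4, 0.4, "shoot")
  v <- nc_value(strict, w)
  expect_true(all(diff(v) < 0))
  v0 <- nc_value(nc_curve(4, 0, "shoot"), w)
  expect_true(all(diff(v0) == 0))
})

test_that("credible band reproduces the A1 interval at W = 1 and shrinks with W", {
  sim <- sim_standard(seed = 17)
  ds <- filter_low_biomass(sim$dataset, quiet = TRUE)
  fit <- fit_dilution_curve(ds, "shoot", seed = 55)
  expect_true(fit$converged)
  band <- credible_band(fit, c(0.5, 1, 3, 6))
  s <- fit$summary
  at1 <- band[band$W == 1, ]
  expect_equal(at1$lower, s$q2.5[s$parameter == "A1"], tolerance = 1e-12)
  expect_equal(at1$upper, s$q97.5[s$parameter == "A1"], tolerance = 1e-12)
  expect_true(all(band$lower <= band$median & band$median <= band$upper))
  # uncertainty is widest at low biomass
  expect_gt(band$width[band$W == 0.5], band$width[band$W == 3])
  # refusal on a non-converged fit
  fit_bad <- fit
  fit_bad$converged <- FALSE
  expect_error(credible_band(fit_bad, 1:3), "non-converged")
  # degenerate single-draw posterior has zero width
  d0 <- array(c(3, 3, 0.3, 0.3), dim = c(1, 2, 2),
              dimnames = list(NULL, NULL, c("A1", "A2")))
  fit0 <- fake_fit("pt", rep(3, 4), rep(0.3, 4))
  band0 <- credible_band(fit0, c(1, 5))
  expect_equal(band0$width, c(0, 0))
})

test_that("pooling a single experiment equals the specific fit", {
  sim <- sim_standard(seed = 23, n_dates = 5)
  ds <- filter_low_biomass(sim$dataset, quiet = TRUE)
  args <- c(list(seed = 5), fast_mcmc)
  f_spec <- do.call(fit_dilution_curve, c(list(ds, "shoot"), args))
  f_hyb <- do.call(fit_hybrid, c(list(ds, "shoot"), args))
  expect_identical(f_spec$posterior$draws, f_hyb$posterior$draws)
})

test_that("hybrid fit interpolates between two discordant conditions", {
  truths <- lapply(c(3.0, 4.5), function(a1)
    truth_record(a1, 0.35, default_bmax(6, 1.5, 10), 0.6, 0.05))
  cfgs <- lapply(1:2, function(j) sim_config(paste0("H", j), n_dates = 6))
  suite <- simulate_gem_suite(truths, cfgs, master_seed = 41)
  dss <- lapply(suite, function(s) filter_low_biomass(s$dataset, quiet = TRUE))
  f1 <- fit_dilution_curve(dss[[1]], "shoot", seed = 61)
  f2 <- fit_dilution_curve(dss[[2]], "shoot", seed = 62)
  fh <- fit_hybrid(dss, "shoot", seed = 63)
  m <- function(f) f$summary$median[f$summary$parameter == "A1"]
  expect_gt(m(fh), min(m(f1), m(f2)))
  expect_lt(m(fh), max(m(f1), m(f2)))
})

test_that("parameter comparison separates disjoint posteriors and groups identical ones", {
  set.seed(3)
  base_a1 <- runif(4000, 2, 2.5); base_a2 <- runif(4000, 0.3, 0.35)
  f_a <- fake_fit("A", base_a1, base_a2)
  f_b <- fake_fit("B", base_a1, base_a2)          # identical draw set
  f_c <- fake_fit("C", base_a1 + 2, base_a2)      # disjoint A1 support
  cmp <- compare_parameters(list(f_a, f_b, f_c))
  lt <- cmp$letters
  a1 <- lt[lt$parameter == "A1", ]
  expect_identical(a1$letters[a1$fit_id == "A"], a1$letters[a1$fit_id == "B"])
  expect_false(a1$letters[a1$fit_id == "C"] %in%
                 a1$letters[a1$fit_id == "A"])
  pw <- cmp$pairwise
  ab <- pw[pw$parameter == "A1" & pw$fit_a == "A" & pw$fit_b == "B", ]
  expect_false(ab$different)
  expect_true(ab$diff_lower <= 0 && ab$diff_upper >= 0)
  # grouping invariant to input order
  cmp_rev <- compare_parameters(list(f_c, f_b, f_a))
  expect_identical(cmp$letters, cmp_rev$letters)
})

test_that("non-converged fits are excluded and too few fits error", {
  set.seed(4)
  f_a <- fake_fit("A", rnorm(2000, 3, 0.1), rnorm(2000, 0.3, 0.02))
  f_bad <- fake_fit("B", rnorm(2000, 3, 0.1), rnorm(2000, 0.3, 0.02),
                    converged = FALSE)
  expect_error(suppressMessages(compare_parameters(list(f_a, f_bad))),
               ">= 2 converged")
})

test_that("the CV of medians matches the closed-form definition", {
  set.seed(9)
  meds <- seq(2.8, 4.6, length.out = 14)
  fits <- lapply(seq_along(meds), function(j)
    fake_fit(sprintf("F%02d", j), rnorm(2000, meds[j], 1e-6),
             rnorm(2000, 0.3, 1e-6)))
  cmp <- compare_parameters(fits)
  a1_meds <- cmp$letters$median[cmp$letters$parameter == "A1"]
  expect_equal(cmp$cv[["A1"]], sd(a1_meds) / mean(a1_meds) * 100,
               tolerance = 1e-9)
  x <- c(1.2, 5.3, 2.2, 9.9)
  expect_equal(cv_percent(x), sd(x) / mean(x) * 100, tolerance = 1e-12)
})

test_that("the published-curve registry loads with the leaf reference", {
  reg <- published_curves()
  leaf <- reg[reg$basis == "leaf", ]
  expect_equal(leaf$A1[1], 3.06)
  expect_equal(leaf$A2[1], 0.15)
})
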