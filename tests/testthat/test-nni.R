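test_that("NNI is the ratio of measured to critical N", {
  expect_equal(compute_nni(2.0, 2.0), 1.0)
  expect_equal(compute_nni(1.5, 3.0), 0.5)
  expect_error(compute_nni(2.0, 0), "Nc")
  expect_error(compute_nni(-1, 2), "Nt")
})

test_that("NNI series covers every observation of the basis", {
  sim <- sim_standard(seed = 19, n_dates = 6)
  ds <- filter_low_biomass(sim$dataset, quiet = TRUE)
  curve <- nc_curve(3.5, 0.35, "shoot", "truth")
  nni <- nni_series(ds, curve, "shoot")
  expect_equal(nrow(nni), sum(ds$observations$organ == "shoot"))
  expect_true(all(nni$NNI > 0))
  # basis mismatch refused
  expect_error(nni_series(ds, curve, "leaf"), "does not match")
})

test_that("flat curve with Nt = A1 gives NNI = 1 everywhere", {
  ds <- tiny_dataset()
  curve <- nc_curve(3.0, 0, "shoot")
  o <- ds$observations
  o$n_conc_pct[o$organ == "shoot"] <- 3.0
  ds$observations <- o
  nni <- nni_series(ds, curve, "shoot")
  expect_equal(nni$NNI, rep(1, nrow(nni)))
})

test_that("truth-curve NNI classifies deficient and luxury treatments on noise-free data", {
  sim <- sim_standard(seed = 29, n_dates = 5, sigma_frac = 0)
  ds <- sim$dataset  # unfiltered: keep all dates
  curve <- nc_curve(sim$truth$A1, sim$truth$A2, "shoot", "truth")
  nni <- nni_series(ds, curve, "shoot")
  q <- c(0.6, 0.8, 0.95, 1.05, 1.2, 1.4)[as.integer(sub("N", "",
                                                        nni$treatment_id))]
  # on the plateau W = Bmax so Nc(W) is the date's critical value exactly
  expect_true(all(nni$NNI[q > 1] > 1))
  # deficient treatments have W < Bmax hence Nc(W) > Nc_i, driving NNI < 1
  expect_true(all(nni$NNI[q < 1] < 1))
})

test_that("weighted mean NNI interpolates its organ components", {
  expect_equal(weighted_mean_nni(0.9, 0.6, 2, 4), 0.7)
  expect_equal(weighted_mean_nni(0.8, 0.6, 3, 3), 0.7)  # equal weights
  expect_equal(weighted_mean_nni(0.9, 0.6, 2, 0), 0.9)  # degenerate weight
  expect_error(weighted_mean_nni(0.9, 0.6, 0, 0), "positive sum")
  for (i in 1:20) {
    nl <- runif(1, 0.4, 1.4); ns <- runif(1, 0.4, 1.4)
    wl <- runif(1, 0.1, 5); ws <- runif(1, 0.1, 5)
    wm <- weighted_mean_nni(nl, ns, wl, ws)
    expect_gte(wm, min(nl, ns)); expect_lte(wm, max(nl, ns))
  }
})

test_that("agreement statistics match hand arithmetic and scale correctly", {
  ag0 <- agreement(c(1, 1, 1), c(1, 1, 1))
  expect_equal(ag0$rmse, 0); expect_equal(ag0$nrmse_pct, 0)
  ag <- agreement(c(3, 4), c(0, 0))
  expect_equal(ag$rmse, sqrt(12.5), tolerance = 1e-12)
  expect_equal(ag$nrmse_pct, sqrt(12.5) / 3.5 * 100, tolerance = 1e-12)
  expect_equal(round(ag$nrmse_pct, 1), 101.0)
  # homogeneity: scaling both series scales RMSE, leaves n-RMSE unchanged
  O <- runif(10, 0.5, 1.5); P <- runif(10, 0.5, 1.5)
  a1 <- agreement(O, P); a2 <- agreement(3 * O, 3 * P)
  expect_equal(a2$rmse, 3 * a1$rmse, tolerance = 1e-12)
  expect_equal(a2$nrmse_pct, a1$nrmse_pct, tolerance = 1e-12)
  # RMSE symmetric, n-RMSE not (reference-mean normalization)
  a_sw <- agreement(P, O)
  expect_equal(a_sw$rmse, a1$rmse, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a_sw$nrmse_pct, a1$nrmse_pct)))
  expect_error(agreement(1:3, 1:4), "equal length")
  expect_error(agreement(c(-1, 1), c(1, 1)), "zero")
})

test_that("basis crosswalk pairs observations and ranks weighted mean closest to shoot", {
  sim <- sim_standard(seed = 37, n_dates = 6)
  ds <- filter_low_biomass(sim$dataset, quiet = TRUE)
  tr <- sim$truth
  # truth-derived curves: exact for shoot; organ bases use their own scale
  curves <- list(
    shoot = nc_curve(tr$A1, tr$A2, "shoot", "truth"),
    leaf = nc_curve(tr$A1 + 0.8, tr$A2 * 0.8, "leaf", "truth"),
    stem = nc_curve(tr$A1 * 0.55, tr$A2 * 1.1, "stem", "truth"),
    lai = nc_curve(tr$A1 + 0.3, tr$A2, "lai", "truth")
  )
  cw <- basis_crosswalk(ds, curves)
  expect_equal(nrow(cw$pairs), sum(ds$observations$organ == "shoot"))
  st <- cw$stats
  expect_setequal(st$comparison, c("leaf_vs_shoot", "stem_vs_shoot",
                                   "lai_vs_shoot", "weighted_vs_shoot"))
  wm <- st$nrmse_pct[st$comparison == "weighted_vs_shoot"]
  expect_lt(wm, st$nrmse_pct[st$comparison == "stem_vs_shoot"])
  # identical observations and curves agree exactly
  same <- basis_crosswalk(ds, list(
    shoot = curves$shoot,
    leaf = nc_curve(tr$A1, tr$A2, "leaf", "truth"),
    stem = nc_curve(tr$A1, tr$A2, "stem", "truth")))
  expect_true(all(same$stats$rmse >= 0))
})

test_that("crosswalk drops unmatched observations with a warning", {
  sim <- sim_standard(seed = 43, n_dates = 5, replicates = 1)
  ds <- filter_low_biomass(sim$dataset, quiet = TRUE)
  o <- ds$observations
  drop_key <- o$organ == "leaf" & o$treatment_id == "N3"
  n_dropped <- sum(o$organ == "shoot" & o$treatment_id == "N3")
  ds$observations <- o[!drop_key, ]
  curves <- list(shoot = nc_curve(3.5, 0.35, "shoot"),
                 leaf = nc_curve(4.3, 0.28, "leaf"),
                 stem = nc_curve(1.9, 0.4, "stem"))
  expect_warning(cw <- basis_crosswalk(ds, curves), "unmatched")
  expect_equal(nrow(cw$pairs),
               sum(ds$observations$organ == "shoot") - n_dropped)
})
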