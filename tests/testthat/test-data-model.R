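test_that("loading a well-formed CSV preserves every row and numeric field", {
  dir <- withr::local_tempdir()
  ds0 <- tiny_dataset(weather = tiny_weather())
  paths <- write_experiment(ds0, dir)
  ds <- suppressWarnings(load_experiment(paths["observations"],
                                         paths["metadata"],
                                         paths["weather"], quiet = TRUE))
  expect_equal(nrow(ds$observations), 12)
  expect_identical(ds$observations$biomass_t_ha, ds0$observations$biomass_t_ha)
  expect_identical(ds$observations$n_conc_pct, ds0$observations$n_conc_pct)
  expect_identical(ds$meta$n_rates_kg_ha, ds0$meta$n_rates_kg_ha)
  # write -> load -> write is byte-stable (bit-exact round trip)
  dir2 <- withr::local_tempdir()
  paths2 <- write_experiment(ds, dir2)
  expect_identical(readLines(paths2["observations"]),
                   readLines(paths["observations"]))
})

test_that("rows violating observation invariants are rejected and reported", {
  obs <- tiny_obs()
  obs$biomass_t_ha[4] <- -1
  expect_message(
    ds <- experiment_dataset(tiny_meta(), obs) |> suppressWarnings(),
    "1 observation row"
  )
  expect_equal(nrow(ds$observations), 11)
  expect_equal(nrow(attr(ds, "rejected")), 1)
})

test_that("a missing mandatory column is a schema error naming the column", {
  obs <- tiny_obs()
  obs$n_conc_pct <- NULL
  expect_error(experiment_dataset(tiny_meta(), obs), "n_conc_pct")
})

test_that("all rows invalid is an empty-dataset error", {
  obs <- tiny_obs()
  obs$n_conc_pct <- -5
  expect_error(experiment_dataset(tiny_meta(), obs), "no valid observation")
})

test_that("metadata invariants are enforced", {
  expect_error(experiment_meta("X", "s", 2013, "g", 0, "2012-10-25",
                               "2013-04-20", c(0, 150)), "density")
  expect_error(experiment_meta("X", "s", 2013, "g", 200, "2013-04-20",
                               "2012-10-25", c(0, 150)), "flowering")
  expect_error(experiment_meta("X", "s", 2013, "g", 200, "2012-10-25",
                               "2013-04-20", numeric(0)), "n_rates")
})

test_that("low-biomass filter keeps the threshold boundary and is idempotent", {
  obs <- do.call(rbind, lapply(seq_along(c(0.4, 0.8, 1.0, 2.1, 3.0)),
    function(i) {
      w <- c(0.4, 0.8, 1.0, 2.1, 3.0)[i]
      data.frame(experiment_id = "F", date = "2013-03-01",
                 treatment_id = paste0("N", i), organ = "shoot",
                 biomass_t_ha = w, lai = NA, n_conc_pct = 2.5,
                 shoot_biomass_t_ha = w, shoot_n_conc_pct = 2.5,
                 replicate = 1L, stringsAsFactors = FALSE)
    }))
  ds <- suppressWarnings(experiment_dataset(tiny_meta(), obs, quiet = TRUE))
  f1 <- filter_low_biomass(ds, 1.0, quiet = TRUE)
  expect_equal(sort(f1$observations$shoot_biomass_t_ha), c(1.0, 2.1, 3.0))
  f2 <- filter_low_biomass(f1, 1.0, quiet = TRUE)
  expect_identical(f2$observations, f1$observations)
  # threshold 0 is a vacuous filter
  expect_equal(nrow(filter_low_biomass(ds, 0, quiet = TRUE)$observations), 5)
  # removing everything errors
  expect_error(filter_low_biomass(ds, 10), "review the threshold")
})

test_that("date groups partition observations under the basis pairing rule", {
  sim <- sim_standard(seed = 3, n_dates = 6, n_rates = 6, replicates = 1)
  ds <- filter_low_biomass(sim$dataset, quiet = TRUE)
  n_dates_kept <- length(unique(ds$observations$date_index))
  for (b in c("leaf", "stem", "shoot")) {
    groups <- make_date_groups(ds, b)
    expect_length(groups, n_dates_kept)
    total_pairs <- sum(vapply(groups, function(g) length(g$W), integer(1)))
    expect_equal(total_pairs, sum(ds$observations$organ == b))
  }
  # LAI basis pairs LAI with the shoot N concentration of the same plot
  lai_groups <- make_date_groups(ds, "lai")
  o <- ds$observations
  leaf_rows <- o[o$organ == "leaf", ]
  for (g in lai_groups) {
    ref <- leaf_rows[leaf_rows$date_index == g$date_index, ]
    expect_setequal(g$N, ref$shoot_n_conc_pct)
    expect_setequal(g$W, ref$lai)
  }
})

test_that("date groups with fewer than 3 pairs are dropped with a warning", {
  obs <- tiny_obs()  # 2 treatments per date only
  ds <- suppressWarnings(experiment_dataset(tiny_meta(), obs, quiet = TRUE))
  expect_warning(expect_error(make_date_groups(ds, "leaf"), "no date group"),
                 "fewer than 3")
})

test_that("replicate means mode averages replicates per treatment", {
  sim <- sim_standard(seed = 5, n_dates = 5, n_rates = 6, replicates = 3)
  ds <- filter_low_biomass(sim$dataset, quiet = TRUE)
  g_rep <- make_date_groups(ds, "shoot")
  g_mean <- make_date_groups(ds, "shoot", use = "means")
  expect_equal(length(g_mean[[1]]$W) * 3, length(g_rep[[1]]$W))
})
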