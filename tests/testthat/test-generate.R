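test_that("simulated spectra have the configured grid length", {
  sp <- simulate_spectrum(spectrum_model(), severity = 1, day = 0, rng_seed = 1)
  expect_length(sp$intensities, 3438)
  expect_length(sp$wavenumbers, 3438)
  expect_true(all(diff(sp$wavenumbers) > 0))
  expect_true(all(is.finite(sp$intensities)))
})

test_that("zero-effect scenario makes storage day invisible", {
  mod <- tiny_model()
  sc <- aging_scenario(day0_effect = 0, per_day_effect = 0, response_sdlog = 0)
  d0 <- simulate_spectrum(mod, 1.5, day = 0, scenario = sc, rng_seed = 42)
  d7 <- simulate_spectrum(mod, 1.5, day = 7, scenario = sc, rng_seed = 42)
  expect_identical(d0$intensities, d7$intensities)
})

test_that("severity scales the fluorescence background but not peaks or substrate", {
  mod <- spectrum_model(n_points = 512, noise_sd = 0, gain_sdlog = 0,
                        substrate_shape = list(center = 1370, width = 450,
                                               amplitude = 0))
  sc <- aging_scenario(day0_effect = 0, per_day_effect = 0, response_sdlog = 0)
  # severity -> 0 isolates substrate + peaks; the baseline is the remainder
  sp_eps <- simulate_spectrum(mod, 1e-9, day = 0, scenario = sc, rng_seed = 3)
  sp1 <- simulate_spectrum(mod, 1, day = 0, scenario = sc, rng_seed = 3)
  sp10 <- simulate_spectrum(mod, 10, day = 0, scenario = sc, rng_seed = 3)
  baseline1 <- sp1$intensities - sp_eps$intensities
  baseline10 <- sp10$intensities - sp_eps$intensities
  expect_equal(baseline10, 10 * baseline1, tolerance = 1e-6)
  # and the baseline dominates the peak structure by more than an order of
  # magnitude for a median-severity patient
  expect_gt(max(baseline1), 10 * max(sp_eps$intensities))
})

test_that("aging magnitude is zero fresh, jumps at day 1, then drifts", {
  sc <- aging_scenario(day0_effect = 1, per_day_effect = 0.12)
  a <- aging_magnitude(0:7, sc)
  expect_identical(a[1], 0)
  expect_identical(a[2], 1)
  expect_equal(diff(a[2:8]), rep(0.12, 6))
  expect_true(all(diff(a) >= 0))
  expect_error(aging_magnitude(8, sc), "invalid-day")
})

test_that("mean spectral distance from day 0 is non-decreasing in day", {
  mod <- tiny_model(n_points = 256)
  sc <- aging_scenario(response_sdlog = 0)
  ref <- simulate_spectrum(mod, 1, 0, sc, rng_seed = 1)$intensities
  dist <- vapply(0:7, function(d) {
    sqrt(mean((simulate_spectrum(mod, 1, d, sc, rng_seed = 1)$intensities - ref)^2))
  }, numeric(1))
  expect_true(all(diff(dist) >= 0))
})

test_that("cohort simulation honors the measurement schedule", {
  coh <- simulate_cohort(tiny_model(n_points = 32),
                         cohort_schedule(330, table2_counts),
                         master_seed = 1)
  cnt <- table(coh$day)
  expect_identical(as.integer(cnt), table2_counts)
  expect_identical(sum(coh$day == 0), 330L)
  expect_identical(sum(coh$day == 5), 38L)
  expect_identical(nrow(coh), sum(table2_counts))
  # severities are constant within a sample and span a wide range
  by_sample <- tapply(coh$severity, coh$sample_id, function(s) diff(range(s)))
  expect_true(all(by_sample == 0))
  expect_gt(max(coh$severity) / min(coh$severity), 10)
})

test_that("a one-sample schedule yields one spectrum per day", {
  coh <- simulate_cohort(tiny_model(n_points = 16),
                         cohort_schedule(1, rep(1L, 8)),
                         master_seed = 2)
  expect_identical(nrow(coh), 8L)
  expect_identical(sort(coh$day), 0:7)
})

test_that("cohort simulation is byte-reproducible from the master seed", {
  mod <- spectrum_model(n_points = 48)  # noise and gain jitter active
  a <- simulate_cohort(mod, cohort_schedule(6), master_seed = 7)
  b <- simulate_cohort(mod, cohort_schedule(6), master_seed = 7)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$sample_id, b$sample_id)
  expect_identical(a$severity, b$severity)
  c <- simulate_cohort(mod, cohort_schedule(6), master_seed = 8)
  expect_false(identical(a$intensity, c$intensity))
})

test_that("generator rejects invalid inputs", {
  expect_error(simulate_spectrum(tiny_model(), severity = -1, day = 0), "domain error")
  expect_error(simulate_spectrum(tiny_model(), severity = 1, day = 9), "invalid-day")
  expect_error(cohort_schedule(10, counts_per_day = c(10L, 11L, rep(1L, 6))),
               "schedule error")
  expect_error(aging_scenario(day0_effect = -0.1), "scenario error")
  expect_error(aging_scenario(baseline_fraction = 1.2), "scenario error")
})

test_that("full-cohort generation stays fast", {
  elapsed <- system.time(
    simulate_cohort(spectrum_model(), cohort_schedule(330, table2_counts),
                    master_seed = 1)
  )[["elapsed"]]
  expect_lt(elapsed, 60)
})
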