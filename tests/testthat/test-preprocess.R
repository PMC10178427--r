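test_that("level none is the identity", {
  sp <- simulate_spectrum(spectrum_model(n_points = 300), 1, 0, rng_seed = 1)
  out <- filter_baseline(sp, filter_config("none"))
  expect_identical(out$intensities, sp$intensities)
  expect_identical(out$baseline, rep(0, 300))
})

test_that("the rigorous filter removes a pure smooth background almost entirely", {
  mod <- spectrum_model(
    n_points = 600,
    peaks = dplyr::mutate(serum_peaks(), amplitude = 0),
    substrate_shape = list(center = 1370, width = 450, amplitude = 0),
    noise_sd = 0, gain_sdlog = 0
  )
  sp <- simulate_spectrum(mod, 1, 0, aging_scenario(response_sdlog = 0), rng_seed = 1)
  res <- filter_baseline(sp, filter_config("filter2"))
  expect_lt(sum(abs(res$intensities)), 0.05 * sum(abs(sp$intensities)))
})

test_that("the weak filter preserves narrow peaks on a flat background", {
  mod <- spectrum_model(
    n_points = 600,
    baseline_shape = list(centers = c(1300, 2800), widths = c(800, 550),
                          amplitudes = c(0, 0), scale = 0, aging_weights = c(0, 0)),
    substrate_shape = list(center = 1370, width = 450, amplitude = 0),
    noise_sd = 0, gain_sdlog = 0
  )
  sp <- simulate_spectrum(mod, 1, 0, aging_scenario(response_sdlog = 0), rng_seed = 1)
  res <- filter_baseline(sp, filter_config("filter1"))
  peak_idx <- vapply(serum_peaks()$center, function(cc)
    which.min(abs(sp$wavenumbers - cc)), 1L)
  expect_equal(res$intensities[peak_idx], sp$intensities[peak_idx], tolerance = 0.1)
})

test_that("residual smooth background energy is ordered none >= filter1 >= filter2", {
  sp <- simulate_spectrum(spectrum_model(n_points = 800), 2, 3, rng_seed = 9)
  poly_energy <- function(y) {
    x <- seq_along(y) / length(y)
    sum(stats::fitted(stats::lm(y ~ stats::poly(x, 4)))^2)
  }
  e_none <- poly_energy(filter_baseline(sp, filter_config("none"))$intensities)
  e_f1 <- poly_energy(filter_baseline(sp, filter_config("filter1"))$intensities)
  e_f2 <- poly_energy(filter_baseline(sp, filter_config("filter2"))$intensities)
  expect_lte(e_f2, e_f1)
  expect_lte(e_f1, e_none)
})

test_that("the rigorous filter is idempotent within tolerance", {
  # re-filtering an already-filtered spectrum moves it by less than 1% of the
  # original spectrum's total absolute intensity
  sp <- simulate_spectrum(spectrum_model(n_points = 800), 1.5, 2, rng_seed = 4)
  once <- filter_baseline(sp, filter_config("filter2"))
  twice <- filter_baseline(once, filter_config("filter2"))
  change <- sum(abs(twice$intensities - once$intensities))
  expect_lt(change, 0.01 * sum(abs(sp$intensities)))
})

test_that("filter configuration is validated", {
  expect_error(filter_config(lambda = 0), "penalties")
  expect_error(filter_config(lambda = 1e6, lambda_weak = 1e3), "lambda_weak")
  expect_error(filter_config(asymmetry = 1), "asymmetry")
  short <- new_spectrum(1:3, c(1, 2, 3))
  expect_error(filter_baseline(short, filter_config("filter2")), "too short")
})

test_that("normalization methods behave as defined", {
  sp <- simulate_spectrum(spectrum_model(n_points = 200), 1, 0, rng_seed = 2)
  expect_identical(normalize_spectrum(sp, "none")$intensities, sp$intensities)
  expect_equal(max(normalize_spectrum(sp, "max")$intensities), 1)
  expect_equal(sum(normalize_spectrum(sp, "total_intensity")$intensities), 1,
               tolerance = 1e-9)
  zero <- new_spectrum(1:5, rep(0, 5))
  expect_error(normalize_spectrum(zero, "max"), "degenerate-input")
})

test_that("cohort filtering applies per spectrum and records settings", {
  coh <- simulate_cohort(spectrum_model(n_points = 400), cohort_schedule(2),
                         master_seed = 6)
  out <- filter_baseline(coh, filter_config("filter2"))
  expect_identical(attr(out, "filter")$level, "filter2")
  sp1 <- filter_baseline(
    new_spectrum(wavenumbers(coh), coh$intensity[[1]]), filter_config("filter2"))
  expect_equal(out$intensity[[1]], sp1$intensities, tolerance = 1e-9)
})
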