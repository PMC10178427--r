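#' Spectral model for synthetic serum spectra
#'
#' Describes the components of a simulated serum Raman spectrum on a linear
#' wavenumber grid: a broad fluorescence background (sum of two wide
#' Gaussians, scaled per patient by a severity factor), a fixed glass-substrate
#' background, Lorentzian Raman peaks at serum-plausible positions, and
#' additive Gaussian detector noise. Intensities are in arbitrary device units.
#'
#' The default fluorescence amplitude is more than an order of magnitude above
#' the peak amplitudes, reproducing the baseline dominance seen in serum
#' spectra of liver-disease cohorts, where fluorophores such as bilirubin vary
#' strongly between patients.
#'
#' @param n_points Grid length (default 3438).
#' @param wavenumber_range Two-element numeric, cm^-1 (default 250-3400).
#' @param peaks Data frame with columns `center` (cm^-1), `width` (half width
#'   at half maximum, cm^-1), `amplitude` (a.u.), and logical `aging`
#'   marking the peaks whose amplitude grows with storage time.
#' @param baseline_shape List with `centers`, `widths`, `amplitudes` of the
#'   fluorescence Gaussians and a global `scale` (a.u. at severity 1), plus
#'   `aging_weights`: per-component multiplicative sensitivity to the aging
#'   signal (the fluorophore mix shifts as the sample ages).
#' @param substrate_shape List with `center`, `width`, `amplitude` of the
#'   fixed glass background.
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.).
#' @param gain_sdlog Log-scale sd of the per-measurement multiplicative gain
#'   (droplet placement, focus and laser drift between measurement sessions);
#'   0 disables.
#' @param peak_jitter_sdlog Log-scale sd of the per-measurement, per-peak
#'   amplitude jitter (biochemical composition differences between patients
#'   and freeze-thaw handling); uncorrelated with the storage day, this is the
#'   main nuisance the classifier has to see through. 0 disables.
#' @param baseline_jitter_sdlog Log-scale sd of the per-measurement amplitude
#'   jitter of each fluorescence component: the fluorophore mix itself varies
#'   between measurements, so the background shape carries day-uncorrelated
#'   noise as well. 0 disables.
#' @return A `spectrum_model` object.
#' @examples
#' mod <- spectrum_model()
#' sp <- simulate_spectrum(mod, severity = 1, day = 0, rng_seed = 1)
#' length(sp$intensities)
#' @export
spectrum_model <- function(n_points = 3438L,
                           wavenumber_range = c(250, 3400),
                           peaks = serum_peaks(),
                           baseline_shape = list(
                             centers = c(1300, 2800),
                             widths = c(800, 550),
                             amplitudes = c(1, 0.55),
                             scale = 1200,
                             aging_weights = c(0.3, -0.12)
                           ),
                           substrate_shape = list(center = 1370, width = 450,
                                                  amplitude = 160),
                           noise_sd = 4,
                           gain_sdlog = 0.1,
                           peak_jitter_sdlog = 0.2,
                           baseline_jitter_sdlog = 0.06) {
  if (n_points < 2) stop("model error: n_points must be >= 2", call. = FALSE)
  if (any(peaks$width <= 0)) stop("model error: peak widths must be > 0", call. = FALSE)
  if (any(peaks$amplitude < 0)) stop("model error: peak amplitudes must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("model error: noise_sd must be >= 0", call. = FALSE)
  structure(
    list(
      n_points = as.integer(n_points),
      wavenumber_range = wavenumber_range,
      peaks = peaks,
      baseline_shape = baseline_shape,
      substrate_shape = substrate_shape,
      noise_sd = noise_sd,
      gain_sdlog = gain_sdlog,
      peak_jitter_sdlog = peak_jitter_sdlog,
      baseline_jitter_sdlog = baseline_jitter_sdlog
    ),
    class = "spectrum_model"
  )
}

#' Default serum Raman peak table
#'
#' Lorentzian peaks at positions typical for blood serum: tyrosine (850),
#' phenylalanine ring breathing (1004), carotenoids (1157, 1518), tryptophan /
#' CH deformation (1340), CH2 bending (1445), amide I (1655) and the CH
#' stretch region (2935). The phenylalanine, CH2 and amide-I bands carry the
#' storage-aging signal by default.
#'
#' @return A tibble with columns `center`, `width`, `amplitude`, `aging`.
#' @export
serum_peaks <- function() {
  tibble::tibble(
    center    = c(850, 1004, 1157, 1340, 1445, 1518, 1655, 2935),
    width     = c(10,    8,    9,   12,   14,    9,   16,   22),
    amplitude = c(25,   60,   35,   30,   55,   40,   50,   70),
    aging     = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  )
}

#' Storage-aging scenario
#'
#' Parameterizes the spectral change caused by pre-analytical delay. The aging
#' magnitude is `a(0) = 0`, `a(1) = day0_effect` and
#' `a(d) = day0_effect + (d - 1) * per_day_effect` for later days: the jump
#' between day 0 (stored at room temperature) and day 1 is the largest change,
#' and subsequent refrigerated days drift more slowly. `baseline_fraction`
#' splits the signal between the fluorescence background (multiplicative,
#' shifting the fluorophore mix) and the designated Raman peaks (additive
#' amplitude increase).
#'
#' @param day0_effect Effect size of the day-0 to day-1 change (>= 0).
#' @param per_day_effect Effect size per refrigerated day after day 1 (>= 0).
#' @param baseline_fraction Fraction in `[0, 1]` of the signal placed in the
#'   background rather than the peaks.
#' @param temperatures Per-day storage temperature labels in deg C
#'   (informational): room temperature after the day-0 measurement, the
#'   refrigerator afterwards.
#' @param response_sdlog Log-scale sd of the per-patient aging response
#'   multiplier: samples age at different rates, so the effect magnitude
#'   `a(d)` is scaled per patient by a log-normal factor with median 1.
#' @return An `aging_scenario` object.
#' @export
aging_scenario <- function(day0_effect = 1,
                           per_day_effect = 0.12,
                           baseline_fraction = 0.5,
                           temperatures = c(22, rep(7, 7)),
                           response_sdlog = 0.4) {
  if (day0_effect < 0 || per_day_effect < 0)
    stop("scenario error: effect sizes must be >= 0", call. = FALSE)
  if (baseline_fraction < 0 || baseline_fraction > 1)
    stop("scenario error: baseline_fraction must be in [0, 1]", call. = FALSE)
  structure(
    list(
      day0_effect = day0_effect,
      per_day_effect = per_day_effect,
      baseline_fraction = baseline_fraction,
      temperatures = temperatures,
      response_sdlog = response_sdlog
    ),
    class = "aging_scenario"
  )
}

#' Aging signal magnitude for a storage day
#'
#' @param day Integer vector of days 0-7.
#' @param scenario An [aging_scenario()].
#' @return Numeric vector `a(day)`, non-decreasing in `day`.
#' @export
aging_magnitude <- function(day, scenario) {
  if (any(day < 0 | day > 7)) stop("invalid-day error: day must be in 0..7", call. = FALSE)
  ifelse(day == 0, 0,
         scenario$day0_effect + pmax(day - 1, 0) * scenario$per_day_effect)
}

#' Measurement schedule of a simulated cohort
#'
#' How many of the `n_samples` serum samples are measured on each of days
#' 0-7, and the distribution of the per-patient fluorescence severity (a
#' log-normal, so severities span more than an order of magnitude across a
#' cohort by default). Every sample is measured fresh on day 0; on
#' under-represented days a random subset is re-measured.
#'
#' The default counts are the study schedule for a 330-sample cohort
#' (330, 330, 106, 294, 230, 38, 144, 155 for days 0-7). For a different
#' `n_samples` the counts are scaled proportionally, keeping day 0 complete.
#'
#' @param n_samples Number of simulated patients.
#' @param counts_per_day Integer vector of length 8 (days 0-7).
#' @param severity_meanlog,severity_sdlog Log-scale parameters of the
#'   severity distribution.
#' @return A `cohort_schedule` object.
#' @examples
#' cohort_schedule(330)$counts_per_day
#' @export
cohort_schedule <- function(n_samples = 330L,
                            counts_per_day = NULL,
                            severity_meanlog = 0,
                            severity_sdlog = 0.6) {
  reference <- c(330L, 330L, 106L, 294L, 230L, 38L, 144L, 155L)
  if (is.null(counts_per_day)) {
    counts_per_day <- pmax(1L, as.integer(round(n_samples * reference / 330)))
    counts_per_day[1] <- as.integer(n_samples)
  }
  counts_per_day <- as.integer(counts_per_day)
  if (length(counts_per_day) != 8)
    stop("schedule error: counts_per_day must cover days 0-7", call. = FALSE)
  if (any(counts_per_day > n_samples))
    stop("schedule error: counts_per_day may not exceed n_samples", call. = FALSE)
  if (counts_per_day[1] != n_samples)
    stop("schedule error: every sample is measured fresh, so the day-0 count must equal n_samples",
         call. = FALSE)
  structure(
    list(
      n_samples = as.integer(n_samples),
      counts_per_day = counts_per_day,
      severity_meanlog = severity_meanlog,
      severity_sdlog = severity_sdlog
    ),
    class = "cohort_schedule"
  )
}

lorentzian <- function(w, center, width) {
  1 / (1 + ((w - center) / width)^2)
}

gaussian_curve <- function(w, center, width) {
  exp(-0.5 * ((w - center) / width)^2)
}

spectrum_components <- function(model, severity, day, scenario, aging_response = 1,
                                peak_jitter = 1, baseline_jitter = 1) {
  w <- seq(model$wavenumber_range[1], model$wavenumber_range[2],
           length.out = model$n_points)
  a <- aging_magnitude(day, scenario) * aging_response
  bf <- scenario$baseline_fraction
  bs <- model$baseline_shape
  baseline <- rep(0, model$n_points)
  bjit <- rep_len(baseline_jitter, length(bs$centers))
  for (i in seq_along(bs$centers)) {
    comp <- bs$amplitudes[i] * bjit[i] * gaussian_curve(w, bs$centers[i], bs$widths[i])
    baseline <- baseline + comp * (1 + bf * a * bs$aging_weights[i])
  }
  baseline <- severity * bs$scale * baseline
  ss <- model$substrate_shape
  substrate <- ss$amplitude * gaussian_curve(w, ss$center, ss$width)
  peaks <- rep(0, model$n_points)
  jit <- rep_len(peak_jitter, nrow(model$peaks))
  for (i in seq_len(nrow(model$peaks))) {
    amp <- model$peaks$amplitude[i] * jit[i]
    if (model$peaks$aging[i]) amp <- amp + (1 - bf) * a * peak_aging_delta
    peaks <- peaks + amp * lorentzian(w, model$peaks$center[i], model$peaks$width[i])
  }
  list(wavenumbers = w, baseline = baseline, substrate = substrate, peaks = peaks)
}

# additive amplitude gained by an aging-marked peak per unit aging magnitude
peak_aging_delta <- 40

#' Simulate one serum spectrum
#'
#' Composes severity-scaled fluorescence baseline + glass substrate + Raman
#' peaks + aging perturbation + Gaussian noise. The aging perturbation of
#' magnitude `a(day)` is split by `scenario$baseline_fraction` between a
#' multiplicative change of the fluorescence components and an additive
#' increase of the aging-marked peak amplitudes.
#'
#' @param model A [spectrum_model()].
#' @param severity Positive per-patient fluorescence scale factor.
#' @param day Storage day, integer 0-7.
#' @param scenario An [aging_scenario()].
#' @param rng_seed Integer seed; the same seed reproduces the spectrum exactly.
#' @param sample_id Optional sample identifier stored in the result.
#' @param aging_response Per-patient aging-rate multiplier (default 1).
#' @return A `raman_spectrum`: list with `wavenumbers`, `intensities`,
#'   `sample_id`, `day` and a `meta` list (severity and noise draw info).
#' @export
simulate_spectrum <- function(model, severity, day, scenario = aging_scenario(),
                              rng_seed = 1L, sample_id = NA_character_,
                              aging_response = 1) {
  stopifnot(inherits(model, "spectrum_model"))
  if (!is.numeric(severity) || severity <= 0)
    stop("domain error: severity must be a positive scalar", call. = FALSE)
  if (day < 0 || day > 7) stop("invalid-day error: day must be in 0..7", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  gain <- if (model$gain_sdlog > 0) stats::rlnorm(1, 0, model$gain_sdlog) else 1
  jit <- if (model$peak_jitter_sdlog > 0)
    stats::rlnorm(nrow(model$peaks), 0, model$peak_jitter_sdlog) else 1
  bjit <- if (model$baseline_jitter_sdlog > 0)
    stats::rlnorm(length(model$baseline_shape$centers), 0, model$baseline_jitter_sdlog) else 1
  comp <- spectrum_components(model, severity, day, scenario, aging_response, jit, bjit)
  noise <- if (model$noise_sd > 0) rnorm(model$n_points, 0, model$noise_sd) else 0
  intens <- gain * (comp$baseline + comp$substrate + comp$peaks) + noise
  stopifnot(all(is.finite(intens)))
  new_spectrum(comp$wavenumbers, intens, sample_id = sample_id, day = as.integer(day),
               meta = list(severity = severity, rng_seed = rng_seed, gain = gain))
}

#' Simulate a full measurement cohort
#'
#' Draws per-patient severities from the schedule's log-normal, selects which
#' samples are re-measured on each under-represented day by a seeded random
#' subset, and simulates one spectrum per scheduled (sample, day) pair.
#' Everything is reproducible from `master_seed`: severities and day subsets
#' come from one seeded draw, and spectrum `i` (in day-major order) uses the
#' derived seed `(master_seed + 104729 * i) mod (2^31 - 1)`.
#'
#' @param model A [spectrum_model()].
#' @param schedule A [cohort_schedule()].
#' @param scenario An [aging_scenario()].
#' @param master_seed Integer seed for the whole cohort.
#' @return A `raman_cohort`: a tibble with one row per measured spectrum
#'   (`sample_id`, `day`, `severity`, list-column `intensity`), with the
#'   wavenumber grid and the generator configuration stored as attributes.
#' @examples
#' cohort <- simulate_cohort(spectrum_model(n_points = 64),
#'                           cohort_schedule(4), master_seed = 1)
#' dplyr::count(cohort, day)
#' @export
simulate_cohort <- function(model = spectrum_model(),
                            schedule = cohort_schedule(),
                            scenario = aging_scenario(),
                            master_seed = 1L) {
  stopifnot(inherits(model, "spectrum_model"), inherits(schedule, "cohort_schedule"),
            inherits(scenario, "aging_scenario"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(master_seed)
  n <- schedule$n_samples
  ids <- sprintf("S%03d", seq_len(n))
  severities <- stats::rlnorm(n, schedule$severity_meanlog, schedule$severity_sdlog)
  responses <- if (scenario$response_sdlog > 0)
    stats::rlnorm(n, 0, scenario$response_sdlog) else rep(1, n)
  plan <- purrr::map_dfr(0:7, function(d) {
    cnt <- schedule$counts_per_day[d + 1]
    if (cnt == 0) return(NULL)
    sel <- if (cnt == n) seq_len(n) else sort(sample.int(n, cnt))
    tibble::tibble(sample_idx = sel, day = d)
  })
  w <- NULL
  spectra <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    seed_i <- (master_seed + 104729 * i) %% 2147483647L
    sp <- simulate_spectrum(model, severities[plan$sample_idx[i]], plan$day[i],
                            scenario, rng_seed = seed_i,
                            sample_id = ids[plan$sample_idx[i]],
                            aging_response = responses[plan$sample_idx[i]])
    if (is.null(w)) w <- sp$wavenumbers
    spectra[[i]] <- sp$intensities
  }
  out <- tibble::tibble(
    sample_id = ids[plan$sample_idx],
    day = as.integer(plan$day),
    severity = severities[plan$sample_idx],
    aging_response = responses[plan$sample_idx],
    intensity = spectra
  )
  new_cohort(out, wavenumbers = w,
             provenance = list(master_seed = as.integer(master_seed),
                               model = model, schedule = schedule,
                               scenario = scenario))
}

new_cohort <- function(df, wavenumbers, provenance = list()) {
  structure(
    df,
    wavenumbers = wavenumbers,
    provenance = provenance,
    class = c("raman_cohort", class(tibble::tibble()))
  )
}

#' @export
print.raman_cohort <- function(x, ...) {
  cat("Raman cohort:", nrow(x), "spectra,",
      length(unique(x$sample_id)), "samples,",
      length(attr(x, "wavenumbers")), "points per spectrum\n")
  NextMethod()
}

#' Wavenumber axis of a cohort
#' @param cohort A `raman_cohort`.
#' @return Numeric vector of wavenumbers (cm^-1).
#' @export
wavenumbers <- function(cohort) attr(cohort, "wavenumbers")
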