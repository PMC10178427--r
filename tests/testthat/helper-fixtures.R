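# Small fixtures shared across tests. Everything is generated in code.

# the study's per-day measurement counts for the 330-sample cohort
table2_counts <- c(330L, 330L, 106L, 294L, 230L, 38L, 144L, 155L)

# fast spectral model: short grid, no stochastic nuisances unless asked for
tiny_model <- function(n_points = 64L, noise_sd = 0, gain_sdlog = 0) {
  spectrum_model(n_points = n_points, noise_sd = noise_sd, gain_sdlog = gain_sdlog)
}

# a cohort-shaped tibble with given per-day counts and stub spectra; enough
# for dataset construction, which only looks at `day` and `intensity`
stub_cohort <- function(counts, n_points = 4L) {
  days <- rep(0:7, counts)
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_along(days)),
    day = as.integer(days),
    severity = 1,
    intensity = replicate(length(days), stats::runif(n_points), simplify = FALSE)
  )
}

# compact network for training tests: same structure, desk-scale widths
toy_net_config <- function(n_classes = 2L, n_input = 64L) {
  model_config(n_classes = n_classes, n_input = n_input,
               kernel_sizes = c(3L, 3L), descriptors = c(4L, 8L),
               pool_sizes = c(3L, 3L), hidden_sizes = c(16L, 8L))
}
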