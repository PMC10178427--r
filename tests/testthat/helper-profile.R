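# Desk-scale experiment profile used by the heavier statistical tests and by
# scripts/acceptance.R: a 48-sample cohort with per-day counts scaled from the
# 330-sample design, and an elevated learning rate with a reduced epoch
# budget so one training run takes seconds, not hours. Documented in the
# package vignette.

profile_cohort <- function(scenario = aging_scenario(), seed = 1, n = 48) {
  simulate_cohort(spectrum_model(), cohort_schedule(n), scenario, master_seed = seed)
}

profile_train <- function(max_epochs = 100L) {
  train_config(learning_rate = 2e-3, max_epochs = max_epochs, eval_interval = 10L)
}
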