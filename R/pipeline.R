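#' Experiment configuration
#'
#' Bundles every stage of the pipeline — generator, preprocessing, dataset
#' definition and cross-validation — into one validated object. Accepts a
#' nested list (e.g. parsed from YAML via [read_run_config()]); every section
#' is checked by its module's constructor before any work starts.
#'
#' @param generator List with optional `model`, `schedule`, `scenario`
#'   sections (arguments to [spectrum_model()], [cohort_schedule()],
#'   [aging_scenario()]), or ready-made objects.
#' @param preprocess Arguments to [filter_config()].
#' @param dataset Dataset name string, e.g. `"0, rest"`.
#' @param cv List: `k`, `train_fraction`, `mode`, plus training overrides
#'   `learning_rate`, `max_epochs`, `eval_interval`, `batch_size`,
#'   `dropout_p`, `weight_decay`.
#' @param master_seed Seed for the whole experiment.
#' @return A `run_config` object.
#' @export
run_config <- function(generator = list(), preprocess = list(),
                       dataset = "0, rest", cv = list(), master_seed = 1L) {
  as_section <- function(x, ctor) {
    if (inherits(x, setdiff(class(ctor()), "list"))) x else do.call(ctor, x)
  }
  gen <- list(
    model = if (inherits(generator$model, "spectrum_model")) generator$model
            else do.call(spectrum_model, generator$model %||% list()),
    schedule = if (inherits(generator$schedule, "cohort_schedule")) generator$schedule
               else do.call(cohort_schedule, generator$schedule %||% list()),
    scenario = if (inherits(generator$scenario, "aging_scenario")) generator$scenario
               else do.call(aging_scenario, generator$scenario %||% list())
  )
  filt <- if (inherits(preprocess, "filter_config")) preprocess
          else do.call(filter_config, preprocess)
  spec <- parse_dataset_spec(dataset)
  cv_defaults <- list(k = 20L, train_fraction = 0.8, mode = "monte_carlo",
                      learning_rate = 9e-7, max_epochs = 100000L,
                      eval_interval = 100L, batch_size = NULL,
                      dropout_p = 0, weight_decay = 0)
  cv <- utils::modifyList(cv_defaults, cv)
  structure(
    list(generator = gen, preprocess = filt, dataset = spec, cv = cv,
         master_seed = as.integer(master_seed)),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an experiment configuration from YAML
#'
#' @param path YAML file with (optional) sections `generator`, `preprocess`,
#'   `dataset`, `cv`, `master_seed`.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(generator = y$generator %||% list(),
             preprocess = y$preprocess %||% list(),
             dataset = y$dataset %||% "0, rest",
             cv = y$cv %||% list(),
             master_seed = y$master_seed %||% 1L)
}

cv_from_config <- function(cohort, config) {
  cv <- config$cv
  tc <- train_config(
    learning_rate = cv$learning_rate, max_epochs = cv$max_epochs,
    eval_interval = cv$eval_interval, batch_size = cv$batch_size
  )
  mc <- model_config(
    n_classes = length(config$dataset$bins),
    n_input = config$generator$model$n_points,
    dropout_p = cv$dropout_p, weight_decay = cv$weight_decay
  )
  cross_validate(cohort, config$dataset, k = cv$k,
                 train_fraction = cv$train_fraction, model_config = mc,
                 train = tc, master_seed = config$master_seed, mode = cv$mode)
}

#' Run a full simulated experiment
#'
#' Executes simulate -> preprocess -> build -> cross-validate and returns an
#' experiment report. With `out_dir` set, the cross-validation result, the
#' resolved configuration and a provenance record (configuration hash, seed,
#' package and R versions) are written as JSON; rerunning with the same
#' configuration and seed reproduces every number.
#'
#' @param config A [run_config()] (or nested list coerced to one).
#' @param cohort Optional pre-generated `raman_cohort`; when supplied the
#'   generator stage is skipped (used by [compare_arms()] to share one
#'   cohort).
#' @param out_dir Optional output directory.
#' @return An `experiment_report`: list with the `cv_result`, the config, and
#'   the provenance record.
#' @export
run_experiment <- function(config, cohort = NULL, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$generator$model, config$generator$schedule,
                              config$generator$scenario, config$master_seed)
  }
  cohort <- filter_baseline(cohort, config$preprocess)
  cv <- cv_from_config(cohort, config)
  prov <- list(
    config_hash = rlang::hash(config),
    master_seed = config$master_seed,
    package_version = as.character(utils::packageVersion("ramandelay")),
    r_version = R.version.string
  )
  report <- structure(list(cv = cv, config = config, provenance = prov),
                      class = "experiment_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(
        provenance = prov,
        dataset = config$dataset$text,
        filter = config$preprocess$level,
        final_accuracies = cv$final_accuracies,
        boxplot = as.list(cv$boxplot),
        chance = cv$chance,
        per_class = as.data.frame(cv$per_class),
        runs = cv$runs
      ),
      file.path(out_dir, "cv_result.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "columns"
    )
    yaml::write_yaml(
      list(dataset = config$dataset$text, filter = config$preprocess$level,
           master_seed = config$master_seed, cv = config$cv),
      file.path(out_dir, "config.yaml")
    )
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment \"", x$config$dataset$text, "\" (filter: ",
      x$config$preprocess$level, ")\n", sep = "")
  print(x$cv)
  invisible(x)
}

#' Compare experimental arms sharing one simulated cohort
#'
#' All configurations must share the generator section and master seed; the
#' cohort is simulated once and each arm's preprocessing + dataset +
#' cross-validation runs on it. Returns one row per arm with the boxplot
#' statistics and chance reference, mirroring the side-by-side boxplot
#' comparisons of day-group and filter ablations.
#'
#' @param configs Named list of `run_config` objects.
#' @return An `arm_comparison`: tibble with one row per arm plus the full
#'   `cv_result`s in the `results` attribute.
#' @export
compare_arms <- function(configs) {
  stopifnot(length(configs) >= 1)
  configs <- lapply(configs, function(cf) {
    if (inherits(cf, "run_config")) cf else do.call(run_config, cf)
  })
  gens <- lapply(configs, function(cf) list(cf$generator, cf$master_seed))
  if (length(unique(vapply(gens, rlang::hash, ""))) != 1)
    stop("comparison error: all arms must share the generator section and master seed",
         call. = FALSE)
  cf1 <- configs[[1]]
  cohort <- simulate_cohort(cf1$generator$model, cf1$generator$schedule,
                            cf1$generator$scenario, cf1$master_seed)
  names(configs) <- names(configs) %||%
    vapply(configs, function(cf) cf$dataset$text, "")
  results <- lapply(configs, function(cf) run_experiment(cf, cohort = cohort))
  table <- purrr::map_dfr(names(results), function(nm) {
    dplyr::mutate(glance(results[[nm]]$cv), arm = nm, .before = 1)
  })
  structure(table, results = lapply(results, `[[`, "cv"), class = c("arm_comparison",
                                                                    class(table)))
}
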