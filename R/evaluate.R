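#' Five-number boxplot statistics
#'
#' Minimum, lower quartile, median, upper quartile and maximum with
#' linear-interpolation quantiles (R type 7); the convention matters for small
#' k and is therefore fixed and documented here.
#'
#' @param values Numeric vector (length >= 1).
#' @return Named numeric vector `min`, `q1`, `median`, `q3`, `max`.
#' @export
boxplot_stats <- function(values) {
  if (!length(values)) stop("domain error: no values", call. = FALSE)
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Per-class prediction accuracy
#'
#' Element `c` is the fraction of class-`c` observations predicted as class
#' `c`. Classes absent from the truth vector are undefined and returned as
#' `NA` so they can be excluded from aggregation.
#'
#' @param true_labels,predicted_labels Integer vectors in `0..C-1`.
#' @param C Number of classes.
#' @return Numeric vector of length `C`.
#' @export
per_class_accuracy <- function(true_labels, predicted_labels, C) {
  if (length(true_labels) != length(predicted_labels))
    stop("shape error: label vectors differ in length", call. = FALSE)
  vapply(seq_len(C) - 1L, function(cl) {
    idx <- true_labels == cl
    if (!any(idx)) return(NA_real_)
    mean(predicted_labels[idx] == cl)
  }, numeric(1))
}

#' Chance-level accuracy references
#'
#' The accuracy a label-blind guesser would achieve: `uniform` guesses each
#' (non-empty) class equally often (1/C); `proportional` guesses classes with
#' their empirical frequencies (sum of squared frequencies); `majority` always
#' answers the largest class.
#'
#' @param class_counts Non-negative counts per class, sum > 0.
#' @param strategy One of `"uniform"`, `"proportional"`, `"majority"`.
#' @return Scalar chance accuracy.
#' @examples
#' chance_accuracy(c(330, 330, 106, 294, 230, 38, 144, 155), "proportional")
#' @export
chance_accuracy <- function(class_counts, strategy = c("uniform", "proportional", "majority")) {
  strategy <- match.arg(strategy)
  if (any(class_counts < 0) || sum(class_counts) <= 0)
    stop("domain error: counts must be non-negative with positive sum", call. = FALSE)
  p <- class_counts / sum(class_counts)
  switch(strategy,
    uniform = 1 / sum(class_counts > 0),
    proportional = sum(p^2),
    majority = max(p)
  )
}

#' Monte-Carlo cross-validation of the delay classifier
#'
#' Runs `k` independent repetitions: each run re-balances the dataset with its
#' own seed (the random discarding of excess spectra is part of every run),
#' draws a stratified train/test split, trains a freshly initialized network
#' and records the maximum test accuracy together with per-class accuracies of
#' the selected model. A partition-based k-fold mode is available via
#' `mode = "kfold"`, where the balanced dataset is built once and each fold
#' serves as the test set in turn.
#'
#' Rows are put in canonical (sample_id, day) order before any seeded draw, so
#' the result is invariant to the storage order of the cohort.
#'
#' @param cohort A `raman_cohort` tibble.
#' @param spec Dataset name or [parse_dataset_spec()] result.
#' @param k Number of runs (default 20; 100 is supported for confirmation
#'   runs).
#' @param train_fraction Training fraction for the stratified split.
#' @param model_config A [model_config()]; `n_classes` must match the day-group definition.
#'   `NULL` builds the default architecture for its class count.
#' @param train A [train_config()].
#' @param master_seed Seed from which every run's seeds are derived
#'   (`run_seed_i = (master_seed + 7919 i) mod 2^31-1`).
#' @param mode `"monte_carlo"` (independent splits, the default) or
#'   `"kfold"`.
#' @param group_by_sample If `TRUE`, all spectra of a patient are kept in the
#'   same partition (leakage-safe splitting); default `FALSE`, matching the
#'   per-spectrum protocol.
#' @return A `cv_result`: per-run tibble, per-class accuracy matrix, boxplot
#'   statistics of the k final accuracies and chance references.
#' @export
cross_validate <- function(cohort, spec, k = 20L, train_fraction = 0.8,
                           model_config = NULL, train = train_config(),
                           master_seed = 1L,
                           mode = c("monte_carlo", "kfold"),
                           group_by_sample = FALSE) {
  mode <- match.arg(mode)
  if (k < 2) stop("config error: k must be >= 2", call. = FALSE)
  if (is.character(spec)) spec <- parse_dataset_spec(spec)
  cohort <- cohort[order(cohort$sample_id, cohort$day), ]
  C <- length(spec$bins)
  if (is.null(model_config)) {
    model_config <- model_config(n_classes = C,
                                 n_input = length(cohort$intensity[[1]]))
  }
  if (model_config$n_classes != C)
    stop("config error: model n_classes != number of day bins", call. = FALSE)

  # class counts before balancing, for the chance references
  day_to_bin <- rep(NA_integer_, 8)
  for (b in seq_len(C)) day_to_bin[spec$bins[[b]] + 1L] <- b
  pre_counts <- vapply(seq_len(C),
                       function(b) sum(day_to_bin[cohort$day + 1L] == b, na.rm = TRUE), 0L)

  folds <- NULL
  if (mode == "kfold") {
    ds0 <- build_dataset(cohort, spec, rng_seed = master_seed)
    old <- .Random.seed_save()
    set.seed(master_seed)
    folds <- unlist(lapply(split(seq_along(ds0$labels), ds0$labels), function(rows) {
      f <- rep_len(seq_len(k), length(rows))
      stats::setNames(sample(f), rows)
    }))
    folds <- folds[order(as.integer(names(folds)))]
    .Random.seed_restore(old)
  }

  runs <- vector("list", k)
  per_class <- matrix(NA_real_, k, C, dimnames = list(NULL, spec$bin_names))
  for (i in seq_len(k)) {
    run_seed <- (master_seed + 7919 * i) %% 2147483647
    if (mode == "monte_carlo") {
      ds <- build_dataset(cohort, spec, rng_seed = run_seed)
      if (group_by_sample) {
        parts <- split_by_sample(ds, cohort, train_fraction, run_seed + 1)
      } else {
        parts <- split_train_test(ds, train_fraction, rng_seed = run_seed + 1)
      }
    } else {
      idx_te <- which(folds == i)
      idx_tr <- which(folds != i)
      parts <- list(
        train = new_delay_dataset(ds0$features[idx_tr, , drop = FALSE], ds0$labels[idx_tr],
                                  ds0$class_names, ds0$source_rows[idx_tr]),
        test = new_delay_dataset(ds0$features[idx_te, , drop = FALSE], ds0$labels[idx_te],
                                 ds0$class_names, ds0$source_rows[idx_te])
      )
    }
    net <- build_model(model_config, seed = run_seed + 2)
    tc <- train
    tc$seed <- as.integer((run_seed + 3) %% 2147483647)
    fit <- train_cnn(net, parts$train, parts$test, tc)
    pred <- predict(fit, parts$test)
    per_class[i, ] <- per_class_accuracy(parts$test$labels, pred, C)
    runs[[i]] <- tibble::tibble(
      run = i, seed = run_seed,
      final_accuracy = fit$final_accuracy,
      last_accuracy = fit$last_accuracy,
      best_epoch = fit$best_epoch,
      n_train = length(parts$train$labels),
      n_test = length(parts$test$labels)
    )
  }
  runs <- dplyr::bind_rows(runs)
  structure(
    list(
      runs = runs,
      final_accuracies = runs$final_accuracy,
      per_class = per_class,
      boxplot = boxplot_stats(runs$final_accuracy),
      chance = list(
        uniform = chance_accuracy(pre_counts, "uniform"),
        proportional = chance_accuracy(pre_counts, "proportional"),
        majority = chance_accuracy(pre_counts, "majority")
      ),
      class_counts = pre_counts,
      class_names = spec$bin_names,
      spec = spec,
      k = as.integer(k),
      mode = mode,
      master_seed = as.integer(master_seed)
    ),
    class = "cv_result"
  )
}

split_by_sample <- function(ds, cohort, train_fraction, rng_seed) {
  sample_of_row <- cohort$sample_id[ds$source_rows]
  ids <- unique(sample_of_row)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  train_ids <- sample(ids, max(1L, round(train_fraction * length(ids))))
  idx_tr <- which(sample_of_row %in% train_ids)
  idx_te <- setdiff(seq_along(ds$labels), idx_tr)
  if (!length(idx_te) || length(unique(ds$labels[idx_tr])) < length(ds$class_names))
    stop("split error: grouped split left a partition without all classes", call. = FALSE)
  list(
    train = new_delay_dataset(ds$features[idx_tr, , drop = FALSE], ds$labels[idx_tr],
                              ds$class_names, ds$source_rows[idx_tr]),
    test = new_delay_dataset(ds$features[idx_te, , drop = FALSE], ds$labels[idx_te],
                             ds$class_names, ds$source_rows[idx_te])
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-run %s cross-validation of dataset \"%s\"\n", x$k,
              ifelse(x$mode == "kfold", "k-fold", "Monte-Carlo"), x$spec$text))
  b <- x$boxplot
  cat(sprintf("  accuracy: median %.3f [q1 %.3f, q3 %.3f], range %.3f-%.3f (chance %.3f)\n",
              b["median"], b["q1"], b["q3"], b["min"], b["max"], x$chance$uniform))
  invisible(x)
}

#' Spectral clustering of spectra
#'
#' Graph-Laplacian clustering on a cosine-similarity affinity: rows are
#' L2-normalized, the affinity's diagonal is zeroed, the symmetric normalized
#' Laplacian's leading eigenvectors are row-normalized, and k-means assigns
#' the clusters. In serum cohorts the fluorescence level dominates this
#' geometry, so clusters track patient disease severity rather than storage
#' day; training restricted to the largest cluster probes whether a more
#' homogeneous cohort learns the delay better.
#'
#' @param x Feature matrix (rows = spectra) or a `raman_cohort`.
#' @param n_clusters Number of clusters (default 3).
#' @param seed Seed for the k-means step.
#' @return Integer cluster labels (1-based) with the eigengap diagnostic in
#'   attribute `eigengap`.
#' @export
spectral_cluster <- function(x, n_clusters = 3L, seed = 1L) {
  X <- if (inherits(x, "raman_cohort")) do.call(rbind, x$intensity) else as.matrix(x)
  n <- nrow(X)
  if (n_clusters < 1 || n_clusters > n)
    stop("config error: n_clusters must be in 1..nrow", call. = FALSE)
  if (n_clusters == 1) return(structure(rep(1L, n), eigengap = NA_real_))
  S <- X / sqrt(rowSums(X^2))
  A <- S %*% t(S)
  A[A < 0] <- 0
  diag(A) <- 0
  d <- pmax(rowSums(A), .Machine$double.eps)
  Dm <- 1 / sqrt(d)
  L <- A * tcrossprod(Dm)  # D^{-1/2} A D^{-1/2}
  eig <- eigen(L, symmetric = TRUE)
  U <- eig$vectors[, seq_len(n_clusters), drop = FALSE]
  U <- U / pmax(sqrt(rowSums(U^2)), .Machine$double.eps)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(U, centers = n_clusters, nstart = 10, iter.max = 100)
  gap <- if (length(eig$values) > n_clusters)
    eig$values[n_clusters] - eig$values[n_clusters + 1] else NA_real_
  structure(as.integer(km$cluster), eigengap = gap)
}

#' Rows of the largest cluster
#'
#' Convenience selector for cluster-restricted training: returns the row
#' indices of the most populated cluster (lowest label on ties).
#'
#' @param labels Integer cluster labels.
#' @return Integer row indices.
#' @export
largest_cluster <- function(labels) {
  tab <- table(labels)
  which(labels == as.integer(names(tab)[which.max(tab)]))
}
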