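#' Parse a day-group dataset name
#'
#' Datasets are named by the day groups they contain: `"0, 1"` holds day-0 and
#' day-1 spectra as two classes, `"0, 1, 3 + 4"` additionally merges days 3
#' and 4 into one bin, `"0, rest"` pits day 0 against all remaining days
#' merged, and `"all"` is the unmodified 8-class dataset. All datasets except
#' `"all"` are balanced by randomly discarding excess spectra.
#'
#' @param text Dataset name.
#' @return A `dataset_spec` with fields `bins` (list of integer day sets),
#'   `bin_names`, `uses_rest`, `is_all` and `balance`.
#' @examples
#' parse_dataset_spec("0, 1, 3 + 4")$bins
#' @export
parse_dataset_spec <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop("spec error: dataset name must be a non-empty string", call. = FALSE)
  raw <- trimws(text)
  if (identical(tolower(raw), "all")) {
    return(structure(
      list(bins = as.list(0:7), bin_names = as.character(0:7),
           uses_rest = FALSE, is_all = TRUE, balance = FALSE, text = raw),
      class = "dataset_spec"
    ))
  }
  items <- trimws(strsplit(raw, ",")[[1]])
  if (any(!nzchar(items))) stop("parse error: empty bin in dataset name", call. = FALSE)
  uses_rest <- FALSE
  bins <- list()
  for (i in seq_along(items)) {
    item <- items[i]
    if (identical(tolower(item), "rest")) {
      if (i != length(items))
        stop("spec error: 'rest' must be the last bin", call. = FALSE)
      uses_rest <- TRUE
      bins[[i]] <- setdiff(0:7, unlist(bins))
      if (!length(bins[[i]]))
        stop("spec error: 'rest' bin is empty", call. = FALSE)
    } else {
      days <- trimws(strsplit(item, "\\+")[[1]])
      if (any(!grepl("^[0-7]$", days)))
        stop("parse error: unknown token in '", item, "'", call. = FALSE)
      bins[[i]] <- as.integer(days)
    }
  }
  all_days <- unlist(bins)
  if (anyDuplicated(all_days))
    stop("spec error: day ", all_days[duplicated(all_days)][1],
         " appears in more than one bin", call. = FALSE)
  if (length(bins) < 2)
    stop("spec error: need at least 2 bins (or 'all')", call. = FALSE)
  names <- vapply(bins, function(b) paste(b, collapse = "+"), "")
  if (uses_rest) names[length(names)] <- "rest"
  structure(
    list(bins = bins, bin_names = names, uses_rest = uses_rest,
         is_all = FALSE, balance = TRUE, text = raw),
    class = "dataset_spec"
  )
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat("Dataset spec \"", x$text, "\": ", length(x$bins), " classes (",
      paste(x$bin_names, collapse = " | "), "), ",
      if (x$balance) "balanced" else "unbalanced", "\n", sep = "")
  invisible(x)
}

new_delay_dataset <- function(features, labels, class_names, source_rows) {
  structure(
    list(features = features, labels = as.integer(labels),
         class_names = class_names, source_rows = as.integer(source_rows)),
    class = "delay_dataset"
  )
}

#' @export
print.delay_dataset <- function(x, ...) {
  cnt <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L))
  cat("Labeled dataset:", nrow(x$features), "x", ncol(x$features),
      "features;", length(x$class_names), "classes (",
      paste(sprintf("%s: %d", x$class_names, cnt), collapse = ", "), ")\n")
  invisible(x)
}

#' Build a labeled dataset from a cohort
#'
#' Assigns each spectrum the index of the day bin containing its measurement
#' day (spectra in no bin are dropped) and, for balanced specs, randomly
#' downsamples every class to the size of the smallest one. The balancing
#' draw is seeded and is meant to be redone for every cross-validation run.
#'
#' @param cohort A `raman_cohort` tibble (or any tibble with `day` and a
#'   list-column `intensity`).
#' @param spec A [parse_dataset_spec()] result or the dataset name as string.
#' @param rng_seed Seed for the balancing draw.
#' @return A `delay_dataset`: feature matrix (rows = spectra), zero-based
#'   integer labels, class names, and the cohort row indices used.
#' @export
build_dataset <- function(cohort, spec, rng_seed = 1L) {
  if (is.character(spec)) spec <- parse_dataset_spec(spec)
  stopifnot(inherits(spec, "dataset_spec"))
  lens <- lengths(cohort$intensity)
  if (length(unique(lens)) > 1)
    stop("shape error: spectra of unequal length", call. = FALSE)
  day_to_bin <- rep(NA_integer_, 8)
  for (b in seq_along(spec$bins)) day_to_bin[spec$bins[[b]] + 1L] <- b
  bin <- day_to_bin[cohort$day + 1L]
  keep <- which(!is.na(bin))
  counts <- vapply(seq_along(spec$bins), function(b) sum(bin[keep] == b, na.rm = TRUE), 0L)
  if (any(counts == 0))
    stop("data error: no spectra for bin '",
         spec$bin_names[which(counts == 0)[1]], "'", call. = FALSE)
  if (spec$balance) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(rng_seed)
    m <- min(counts)
    keep <- unlist(lapply(seq_along(spec$bins), function(b) {
      rows <- keep[bin[keep] == b]
      if (length(rows) > m) sort(sample(rows, m)) else rows
    }))
  }
  features <- do.call(rbind, cohort$intensity[keep])
  new_delay_dataset(features, bin[keep] - 1L, spec$bin_names, keep)
}

#' Stratified train/test split
#'
#' Randomly assigns `round(train_fraction * n_c)` spectra of every class `c`
#' to the training partition; the split is disjoint, exhaustive and
#' reproducible from `rng_seed`. Stratification keeps balanced datasets
#' balanced in both partitions.
#'
#' @param dataset A `delay_dataset`.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param rng_seed Seed for the assignment draw.
#' @return List with elements `train` and `test`, both `delay_dataset`s whose
#'   `source_rows` refer to the original cohort rows.
#' @export
split_train_test <- function(dataset, train_fraction = 0.8, rng_seed = 1L) {
  stopifnot(inherits(dataset, "delay_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("split error: train_fraction must be in (0, 1)", call. = FALSE)
  cnt <- table(dataset$labels)
  if (any(cnt < 2))
    stop("split error: every class needs at least 2 members", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed)
  train_idx <- unlist(lapply(sort(unique(dataset$labels)), function(cl) {
    rows <- which(dataset$labels == cl)
    n_tr <- round(train_fraction * length(rows))
    n_tr <- min(max(n_tr, 1L), length(rows) - 1L)  # both partitions non-empty
    sort(sample(rows, n_tr))
  }))
  test_idx <- setdiff(seq_along(dataset$labels), train_idx)
  subset_ds <- function(idx) {
    new_delay_dataset(dataset$features[idx, , drop = FALSE], dataset$labels[idx],
                      dataset$class_names, dataset$source_rows[idx])
  }
  list(train = subset_ds(train_idx), test = subset_ds(test_idx))
}
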