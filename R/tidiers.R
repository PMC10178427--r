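#' Tidy a training run
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return The epoch log as a tibble (`epoch`, `loss`, `train_accuracy`,
#'   `test_accuracy`).
#' @export
tidy.cnn_fit <- function(x, ...) x$epoch_log

#' @rdname tidy.cnn_fit
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble::tibble(
    final_accuracy = x$final_accuracy,
    best_epoch = x$best_epoch,
    last_accuracy = x$last_accuracy,
    final_loss = x$epoch_log$loss[nrow(x$epoch_log)],
    epochs = x$epoch_log$epoch[nrow(x$epoch_log)],
    n_parameters = n_parameters(x$config)
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One row per run: seed, final (max-test) accuracy, last-epoch
#'   accuracy, best epoch and partition sizes.
#' @export
tidy.cv_result <- function(x, ...) x$runs

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  b <- x$boxplot
  tibble::tibble(
    dataset = x$spec$text,
    k = x$k,
    median_accuracy = b[["median"]],
    q1 = b[["q1"]],
    q3 = b[["q3"]],
    min = b[["min"]],
    max = b[["max"]],
    chance_uniform = x$chance$uniform,
    chance_proportional = x$chance$proportional
  )
}

#' Per-class accuracies of a cross-validation, long format
#'
#' @param x A `cv_result`.
#' @return Tibble with `run`, `class` (bin name) and `accuracy`.
#' @export
per_class_tidy <- function(x) {
  stopifnot(inherits(x, "cv_result"))
  tibble::as_tibble(x$per_class) |>
    dplyr::mutate(run = dplyr::row_number()) |>
    tidyr::pivot_longer(-"run", names_to = "class", values_to = "accuracy") |>
    dplyr::mutate(class = factor(.data$class, levels = x$class_names))
}

#' Training-curve plot
#'
#' Loss, training accuracy and test accuracy against the epoch, with the
#' maximum test accuracy (the run's reported predictive power) marked by a
#' dashed line; later epochs are overfitting.
#'
#' @param object A `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$epoch_log, -"epoch",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$final_accuracy, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Accuracy boxplot of a cross-validation
#'
#' The distribution of the k final accuracies, with the chance reference
#' marked by an orange cross.
#'
#' @param object A `cv_result`.
#' @param chance Which chance reference to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, chance = c("uniform", "proportional", "majority"),
                               ...) {
  chance <- match.arg(chance)
  df <- tibble::tibble(dataset = object$spec$text,
                       accuracy = object$final_accuracies)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dataset, y = .data$accuracy)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::annotate("point", x = 1, y = object$chance[[chance]],
                      shape = 4, size = 3, colour = "orange") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "final accuracy") +
    ggplot2::theme_minimal()
}

#' Per-day accuracy boxplots
#'
#' One box per day bin, summarizing the per-class accuracies across runs.
#'
#' @param x A `cv_result`.
#' @return A ggplot object.
#' @export
plot_per_class <- function(x) {
  df <- per_class_tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$accuracy)) +
    ggplot2::geom_boxplot(width = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "day bin", y = "per-class accuracy") +
    ggplot2::theme_minimal()
}

#' Spectrum plot
#'
#' @param object A `raman_spectrum`.
#' @param ... Unused.
#' @return A ggplot object; the estimated baseline is overlaid when present.
#' @export
autoplot.raman_spectrum <- function(object, ...) {
  df <- tibble::tibble(wavenumber = object$wavenumbers,
                       intensity = object$intensities)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(object$baseline)) {
    bl <- tibble::tibble(wavenumber = object$wavenumbers, intensity = object$baseline)
    p <- p + ggplot2::geom_line(data = bl, colour = "red", linetype = "dotted")
  }
  p
}
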