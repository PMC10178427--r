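#' Configure the 1D convolutional network
#'
#' Describes the spectrum classifier: three valid (no-padding, stride-1)
#' convolution blocks, each followed by a leaky-ReLU activation and a
#' non-overlapping max pool, then a fully connected head. The defaults are the
#' architecture used throughout the delay-prediction experiments: kernels of
#' width 3 with 8, 16 and 32 descriptors (channels), pool width 3, and hidden
#' layers of 256, 128 and 64 units.
#'
#' @param n_classes Number of day-group classes (>= 2).
#' @param n_input Spectrum length fed to the network. Default 3438 points.
#' @param kernel_sizes,descriptors,pool_sizes Integer vectors, one entry per
#'   convolution layer; must all have the same length.
#' @param hidden_sizes Integer vector of fully connected hidden-layer widths.
#' @param activation_slope Negative-side slope of the leaky ReLU.
#' @param dropout_p Dropout probability on the hidden dense layers (0 disables).
#' @param weight_decay Decoupled (AdamW) weight-decay factor.
#' @return A `model_config` object.
#' @examples
#' cfg <- model_config(n_classes = 2)
#' flattened_size(3438, cfg)
#' @export
model_config <- function(n_classes,
                         n_input = 3438L,
                         kernel_sizes = c(3L, 3L, 3L),
                         descriptors = c(8L, 16L, 32L),
                         pool_sizes = c(3L, 3L, 3L),
                         hidden_sizes = c(256L, 128L, 64L),
                         activation_slope = 0.01,
                         dropout_p = 0,
                         weight_decay = 0) {
  if (n_classes < 2) stop("config error: n_classes must be >= 2", call. = FALSE)
  n_conv <- length(kernel_sizes)
  if (length(descriptors) != n_conv || length(pool_sizes) != n_conv)
    stop("config error: kernel_sizes, descriptors and pool_sizes must have equal length",
         call. = FALSE)
  if (any(kernel_sizes < 1) || any(pool_sizes < 1) || any(descriptors < 1))
    stop("config error: kernel, pool and descriptor counts must be positive", call. = FALSE)
  if (dropout_p < 0 || dropout_p >= 1)
    stop("config error: dropout_p must be in [0, 1)", call. = FALSE)
  if (weight_decay < 0) stop("config error: weight_decay must be >= 0", call. = FALSE)
  cfg <- structure(
    list(
      n_input = as.integer(n_input),
      n_classes = as.integer(n_classes),
      kernel_sizes = as.integer(kernel_sizes),
      descriptors = as.integer(descriptors),
      pool_sizes = as.integer(pool_sizes),
      hidden_sizes = as.integer(hidden_sizes),
      activation_slope = activation_slope,
      dropout_p = dropout_p,
      weight_decay = weight_decay
    ),
    class = "model_config"
  )
  flattened_size(cfg$n_input, cfg)  # errors if any intermediate length collapses
  cfg
}

#' Length of the flattened convolutional output
#'
#' Propagates the input length through the convolution blocks: a valid
#' stride-1 convolution maps length L to L - k + 1 and a non-overlapping max
#' pool of width p to floor(L / p). The result is the final length times the
#' last descriptor count, i.e. the width of the first dense layer.
#'
#' @param n_input Input spectrum length.
#' @param config A [model_config()].
#' @return Integer flattened size.
#' @export
flattened_size <- function(n_input, config) {
  L <- as.integer(n_input)
  for (l in seq_along(config$kernel_sizes)) {
    L <- L - config$kernel_sizes[l] + 1L
    if (L < 1L)
      stop("architecture error: input too short for kernel in conv layer ", l, call. = FALSE)
    L <- L %/% config$pool_sizes[l]
    if (L < 1L)
      stop("architecture error: input too short for pool in conv layer ", l, call. = FALSE)
  }
  L * config$descriptors[length(config$descriptors)]
}

#' Total number of trainable parameters
#'
#' Closed-form count: each convolution contributes `k * c_in * c_out + c_out`
#' and each dense layer `n_in * n_out + n_out`.
#'
#' @inheritParams flattened_size
#' @return Integer parameter count.
#' @export
n_parameters <- function(config) {
  total <- 0L
  c_in <- 1L
  for (l in seq_along(config$kernel_sizes)) {
    c_out <- config$descriptors[l]
    total <- total + config$kernel_sizes[l] * c_in * c_out + c_out
    c_in <- c_out
  }
  widths <- c(flattened_size(config$n_input, config), config$hidden_sizes, config$n_classes)
  for (i in seq_len(length(widths) - 1L))
    total <- total + widths[i] * widths[i + 1L] + widths[i + 1L]
  total
}

arch_list <- function(config) {
  list(
    n_input = config$n_input,
    n_classes = config$n_classes,
    kernel = config$kernel_sizes,
    pool = config$pool_sizes,
    channels = config$descriptors,
    hidden = config$hidden_sizes,
    slope = config$activation_slope
  )
}

#' Initialize a network
#'
#' Draws all weights and biases from the uniform fan-in scheme
#' U(-1/sqrt(fan_in), 1/sqrt(fan_in)); the draw is fully determined by `seed`.
#'
#' @inheritParams flattened_size
#' @param seed Integer seed for the initialization draw.
#' @return A `cnn_model` with elements `config` and `params` (named list of
#'   weight matrices and bias vectors, convolution layers first).
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  params <- list()
  c_in <- 1L
  for (l in seq_along(config$kernel_sizes)) {
    c_out <- config$descriptors[l]
    fan_in <- config$kernel_sizes[l] * c_in
    bound <- 1 / sqrt(fan_in)
    params[[paste0("conv", l, "_W")]] <-
      matrix(stats::runif(c_out * fan_in, -bound, bound), c_out, fan_in)
    params[[paste0("conv", l, "_b")]] <- stats::runif(c_out, -bound, bound)
    c_in <- c_out
  }
  widths <- c(flattened_size(config$n_input, config), config$hidden_sizes, config$n_classes)
  for (i in seq_len(length(widths) - 1L)) {
    bound <- 1 / sqrt(widths[i])
    params[[paste0("dense", i, "_W")]] <-
      matrix(stats::runif(widths[i + 1L] * widths[i], -bound, bound), widths[i + 1L], widths[i])
    params[[paste0("dense", i, "_b")]] <- stats::runif(widths[i + 1L], -bound, bound)
  }
  structure(list(config = config, params = params), class = "cnn_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Training protocol settings
#'
#' Defaults follow the delay-prediction protocol: AdamW with learning rate
#' 9e-7, cross-entropy loss, full-batch gradient steps, and a budget of up to
#' 100 000 epochs. `eval_interval` controls how often the held-out test set is
#' scored; the reported accuracy of a run is the maximum test accuracy seen at
#' any evaluation. For desk-scale experiments pass a larger learning rate and a
#' smaller epoch budget (see the package vignette's test profile).
#'
#' @param learning_rate AdamW step size (> 0).
#' @param max_epochs Maximum number of epochs (full passes).
#' @param eval_interval Epochs between test evaluations.
#' @param batch_size `NULL` for full-batch training (the default), otherwise a
#'   mini-batch size.
#' @param seed Integer seed for dropout masks and mini-batch shuffling.
#' @param scale_features Divide all intensities by the maximum absolute value
#'   of the training features (one global factor, applied identically to the
#'   test set) so that raw-device-unit spectra are numerically well
#'   conditioned. The relative structure of the spectra is unchanged.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 9e-7,
                         max_epochs = 100000L,
                         eval_interval = 100L,
                         batch_size = NULL,
                         seed = 1L,
                         scale_features = TRUE) {
  if (learning_rate <= 0) stop("config error: learning_rate must be > 0", call. = FALSE)
  if (max_epochs < 1) stop("config error: max_epochs must be >= 1", call. = FALSE)
  if (eval_interval < 1) stop("config error: eval_interval must be >= 1", call. = FALSE)
  structure(
    list(
      learning_rate = learning_rate,
      max_epochs = as.integer(max_epochs),
      eval_interval = as.integer(eval_interval),
      batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
      seed = as.integer(seed),
      scale_features = isTRUE(scale_features)
    ),
    class = "train_config"
  )
}

#' Train the network on a labeled dataset
#'
#' Minimizes softmax cross-entropy with AdamW. The test set is evaluated every
#' `eval_interval` epochs; the run's reported (`final`) accuracy is the maximum
#' test accuracy over all evaluations, which mirrors the max-test-accuracy
#' model-selection rule, and the last-epoch accuracy is kept alongside for
#' honest reporting.
#'
#' @param model A `cnn_model` from [build_model()].
#' @param train_set,test_set `delay_dataset` objects (see [build_dataset()]
#'   and [split_train_test()]) whose feature width matches the model input.
#' @param tc A [train_config()].
#' @return A `cnn_fit` with the epoch log (tibble: epoch, loss,
#'   train_accuracy, test_accuracy), `final_accuracy`, `best_epoch`,
#'   `last_accuracy`, the trained parameters and the feature scale used.
#'   `params` holds the weights at the best test evaluation (the selected
#'   model); `last_params` the weights after the final epoch.
#' @export
train_cnn <- function(model, train_set, test_set, tc = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(tc, "train_config"))
  cfg <- model$config
  for (ds in list(train_set, test_set)) {
    if (!inherits(ds, "delay_dataset")) stop("train_cnn expects delay_dataset inputs", call. = FALSE)
    if (ncol(ds$features) != cfg$n_input)
      stop("shape error: feature width ", ncol(ds$features), " != model n_input ", cfg$n_input,
           call. = FALSE)
    if (any(ds$labels < 0L | ds$labels >= cfg$n_classes))
      stop("data error: labels outside 0..C-1", call. = FALSE)
  }
  if (length(unique(train_set$labels)) < cfg$n_classes)
    stop("data error: some class is absent from the training set", call. = FALSE)

  scale <- 1
  if (tc$scale_features) {
    scale <- max(abs(train_set$features))
    if (!is.finite(scale) || scale == 0) scale <- 1
  }
  res <- cnn_train_cpp(
    model$params, arch_list(cfg),
    train_set$features / scale, as.integer(train_set$labels),
    test_set$features / scale, as.integer(test_set$labels),
    lr = tc$learning_rate, weight_decay = cfg$weight_decay, dropout = cfg$dropout_p,
    max_epochs = tc$max_epochs, eval_interval = tc$eval_interval,
    batch_size = if (is.null(tc$batch_size)) -1L else tc$batch_size,
    chunk = 64L, seed = tc$seed
  )
  log <- tibble::tibble(
    epoch = as.integer(res$epoch),
    loss = res$loss,
    train_accuracy = res$train_accuracy,
    test_accuracy = res$test_accuracy
  )
  best <- which.max(log$test_accuracy)
  structure(
    list(
      config = cfg,
      params = res$best_params,
      last_params = res$params,
      feature_scale = scale,
      epoch_log = log,
      final_accuracy = log$test_accuracy[best],
      best_epoch = log$epoch[best],
      last_accuracy = log$test_accuracy[nrow(log)],
      class_names = train_set$class_names
    ),
    class = "cnn_fit"
  )
}

#' @describeIn train_cnn Predict classes (or logits/probabilities) for a
#'   feature matrix or `delay_dataset`.
#' @param object A `cnn_fit`.
#' @param newdata Feature matrix (rows = spectra) or `delay_dataset`.
#' @param type `"class"`, `"prob"` or `"logits"`.
#' @param ... Unused.
#' @export
predict.cnn_fit <- function(object, newdata, type = c("class", "prob", "logits"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "delay_dataset")) newdata$features else as.matrix(newdata)
  logits <- cnn_forward_cpp(object$params, arch_list(object$config), X / object$feature_scale)
  if (type == "logits") return(logits)
  if (type == "prob") {
    z <- exp(logits - apply(logits, 1, max))
    return(z / rowSums(z))
  }
  max.col(logits, ties.method = "first") - 1L
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat("1D CNN fit:", x$config$n_classes, "classes,",
      format(n_parameters(x$config), big.mark = ","), "parameters\n")
  cat(sprintf("  final (max test) accuracy %.3f at epoch %d; last-epoch accuracy %.3f\n",
              x$final_accuracy, x$best_epoch, x$last_accuracy))
  invisible(x)
}

#' @export
print.model_config <- function(x, ...) {
  cat("1D CNN config: input", x$n_input, "->",
      paste0("conv[k=", paste(x$kernel_sizes, collapse = ","), "; c=",
             paste(x$descriptors, collapse = ","), "; pool=",
             paste(x$pool_sizes, collapse = ","), "]"),
      "-> flatten", flattened_size(x$n_input, x), "->",
      paste(x$hidden_sizes, collapse = "-"), "->", x$n_classes, "classes\n")
  invisible(x)
}
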