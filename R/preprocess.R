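#' Fluorescence filter configuration
#'
#' Two baseline-correction strengths are provided, both asymmetric-least-
#' squares (Eilers-style) estimates that differ in stiffness. `filter1` is
#' the less flexible smoother: a larger roughness penalty keeps its baseline
#' stiff, so a small fraction of the broad fluorescence background survives
#' in the residual. `filter2` is the more rigorous filter: with a smaller
#' penalty the estimate follows the background closely and the residual
#' retains essentially only peaks and noise.
#'
#' @param level One of `"none"`, `"filter1"`, `"filter2"`.
#' @param lambda Roughness penalty of the rigorous filter (> 0), defined at
#'   the reference 3438-point grid; larger is stiffer.
#' @param lambda_weak Roughness penalty of the weak filter (> `lambda`).
#' @param asymmetry Asymmetry weight in (0, 1) given to points above the
#'   baseline; small values let peaks float above the estimate.
#' @param iterations Reweighting iterations.
#' @return A `filter_config` object.
#' @export
filter_config <- function(level = c("none", "filter1", "filter2"),
                          lambda = 1e6, lambda_weak = 1e7, asymmetry = 0.01,
                          iterations = 10L) {
  level <- match.arg(level)
  if (lambda <= 0 || lambda_weak <= 0)
    stop("config error: roughness penalties must be > 0", call. = FALSE)
  if (lambda_weak < lambda)
    stop("config error: lambda_weak must be >= lambda (filter1 is the stiffer filter)",
         call. = FALSE)
  if (asymmetry <= 0 || asymmetry >= 1)
    stop("config error: asymmetry must be in (0, 1)", call. = FALSE)
  structure(list(level = level, lambda = lambda, lambda_weak = lambda_weak,
                 asymmetry = asymmetry, iterations = as.integer(iterations)),
            class = "filter_config")
}

# asymmetric least squares (Eilers): penalized least squares with asymmetric
# weights; points above the running estimate get weight `asymmetry`. The
# roughness penalty acts on second differences, whose magnitude depends on
# the sampling density, so `lambda` is defined at the reference 3438-point
# grid and rescaled by (n/3438)^4 to keep the continuous-domain stiffness
# independent of grid length.
baseline_als <- function(y, lambda, asymmetry, iterations) {
  n <- length(y)
  if (n < 4) stop("config error: spectrum too short for baseline estimation", call. = FALSE)
  lambda <- lambda * (n / 3438)^4
  D <- Matrix::diff(Matrix::Diagonal(n), differences = 2)
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iterations)) {
    A <- Matrix::Diagonal(n, w) + P
    z <- as.numeric(Matrix::solve(A, w * y))
    w_new <- ifelse(y > z, asymmetry, 1 - asymmetry)
    if (all(w_new == w)) break
    w <- w_new
  }
  z
}

estimate_baseline <- function(y, config) {
  switch(config$level,
    none = rep(0, length(y)),
    filter1 = baseline_als(y, config$lambda_weak, config$asymmetry, config$iterations),
    filter2 = baseline_als(y, config$lambda, config$asymmetry, config$iterations)
  )
}

#' Remove the fluorescence baseline from spectra
#'
#' Subtracts an estimated smooth background at the strength set by `config`.
#' Negative residuals are kept (not clipped). With `level = "none"` the input
#' is returned unchanged.
#'
#' @param x A `raman_spectrum` or a `raman_cohort` tibble.
#' @param config A [filter_config()].
#' @param ... Unused.
#' @return Same type as `x`, with intensities replaced by the residual. For a
#'   single spectrum the estimated baseline is attached as `$baseline`; for a
#'   cohort the filter settings are recorded in the `filter` attribute.
#' @export
filter_baseline <- function(x, config = filter_config(), ...) {
  UseMethod("filter_baseline")
}

#' @export
filter_baseline.raman_spectrum <- function(x, config = filter_config(), ...) {
  stopifnot(inherits(config, "filter_config"))
  bl <- estimate_baseline(x$intensities, config)
  out <- x
  out$intensities <- x$intensities - bl
  out$baseline <- bl
  out$meta$filter_level <- config$level
  out
}

#' @export
filter_baseline.raman_cohort <- function(x, config = filter_config(), ...) {
  stopifnot(inherits(config, "filter_config"))
  if (config$level == "none") {
    attr(x, "filter") <- config
    return(x)
  }
  out <- x
  out$intensity <- lapply(x$intensity, function(y) y - estimate_baseline(y, config))
  attr(out, "filter") <- config
  out
}

#' Normalize spectrum intensities
#'
#' @param x A `raman_spectrum` or `raman_cohort`.
#' @param method `"none"` (identity; raw spectra train best in this
#'   application), `"total_intensity"` (sum scaled to 1) or `"max"`
#'   (maximum scaled to 1).
#' @param ... Unused.
#' @return Same type as `x`, scaled; the method is recorded in the metadata.
#' @export
normalize_spectrum <- function(x, method = c("none", "total_intensity", "max"), ...) {
  UseMethod("normalize_spectrum")
}

normalize_vector <- function(y, method) {
  switch(method,
    none = y,
    total_intensity = {
      s <- sum(y)
      if (s <= 0) stop("degenerate-input error: non-positive total intensity", call. = FALSE)
      y / s
    },
    max = {
      m <- max(y)
      if (m <= 0) stop("degenerate-input error: non-positive maximum intensity", call. = FALSE)
      y / m
    }
  )
}

#' @export
normalize_spectrum.raman_spectrum <- function(x, method = c("none", "total_intensity", "max"),
                                              ...) {
  method <- match.arg(method)
  x$intensities <- normalize_vector(x$intensities, method)
  x$meta$normalization <- method
  x
}

#' @export
normalize_spectrum.raman_cohort <- function(x, method = c("none", "total_intensity", "max"),
                                            ...) {
  method <- match.arg(method)
  x$intensity <- lapply(x$intensity, normalize_vector, method = method)
  attr(x, "normalization") <- method
  x
}
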