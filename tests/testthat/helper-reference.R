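# Independent double-precision reference implementation of the network
# forward pass, written in plain R. Used as the oracle for the C++ engine:
# logits must agree to single-precision tolerance and analytic gradients must
# agree with finite differences of this reference loss.

ref_forward_one <- function(params, cfg, x) {
  slope <- cfg$activation_slope
  A <- matrix(x, nrow = 1)
  for (l in seq_along(cfg$kernel_sizes)) {
    k <- cfg$kernel_sizes[l]
    p <- cfg$pool_sizes[l]
    W <- params[[paste0("conv", l, "_W")]]
    b <- params[[paste0("conv", l, "_b")]]
    Lc <- ncol(A) - k + 1
    K <- matrix(0, nrow(A) * k, Lc)
    for (j in seq_len(k))
      K[((j - 1) * nrow(A) + 1):(j * nrow(A)), ] <- A[, j:(j + Lc - 1), drop = FALSE]
    Z <- W %*% K + b
    Z <- ifelse(Z > 0, Z, slope * Z)
    Lp <- Lc %/% p
    P <- matrix(0, nrow(Z), Lp)
    for (t in seq_len(Lp))
      P[, t] <- apply(Z[, ((t - 1) * p + 1):(t * p), drop = FALSE], 1, max)
    A <- P
  }
  h <- as.vector(A)  # column-major flatten: channel index varies fastest
  n_dense <- length(cfg$hidden_sizes) + 1L
  for (i in seq_len(n_dense)) {
    W <- params[[paste0("dense", i, "_W")]]
    b <- params[[paste0("dense", i, "_b")]]
    h <- as.vector(W %*% h + b)
    if (i < n_dense) h <- ifelse(h > 0, h, slope * h)
  }
  h
}

ref_forward <- function(params, cfg, X) {
  t(apply(X, 1, function(x) ref_forward_one(params, cfg, x)))
}

ref_ce_loss <- function(params, cfg, X, y) {
  logits <- ref_forward(params, cfg, X)
  z <- logits - apply(logits, 1, max)
  lse <- log(rowSums(exp(z)))
  mean(lse - z[cbind(seq_len(nrow(z)), y + 1L)])
}

# sort-based quantile oracle for boxplot statistics (type-7 interpolation)
ref_five_numbers <- function(v) {
  s <- sort(v)
  n <- length(s)
  interp <- function(p) {
    h <- (n - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[pmin(lo + 2, n)] - s[lo + 1])
  }
  c(min = s[1], q1 = interp(0.25), median = interp(0.5), q3 = interp(0.75), max = s[n])
}

# confusion-matrix oracle for per-class accuracy
ref_per_class_accuracy <- function(truth, pred, C) {
  vapply(seq_len(C) - 1L, function(cl) {
    idx <- truth == cl
    if (!any(idx)) return(NA_real_)
    mean(pred[idx] == cl)
  }, numeric(1))
}
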