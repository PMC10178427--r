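test_that("boxplot statistics match the sort-based oracle", {
  expect_equal(boxplot_stats(1:5),
               c(min = 1, q1 = 2, median = 3, q3 = 4, max = 5))
  expect_equal(unname(boxplot_stats(rep(3.7, 9))), rep(3.7, 5))
  set.seed(123)
  for (i in 1:100) {
    v <- runif(sample(1:50, 1))
    expect_equal(unname(boxplot_stats(v)), unname(ref_five_numbers(v)),
                 tolerance = 1e-12)
  }
  expect_error(boxplot_stats(numeric(0)), "domain error")
})

test_that("per-class accuracy matches the confusion-matrix oracle", {
  expect_equal(per_class_accuracy(c(0, 0, 1, 1), c(0, 1, 1, 1), 2), c(0.5, 1))
  expect_equal(per_class_accuracy(0:3, 0:3, 4), rep(1, 4))
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:60, 1)
    truth <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    expect_equal(per_class_accuracy(truth, pred, 3),
                 ref_per_class_accuracy(truth, pred, 3))
  }
  # absent classes are undefined, not zero
  expect_identical(per_class_accuracy(c(0, 0), c(0, 1), 3)[3], NA_real_)
  expect_error(per_class_accuracy(0:2, 0:1, 3), "shape error")
})

test_that("chance references follow their definitions", {
  expect_equal(chance_accuracy(c(10, 10), "uniform"), 0.5)
  expect_equal(chance_accuracy(rep(7, 5), "uniform"), 0.2)
  counts <- table2_counts
  expect_equal(chance_accuracy(counts, "proportional"),
               sum((counts / sum(counts))^2))
  expect_equal(chance_accuracy(counts, "majority"), 330 / 1627)
  expect_equal(chance_accuracy(c(0, 5, 5), "uniform"), 0.5)  # empty class ignored
  expect_error(chance_accuracy(c(0, 0), "uniform"), "domain error")
})

test_that("spectral clustering recovers planted fluorescence groups", {
  set.seed(21)
  mod <- tiny_model(n_points = 128, noise_sd = 2)
  low <- replicate(15, simulate_spectrum(mod, 0.2, 0, rng_seed = sample.int(1e6, 1))$intensities)
  high <- replicate(15, simulate_spectrum(mod, 4, 0, rng_seed = sample.int(1e6, 1))$intensities)
  X <- t(cbind(low, high))
  labels <- spectral_cluster(X, n_clusters = 2, seed = 1)
  planted <- rep(1:2, each = 15)
  agreement <- max(mean(labels == planted), mean(labels == 3 - planted))
  expect_equal(agreement, 1)

  expect_equal(spectral_cluster(X, n_clusters = 1), rep(1L, 30), ignore_attr = TRUE)
  expect_error(spectral_cluster(X, n_clusters = 40), "config error")

  lab3 <- spectral_cluster(X, n_clusters = 3, seed = 1)
  expect_gte(length(largest_cluster(lab3)), nrow(X) / 3)  # pigeonhole
})

make_cv_cohort <- function(seed = 1, n = 10) {
  simulate_cohort(spectrum_model(n_points = 64),
                  cohort_schedule(n), aging_scenario(), master_seed = seed)
}

fast_tc <- function(epochs = 30) {
  train_config(learning_rate = 2e-3, max_epochs = epochs, eval_interval = 10)
}

small_mc <- function(C) {
  model_config(n_classes = C, n_input = 64, kernel_sizes = c(3, 3),
               descriptors = c(4, 8), pool_sizes = c(3, 3), hidden_sizes = c(16, 8))
}

test_that("cross-validation produces k runs and is reproducible", {
  coh <- make_cv_cohort()
  cv1 <- cross_validate(coh, "0, rest", k = 3, model_config = small_mc(2),
                        train = fast_tc(), master_seed = 5)
  expect_length(cv1$final_accuracies, 3)
  expect_identical(dim(cv1$per_class), c(3L, 2L))
  expect_equal(unname(cv1$boxplot["median"]), median(cv1$final_accuracies))

  cv2 <- cross_validate(coh, "0, rest", k = 3, model_config = small_mc(2),
                        train = fast_tc(), master_seed = 5)
  expect_identical(cv1$final_accuracies, cv2$final_accuracies)
  expect_identical(cv1$per_class, cv2$per_class)

  cv3 <- cross_validate(coh, "0, rest", k = 3, model_config = small_mc(2),
                        train = fast_tc(), master_seed = 6)
  expect_false(identical(cv1$final_accuracies, cv3$final_accuracies))
})

test_that("cross-validation is invariant to cohort row order", {
  coh <- make_cv_cohort(seed = 3)
  cv1 <- cross_validate(coh, "0, rest", k = 2, model_config = small_mc(2),
                        train = fast_tc(20), master_seed = 9)
  shuffled <- coh[sample(nrow(coh)), ]
  cv2 <- cross_validate(shuffled, "0, rest", k = 2, model_config = small_mc(2),
                        train = fast_tc(20), master_seed = 9)
  expect_identical(cv1$final_accuracies, cv2$final_accuracies)
})

test_that("k-fold mode partitions the balanced dataset once", {
  coh <- make_cv_cohort(seed = 4, n = 8)
  cv <- cross_validate(coh, "0, rest", k = 4, model_config = small_mc(2),
                       train = fast_tc(20), master_seed = 2, mode = "kfold")
  expect_length(cv$final_accuracies, 4)
  # the four test folds tile the balanced dataset: test sizes sum to its size
  expect_equal(sum(cv$runs$n_test), 16)
})

test_that("grouped splitting keeps each patient on one side", {
  coh <- make_cv_cohort(seed = 5, n = 12)
  cv <- cross_validate(coh, "0, rest", k = 2, model_config = small_mc(2),
                       train = fast_tc(20), master_seed = 3, group_by_sample = TRUE)
  expect_length(cv$final_accuracies, 2)
})

test_that("chance references accompany the cross-validation result", {
  coh <- make_cv_cohort(seed = 6)
  cv <- cross_validate(coh, "0, rest", k = 2, model_config = small_mc(2),
                       train = fast_tc(20), master_seed = 1)
  expect_equal(cv$chance$uniform, 0.5)
  n0 <- sum(coh$day == 0)
  nr <- sum(coh$day > 0)
  p <- c(n0, nr) / (n0 + nr)
  expect_equal(cv$chance$proportional, sum(p^2))
  expect_equal(cv$chance$majority, max(p))
})
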