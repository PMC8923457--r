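test_that("confusion matrix counts true-by-predicted pairs", {
  expect_identical(
    confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2), 2),
    matrix(c(1L, 0L, 1L, 2L), 2, 2)
  )
  perfect <- confusion_matrix(rep(1:3, each = 4), rep(1:3, each = 4), 3)
  expect_true(all(perfect == diag(4, 3))) # diagonal, 4 per class
  set.seed(17)
  yt <- sample(1:4, 50, replace = TRUE)
  yp <- sample(1:4, 50, replace = TRUE)
  m <- confusion_matrix(yt, yp, 4)
  expect_identical(unname(rowSums(m)), as.numeric(tabulate(yt, 4)))
  expect_identical(sum(m), 50L)
  expect_error(confusion_matrix(c(1, 5), c(1, 2), 4), class = "pgsa_error_label")
  expect_error(confusion_matrix(1:3, 1:2, 3), class = "pgsa_error_dimension")
})

test_that("per-class metrics agree with a brute-force oracle and published rows", {
  # a recall of 1.00 with precision 0.81 gives F1 = 1.62/1.81 -> 0.90 at 2dp
  expect_equal(round(2 * 1.0 * 0.81 / (1.0 + 0.81), 2), 0.90)
  # equal precision and recall leave the harmonic mean unchanged
  expect_equal(2 * 0.57 * 0.57 / (0.57 + 0.57), 0.57)

  diag4 <- per_class_metrics(diag(5L, 4))
  expect_equal(diag4$per_class$tpr, rep(1, 4))
  expect_equal(diag4$per_class$ppv, rep(1, 4))
  expect_equal(diag4$per_class$f1, rep(1, 4))
  expect_equal(diag4$overall_accuracy, 1)

  set.seed(23)
  for (i in 1:100) {
    C <- sample(2:6, 1)
    conf <- matrix(rpois(C * C, lambda = sample(0:4, 1)), C, C)
    if (sum(conf) == 0) conf[1, 1] <- 1
    got <- per_class_metrics(conf)
    want <- oracle_metrics(conf)
    expect_equal(got$per_class$tpr, unname(want[, "tpr"]))
    expect_equal(got$per_class$ppv, unname(want[, "ppv"]))
    expect_equal(got$per_class$f1, unname(want[, "f1"]))
    expect_equal(got$overall_accuracy, sum(diag(conf)) / sum(conf))
    # F1 between min and max of its parts when both positive
    pos <- want[, "tpr"] > 0 & want[, "ppv"] > 0
    expect_true(all(
      want[pos, "f1"] <= pmax(want[pos, "tpr"], want[pos, "ppv"]) + 1e-12
    ))
    expect_true(all(
      want[pos, "f1"] >= pmin(want[pos, "tpr"], want[pos, "ppv"]) - 1e-12
    ))
    # accuracy is the prevalence-weighted mean of per-class recall
    expect_equal(
      got$overall_accuracy,
      sum(want[, "tpr"] * rowSums(conf)) / sum(conf)
    )
  }
  expect_error(per_class_metrics(matrix(0, 2, 2)), class = "pgsa_error_empty")
})

test_that("zero-denominator conventions keep the metrics total", {
  # class 1 is never predicted correctly and never predicted at all
  m <- per_class_metrics(matrix(c(0L, 2L, 0L, 3L), 2, 2, byrow = TRUE))
  expect_equal(m$per_class$tpr[1], 0) # no true class-1 hits
  expect_equal(m$per_class$f1[1], 0)
})

test_that("summary statistics use the sample standard deviation", {
  s <- summary_stats(c(0.94, 0.87, 0.81, 0.77, 0.94, 0.80))
  expect_equal(s$min, 0.77)
  expect_equal(s$max, 0.94)
  expect_equal(round(s$sd, 2), 0.07)
  expect_equal(summary_stats(rep(0.4, 5))$sd, 0)
  expect_equal(summary_stats(c(2, 5))$sd, 3 / sqrt(2))
  expect_error(summary_stats(1), class = "pgsa_error_empty")
})

test_that("the kernel sweep finds a perfect kernel on separable data and is order-invariant", {
  sim <- tiny_dataset(n_per_class = 15, n_classes = 2, separation = 8, seed = 19)
  cv <- crossval_evaluate(sim$data, sim$informative, k = 5, seed = 1)
  expect_s3_class(cv, "pgsa_cv")
  expect_equal(max(cv$kernel_accuracy$accuracy), 1.0)
  expect_equal(cv$metrics$overall_accuracy, 1.0)
  expect_identical(sum(cv$metrics$confusion), 30L)

  # shuffling sample order leaves the pooled accuracy identical
  shuffled <- sim$data[sample(nrow(sim$data)), ]
  cv2 <- crossval_evaluate(shuffled, sim$informative, k = 5, seed = 1)
  expect_identical(cv$kernel_accuracy$accuracy, cv2$kernel_accuracy$accuracy)
  expect_identical(cv$metrics$confusion, cv2$metrics$confusion)

  # leave-one-per-fold boundary: k equal to the smallest class size
  small <- simulate_expression(
    n_samples_per_class = 5, n_classes = 2, n_genes = 8,
    n_informative = 2, effect_size = 5, seed = 21
  )
  cv3 <- crossval_evaluate(small$data, small$informative, k = 5, seed = 2)
  expect_s3_class(cv3, "pgsa_cv")
  expect_error(
    crossval_evaluate(small$data, small$informative, k = 6, seed = 2),
    class = "pgsa_error_small_class"
  )
})

test_that("cv tidiers and the plain-text table expose per-class rows", {
  sim <- tiny_dataset(n_per_class = 10, n_classes = 3, separation = 6, seed = 23)
  cv <- crossval_evaluate(sim$data, sim$informative, k = 5, seed = 3)
  td <- tidy(cv)
  expect_identical(nrow(td), 3L)
  expect_named(td, c("class", "tpr", "ppv", "f1", "n_true"))
  gl <- glance(cv)
  expect_identical(gl$best_kernel, cv$best_kernel)
  expect_identical(gl$n_samples, 30L)
  lines <- format_metrics_table(cv)
  expect_length(lines, 5)
  expect_match(lines[1], "Overall accuracy")
  expect_match(lines[3], "^TPR")
  expect_s3_class(autoplot(cv), "ggplot")
})
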