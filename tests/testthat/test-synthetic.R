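test_that("the generator is deterministic and shapes are as requested", {
  s1 <- simulate_expression(
    n_samples_per_class = 6, n_classes = 3, n_genes = 30,
    n_informative = 4, seed = 5
  )
  s2 <- simulate_expression(
    n_samples_per_class = 6, n_classes = 3, n_genes = 30,
    n_informative = 4, seed = 5
  )
  expect_identical(s1$data, s2$data)
  expect_identical(s1$informative, s2$informative)
  expect_identical(dim(s1$data), c(18L, 32L)) # sample_id + class + genes
  expect_identical(sort(unique(s1$data$class)), 1:3)
  expect_length(s1$informative, 4)
  s3 <- simulate_expression(
    n_samples_per_class = 6, n_classes = 3, n_genes = 30,
    n_informative = 4, seed = 6
  )
  expect_false(identical(s1$data, s3$data))
})

test_that("informative genes carry per-class mean shifts, noise genes do not", {
  sim <- simulate_expression(
    n_samples_per_class = 200, n_classes = 3, n_genes = 10,
    n_informative = 3, effect_size = 2, seed = 8
  )
  class_means <- function(g) {
    tapply(sim$data[[g]], sim$data$class, mean)
  }
  for (g in sim$informative) {
    mu <- as.numeric(sort(class_means(g)))
    # per-class means sit near a permutation of {0, 2, 4}
    expect_equal(unname(mu), c(0, 2, 4), tolerance = 0.35)
  }
  noise <- setdiff(sprintf("g%04d", 1:10), sim$informative)
  for (g in noise) {
    expect_lt(max(abs(class_means(g))), 0.35)
  }
})

test_that("a single strongly shifted gene supports a near-perfect classifier", {
  sim <- simulate_expression(
    n_samples_per_class = 20, n_classes = 2, n_genes = 10,
    n_informative = 1, effect_size = 5, seed = 12
  )
  split <- make_split(sim$data, seed = 1)
  mask <- as.integer(sprintf("g%04d", 1:10) %in% sim$informative)
  expect_gte(svm_fitness(sim$data, split, mask), 0.9)
})

test_that("with zero effect size no subset beats chance systematically", {
  accs <- sapply(1:6, function(s) {
    sim <- simulate_expression(
      n_samples_per_class = 15, n_classes = 2, n_genes = 12,
      n_informative = 5, effect_size = 0, seed = 30 + s
    )
    split <- make_split(sim$data, seed = s)
    svm_fitness(sim$data, split, rep(1, 12))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.2)
})

test_that("informative genes out-rank constant genes in entropy", {
  sim <- simulate_expression(
    n_samples_per_class = 10, n_classes = 3, n_genes = 8,
    n_informative = 3, effect_size = 3, seed = 14
  )
  d <- sim$data
  d$gflat <- 1.0
  ranking <- entropy_rank(d)
  flat_rank <- ranking$rank[ranking$gene_id == "gflat"]
  inf_ranks <- ranking$rank[ranking$gene_id %in% sim$informative]
  expect_true(all(inf_ranks < flat_rank))
  expect_identical(
    ranking$entropy[ranking$gene_id == "gflat"], 0
  )
})

test_that("recovery scores are set arithmetic", {
  expect_equal(
    recovery_score(c("a", "b"), c("a", "b"))[, c("recall", "precision")],
    tibble::tibble(recall = 1, precision = 1)
  )
  expect_equal(
    recovery_score(c("x", "y"), c("a", "b"))$recall, 0
  )
  sc <- recovery_score(c(1, 2, 3, 9, 10, 11), 1:5)
  expect_equal(sc$recall, 0.6)
  expect_equal(sc$precision, 0.5)
  expect_equal(recovery_score(character(0), c("a"))$precision, 0)
  expect_error(recovery_score("a", character(0)), class = "pgsa_error_empty")
})

test_that("generated data round-trips through the delimited writer and loader", {
  sim <- simulate_expression(
    n_samples_per_class = 5, n_classes = 2, n_genes = 6, seed = 17
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(sim, path)
  ds <- read_expression_matrix(path)
  orig <- as_expression_dataset(sim$data)
  expect_identical(ds$gene_ids, orig$gene_ids)
  expect_identical(ds$sample_ids, orig$sample_ids)
  expect_identical(ds$labels, orig$labels)
  expect_equal(ds$matrix, orig$matrix, tolerance = 1e-12)
})
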