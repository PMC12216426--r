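test_that("ARI is 1 for identical partitions up to relabeling", {
  a <- c(1, 1, 2, 2, 3, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(7, 7, 5, 5, 9, 9, 9)), 1)
  expect_equal(adjusted_rand_index(letters[a], a), 1)
})

test_that("ARI matches direct pair counting and an installed reference", {
  a <- c(0, 0, 1, 1, 2, 2)
  b <- c(0, 0, 1, 2, 2, 2)
  expect_equal(adjusted_rand_index(a, b), ari_pair_oracle(a, b),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:10) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), ari_pair_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("both metrics are symmetric and permutation-invariant", {
  set.seed(17)
  for (i in 1:5) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_identical(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
    expect_identical(adjusted_mutual_information(a, b),
                     adjusted_mutual_information(b, a))
    relab <- c(3, 1, 2)[a]
    expect_equal(adjusted_rand_index(relab, b), adjusted_rand_index(a, b),
                 tolerance = 1e-12)
    expect_equal(adjusted_mutual_information(relab, b),
                 adjusted_mutual_information(a, b), tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
  expect_error(adjusted_mutual_information(1:3, 1:4), "equal length")
})

test_that("AMI is 1 for identical partitions and near 0 under independence", {
  a <- rep(1:5, each = 10)
  expect_equal(adjusted_mutual_information(a, a), 1)
  set.seed(99)
  null_scores <- replicate(50, {
    x <- sample(1:5, 500, replace = TRUE)
    y <- sample(1:5, 500, replace = TRUE)
    adjusted_mutual_information(x, y)
  })
  expect_lt(abs(mean(null_scores)), 0.02)
})

test_that("ARI and AMI agree with scikit-learn on random cases", {
  set.seed(7)
  cases <- lapply(1:20, function(i) {
    n <- sample(20:80, 1)
    list(a = sample(0:4, n, replace = TRUE), b = sample(0:3, n, replace = TRUE))
  })
  ref <- sklearn_partition_scores(cases)
  for (i in seq_along(cases)) {
    expect_equal(adjusted_rand_index(cases[[i]]$a, cases[[i]]$b),
                 ref$ari[i], tolerance = 1e-6)
    expect_equal(adjusted_mutual_information(cases[[i]]$a, cases[[i]]$b),
                 ref$ami[i], tolerance = 1e-6)
  }
})

test_that("greedy mapping recovers a pure relabeling with overlap 1", {
  a <- sample(1:4, 60, replace = TRUE)
  b <- c(4, 1, 3, 2)[a]
  m <- greedy_cluster_mapping(a, b)
  expect_equal(m$overlap_fraction, 1)
  expect_identical(unname(m$mapping[as.character(1:4)]),
                   as.character(c(4, 1, 3, 2)))
  expect_length(m$unmatched_a, 0)
})

test_that("greedy mapping leaves surplus clusters unmatched", {
  a <- c(1, 1, 2, 2, 3, 3)
  b <- c(1, 1, 2, 2, 2, 2)
  m <- greedy_cluster_mapping(a, b)
  expect_length(m$mapping, 2)
  expect_length(m$unmatched_a, 1)
  expect_length(m$unmatched_b, 0)
})

test_that("greedy mapping is optimal on small instances but can be beaten", {
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    g <- greedy_cluster_mapping(a, b)$overlap_fraction
    expect_lte(g, best_mapping_overlap(a, b) + 1e-12)
  }
  # constructed counterexample: greedy grabs the 5-cell and forfeits 4+4
  a <- c(rep(1, 9), rep(2, 4))
  b <- c(rep(1, 5), rep(2, 4), rep(1, 4))
  g <- greedy_cluster_mapping(a, b)
  expect_equal(g$overlap_fraction, 5 / 13)
  expect_equal(best_mapping_overlap(a, b), 8 / 13)  # the documented gap
})

test_that("overlap 1 holds iff partitions are identical up to relabeling", {
  a <- sample(1:3, 30, replace = TRUE)
  expect_equal(greedy_cluster_mapping(a, c(2, 3, 1)[a])$overlap_fraction, 1)
  b <- a; b[1] <- (a[1] %% 3) + 1
  expect_lt(greedy_cluster_mapping(a, b)$overlap_fraction, 1)
})

test_that("consistency benchmark recovers planted expert structure", {
  expert <- rep(1:4, each = 30)
  X <- planted_bundle_embedding(expert, d = 8, noise = 0.02, seed = 2)
  cb <- consistency_benchmark(X, expert, runs = 5, inits_per_run = 5,
                              seed = 3)
  expect_identical(cb$k, 4L)
  expect_gte(cb$summary$mean[cb$summary$metric == "ari"], 0.95)
  expect_gte(cb$summary$mean[cb$summary$metric == "ami"], 0.95)
})

test_that("consistency benchmark scores near zero on pure noise", {
  set.seed(44)
  expert <- sample(1:4, 150, replace = TRUE)
  X <- l2_normalize(matrix(rnorm(150 * 10), 150, 10))
  cb <- consistency_benchmark(X, expert, runs = 5, inits_per_run = 3,
                              seed = 5)
  expect_lt(abs(cb$summary$mean[cb$summary$metric == "ari"]), 0.05)
  expect_error(consistency_benchmark(X, NULL), "expert labels")
})

test_that("matched-field consistency exceeds crossed-field consistency", {
  cfg <- sim_config(n_patients = 800, n_latent_clusters = 4, seed = 1)
  synth <- generate_cohort(cfg)
  Edx <- hash_embed(synth$cohort$diagnosis, 1024, seed = 3)
  Eop <- hash_embed(synth$cohort$operation, 1024, seed = 4)
  score <- function(E, lab) mean(unlist(
    consistency_benchmark(E, lab, k = 8, runs = 3, inits_per_run = 5,
                          seed = 1)$summary$mean))
  diag_mean <- mean(c(score(Edx, synth$cohort$expert_diagnosis),
                      score(Eop, synth$cohort$expert_operation)))
  off_mean <- mean(c(score(Edx, synth$cohort$expert_operation),
                     score(Eop, synth$cohort$expert_diagnosis)))
  expect_gt(diag_mean, off_mean)
  expect_gt(off_mean, 0.02)  # crossed fields still agree via the parent
})

test_that("stability analysis scores every unordered pair of runs", {
  expert <- rep(1:3, each = 15)
  X <- planted_bundle_embedding(expert, d = 6, noise = 0.02, seed = 9)
  st <- stability_analysis(X, k = 3, runs = 10, inits_per_run = 3, seed = 2)
  expect_identical(nrow(st$pairs), 45L)  # 10 * 9 / 2
  expect_equal(st$summary$mean[st$summary$metric == "ari"], 1)
  expect_equal(st$summary$mean[st$summary$metric == "overlap"], 1)
  expect_error(stability_analysis(X, k = 3, runs = 1), "runs")
})

test_that("weakly separated data is stable above the null but below 1", {
  expert <- rep(1:3, each = 40)
  X <- planted_bundle_embedding(expert, d = 6, noise = 1.2, seed = 13)
  st <- stability_analysis(X, k = 3, runs = 5, inits_per_run = 2, seed = 3)
  m <- st$summary$mean[st$summary$metric == "ari"]
  expect_lt(m, 1)
  expect_gt(m, 0.1)
})
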