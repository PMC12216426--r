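test_that("label prompts list every member under its group with field prefixes", {
  cohort <- data.frame(
    diagnosis = c("aortic regurgitation; lv outflow tract obstruction",
                  "mitral regurgitation"),
    operation = c("aortic root replacement", "mitral valvar procedure"),
    stringsAsFactors = FALSE)
  p <- build_label_prompt(cohort, c(1L, 1L),
                          fields = c("operation", "diagnosis"))
  expect_identical(p$k, 1L)
  expect_identical(length(gregexpr("Group 1:", p$text, fixed = TRUE)[[1]]), 1L)
  body_lines <- strsplit(p$text, "\n")[[1]]
  member_lines <- grep(" \\|\\| ", body_lines, value = TRUE)
  expect_length(member_lines, 2)
  expect_true(all(grepl("Operations:", member_lines)))
  expect_true(all(grepl("Diagnoses:", member_lines)))
  expect_true(grepl("grouped into 1 groups", p$text))
  expect_gt(p$token_estimate, 0)
})

test_that("prompt sections cover all clusters and all rows exactly once", {
  synth <- small_cohort(n = 120, k = 3, seed = 41)
  X <- concat_embeddings(hash_embed(synth$cohort$diagnosis, 128, seed = 1),
                         hash_embed(synth$cohort$operation, 128, seed = 2))
  fit <- spherical_kmeans(X, k = 5, n_init = 5, seed = 3)
  p <- build_label_prompt(synth$cohort, fit$assignment)
  expect_identical(p$k, 5L)
  lines <- strsplit(p$text, "\n")[[1]]
  expect_length(grep("^Group [0-9]+:$", lines), 5)
  expect_length(grep(" \\|\\| ", lines), 120)
  # byte-determinism
  expect_identical(p$text, build_label_prompt(synth$cohort,
                                              fit$assignment)$text)
  # empty cluster warns but keeps its section
  expect_warning(pe <- build_label_prompt(synth$cohort[1:10, ],
                                          c(rep(1L, 9), 3L)), "no members")
  expect_true(grepl("Group 2:", pe$text))
  # member cap truncates with an ellipsis marker
  pc <- build_label_prompt(synth$cohort, fit$assignment, member_cap = 3)
  expect_true(grepl("\\.\\.\\.", pc$text))
  expect_length(grep(" \\|\\| ", strsplit(pc$text, "\n")[[1]]), 15)
})

test_that("structured label responses parse and validate", {
  good <- jsonlite::toJSON(lapply(1:3, function(g)
    list(group_number = g, short_label = paste0("label ", g),
         long_label = paste0("long label ", g))), auto_unbox = TRUE)
  ls <- parse_label_response(good, k = 3, source = "stub", run_id = 2L)
  expect_identical(nrow(ls$labels), 3L)
  expect_identical(ls$labels$group_number, 1:3)
  expect_identical(ls$run_id, 2L)

  dup <- jsonlite::toJSON(lapply(c(1, 2, 2), function(g)
    list(group_number = g, short_label = "x", long_label = "y")),
    auto_unbox = TRUE)
  expect_error(parse_label_response(dup, k = 3), "duplicate")
  expect_error(parse_label_response(good, k = 4), "1..4")
  expect_error(parse_label_response("not json", k = 2), "valid JSON")
  expect_error(parse_label_response('[{"group_number": 1}]', k = 1),
               "short_label")
})

test_that("stub labeler round-trips through the parser for many k", {
  synth <- small_cohort(n = 160, k = 4, seed = 43)
  for (k in c(2L, 8L, 16L)) {
    set.seed(k)
    assignment <- sample.int(k, nrow(synth$cohort), replace = TRUE)
    assignment[seq_len(k)] <- seq_len(k)  # ensure no empty cluster
    resp <- stub_labeler(synth$cohort, assignment)
    ls <- parse_label_response(resp, k = k)
    expect_identical(nrow(ls$labels), k)
  }
})

test_that("stub labels surface a cluster's over-represented codes", {
  cohort <- data.frame(
    diagnosis = c(rep("aaa; bbb", 5), rep("ccc; ddd", 5)),
    operation = c(rep("op1", 5), rep("op2", 5)), stringsAsFactors = FALSE)
  resp <- stub_labeler(cohort, rep(1:2, each = 5))
  ls <- parse_label_response(resp, k = 2)
  expect_true(grepl("aaa|bbb|op1", ls$labels$short_label[1]))
  expect_true(grepl("ccc|ddd|op2", ls$labels$short_label[2]))
})

test_that("labels align across runs via the greedy mapping", {
  synth <- small_cohort(n = 100, k = 3, seed = 47)
  base_assign <- sample.int(4, 100, replace = TRUE)
  perms <- list(1:4, c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 4, 1, 2))
  runs <- lapply(seq_along(perms), function(r) {
    assignment <- perms[[r]][base_assign]
    list(assignment = assignment,
         labels = parse_label_response(
           stub_labeler(synth$cohort, assignment), k = 4,
           source = "stub", run_id = r))
  })
  al <- align_labels(runs)
  expect_identical(dim(al$table), c(4L, 4L))
  # permuted relabelings of one partition align to identical label rows
  for (g in 1:4)
    expect_length(unique(al$table[g, ]), 1L)
  expect_true(all(al$pair_overlap$overlap == 1))
  bad <- runs; bad[[2]]$assignment <- bad[[2]]$assignment[1:50]
  expect_error(align_labels(bad), "different row sets")
})

test_that("kendall tau-b matches cor.test on random fixtures", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(30:120, 1)
    x <- if (i %% 2 == 0) rbinom(n, 1, 0.3) else sample(1:5, n, TRUE)
    y <- rnorm(n) + 0.3 * x
    ours <- kendall_tau(x, y)
    ref <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    expect_equal(ours$tau, unname(ref$estimate), tolerance = 1e-8)
  }
  # membership indicator against itself is perfectly concordant
  g <- rbinom(60, 1, 0.4)
  expect_equal(kendall_tau(g, g)$tau, 1)
  expect_true(is.na(kendall_tau(rep(1, 10), rnorm(10))$tau))
})

test_that("tau p-values are calibrated under independence", {
  set.seed(5)
  raw_reject <- replicate(200, {
    g <- rbinom(200, 1, 0.25)
    y <- rnorm(200)
    kendall_tau(g, y)$p < 0.05
  })
  expect_gt(mean(raw_reject), 0.02)
  expect_lt(mean(raw_reject), 0.09)
})

test_that("outcome-cluster correlation tables carry Bonferroni structure", {
  synth <- small_cohort(n = 300, k = 3, seed = 53)
  set.seed(1)
  assignment <- sample.int(10, 300, replace = TRUE)
  ct <- outcome_cluster_correlation(assignment, synth$outcomes,
                                    operation_time = synth$cohort$optime_min)
  expect_identical(ct$m, 50L)  # 5 outcomes x 10 clusters
  expect_identical(nrow(ct$table), 50L)
  expect_true(all(abs(ct$table$tau) <= 1, na.rm = TRUE))
  expect_identical(ct$alpha / ct$m, 0.001)
  expect_length(ct$cluster_order, 10)
  # ordering follows decreasing mean operation time
  expect_true(all(diff(ct$mean_optime[ct$cluster_order]) <= 0))
})

test_that("a planted high-risk cluster shows significant positive tau", {
  cfg <- sim_config(n_patients = 1000, n_latent_clusters = 4,
                    outcome_effects = c(2, 0, 0, 0), seed = 59)
  synth <- cohort_with_outcomes(cfg)
  ct <- outcome_cluster_correlation(synth$true_cluster, synth$outcomes)
  row <- ct$table[ct$table$outcome == "kdigo_binary" & ct$table$cluster == 1, ]
  expect_gt(row$tau, 0)
  expect_true(row$significant_bonferroni)
})

test_that("partition comparison prompts are blind and structured", {
  synth <- small_cohort(n = 60, k = 3, seed = 67)
  a <- sample.int(3, 60, replace = TRUE)
  b <- sample.int(2, 60, replace = TRUE)
  blind <- build_partition_comparison_prompt(synth$cohort, a, b)
  expect_false(grepl("AI", blind))
  expect_false(grepl("expert", blind))
  expect_true(grepl("Partition 1", blind))
  expect_identical(blind, build_partition_comparison_prompt(synth$cohort,
                                                            a, b))
  lines <- strsplit(blind, "\n")[[1]]
  expect_length(grep("^Group [0-9]+:$", lines), 3 + 2)
  open <- build_partition_comparison_prompt(synth$cohort, a, b,
                                            blind = FALSE)
  expect_true(grepl("AI", open))
})
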