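test_that("BMI follows weight over squared height", {
  expect_equal(compute_bmi(16, 1.0), 16)
  expect_equal(compute_bmi(20, 2.0), 5)
  expect_error(compute_bmi(-1, 1), "positive")
  expect_error(compute_bmi(10, 0), "positive")
  synth <- small_cohort(n = 240, seed = 3)
  bmi <- compute_bmi(synth$cohort$weight_kg, synth$cohort$height_cm / 100)
  expect_true(stats::median(bmi) > 10 && stats::median(bmi) < 22)
})

test_that("residual height vanishes on data lying on the smooth", {
  n <- 200
  set.seed(1)
  ages <- stats::runif(n, 1, 180)
  genders <- rep(c("female", "male"), length.out = n)
  heights <- 50 + 0.5 * ages    # locally linear: degree-1 LOESS is exact
  r <- residual_height(heights, ages, genders)
  expect_lt(max(abs(r)), 1e-6)
})

test_that("residual height is centred near zero on synthetic growth data", {
  synth <- small_cohort(n = 1000, seed = 19)
  r <- residual_height(synth$cohort$height_cm, synth$cohort$age_months,
                       synth$cohort$gender)
  expect_lt(abs(mean(r)), 0.01)
  expect_gt(stats::sd(r), 0.03)  # on the scale of the generator's noise
  expect_lt(stats::sd(r), 0.15)
})

test_that("residual height guards group sizes and supports held-out rows", {
  expect_error(residual_height(1:40, 1:40, rep(c("f", "m"), c(35, 5))),
               "m")
  synth <- small_cohort(n = 300, seed = 23)
  tr <- 1:250; te <- 251:300
  r_te <- residual_height(synth$cohort$height_cm[tr],
                          synth$cohort$age_months[tr],
                          synth$cohort$gender[tr],
                          newdata = list(heights = synth$cohort$height_cm[te],
                                         ages = synth$cohort$age_months[te],
                                         genders = synth$cohort$gender[te]))
  expect_length(r_te, 50)
  expect_true(all(is.finite(r_te)))
})

test_that("feature blocks have the documented widths", {
  synth <- small_cohort(n = 240, k = 3, seed = 5)
  cohort <- synth$cohort
  base <- assemble_features(cohort, "baseline")
  expect_identical(ncol(base$matrix), 5L)
  expect_identical(base$provenance, "baseline")

  n_expert <- length(unique(cohort$expert_diagnosis))
  ex <- assemble_features(cohort, "expert", field = "diagnosis")
  expect_identical(ncol(ex$matrix), 5L + n_expert)

  emb <- hash_embed(cohort$diagnosis, 128, seed = 2)
  fit <- spherical_kmeans(emb, k = 10, n_init = 5, seed = 3)
  ai <- assemble_features(cohort, "ai", field = "diagnosis",
                          clustering = fit, embeddings = emb)
  expect_identical(ncol(ai$matrix), 15L)
  expect_false(anyNA(ai$matrix))

  expect_error(assemble_features(cohort, "ai", field = "diagnosis"),
               "clustering")
  expect_error(assemble_features(cohort, "expert", field = "nope"),
               "expert label")
})

test_that("the classifier contract handles separable and degenerate folds", {
  set.seed(6)
  x <- matrix(c(rnorm(40, -3), rnorm(40, 3)), ncol = 1)
  y <- rep(0:1, each = 40)
  p <- fit_predict_binary(x, y, x)
  expect_equal(threshold_averaged_metrics(p, y)$roc_auc, 1)

  p0 <- fit_predict_binary(x, rep(1, 80), x[1:5, , drop = FALSE])
  expect_true(isTRUE(attr(p0, "degenerate")))
  expect_true(all(p0 == 1))

  # permuted labels carry no signal
  aucs <- replicate(20, {
    yp <- sample(y)
    tr <- sample(80, 60)
    pte <- fit_predict_binary(x[tr, , drop = FALSE], yp[tr],
                              x[-tr, , drop = FALSE])
    threshold_averaged_metrics(pte, y[-tr])$roc_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("logistic coefficients recover a planted feature effect", {
  set.seed(8)
  n <- 400
  x <- cbind(signal = rnorm(n), noise = rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(-1 + 1.5 * x[, 1]))
  fit <- suppressWarnings(stats::glm.fit(cbind(1, x), y,
                                         family = stats::binomial()))
  expect_gt(fit$coefficients[2], 0)
  p <- fit_predict_binary(x, y, x)
  expect_gt(threshold_averaged_metrics(p, y)$roc_auc, 0.6)
})

test_that("field averaging and ensembling are the stated weighted means", {
  expect_equal(average_field_models(0.2, 0.4), 0.3)
  expect_equal(average_field_models(c(0.5, 0.1), c(0.5, 0.1)), c(0.5, 0.1))
  set.seed(2)
  a <- runif(50); b <- runif(50)
  avg <- average_field_models(a, b)
  expect_true(all(avg >= pmin(a, b) & avg <= pmax(a, b)))
  expect_error(average_field_models(1:3 / 10, 1:4 / 10), "equal length")

  expect_equal(ensemble_predict(list(0.6, 0.3), c(2, 1)), 0.5)
  expect_equal(ensemble_predict(list(0.6, 0.3, 0.9), c(2, 1, 0.2)), 0.525)
  expect_equal(ensemble_predict(list(c(0.2, 0.8)), 1), c(0.2, 0.8))
  expect_error(ensemble_predict(list(0.5, 0.5), c(0, 0)), "sum")
})

test_that("threshold-averaged metrics match hand enumeration", {
  perfect <- threshold_averaged_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(perfect$roc_auc, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # constant 0.5 scores: thresholds 0.1..0.5 predict all positive,
  # 0.6..0.9 all negative -> sensitivity averages 5/9
  m <- threshold_averaged_metrics(rep(0.5, 4), c(1, 1, 0, 0))
  expect_equal(m$sensitivity, 5 / 9)
  expect_equal(m$specificity, 4 / 9)
  expect_equal(m$precision, 5 * 0.5 / 9)  # zero-positive cutoffs add 0
  expect_equal(m$n_zero_positive_thresholds, 4L)

  # reversing probabilities reflects the AUC
  set.seed(3)
  p <- runif(60); y <- rbinom(60, 1, 0.4)
  expect_equal(threshold_averaged_metrics(1 - p, y)$roc_auc,
               1 - threshold_averaged_metrics(p, y)$roc_auc,
               tolerance = 1e-12)
  expect_error(threshold_averaged_metrics(p, rep(1, 60)), "single class")
  expect_error(threshold_averaged_metrics(p, y, thresholds = c(0.5, 0.2)),
               "increasing")
})

test_that("rank AUC agrees with an installed reference", {
  set.seed(14)
  p <- runif(100); y <- rbinom(100, 1, 0.3)
  ours <- threshold_averaged_metrics(p, y)$roc_auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("repeated CV partitions every row once per repeat", {
  synth <- small_cohort(n = 100, k = 3, seed = 31)
  variants <- list(cv_variant("baseline", "baseline"))
  rep2 <- run_repeated_cv(synth$cohort, variants,
                          cv_config(repeats = 2, folds = 5, master_seed = 1))
  expect_identical(nrow(rep2$records), 10L)
  for (r in 1:2) {
    f <- rep2$fold_ids[, r]
    expect_identical(sort(unique(f)), 1:5)
    expect_true(all(table(f) == 20))
  }
  expect_error(run_repeated_cv(synth$cohort[1:4, ], variants,
                               cv_config(repeats = 1, folds = 5)),
               "fewer rows")
})

test_that("CV reports are deterministic in the master seed", {
  synth <- small_cohort(n = 100, k = 3, seed = 31)
  variants <- list(cv_variant("baseline", "baseline"),
                   cv_variant("expert", "expert"))
  cfg <- cv_config(repeats = 2, folds = 5, master_seed = 7)
  a <- run_repeated_cv(synth$cohort, variants, cfg)
  b <- run_repeated_cv(synth$cohort, variants, cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$fold_ids, b$fold_ids)
})

test_that("ai features lift AUC over baseline on cluster-linked outcomes", {
  cfg <- sim_config(n_patients = 500, n_latent_clusters = 4,
                    outcome_effects = c(2, 0, 0, 0), seed = 55)
  synth <- cohort_with_outcomes(cfg)
  variants <- list(
    cv_variant("baseline", "baseline"),
    cv_variant("ai_hash", "ai",
               embedder = embedder_spec("hash", dimension = 512,
                                        hyperparameters = list(seed = 5)),
               k = 10, n_init = 10))
  rep_ <- suppressWarnings(run_repeated_cv(
    synth$cohort, variants, cv_config(repeats = 3, folds = 10,
                                      master_seed = 2)))
  s <- summary(rep_)
  expect_gt(s$roc_auc[s$model == "ai_hash"], s$roc_auc[s$model == "baseline"])
  tt <- paired_fold_ttest(rep_, "ai_hash", "baseline",
                          alternative = "greater")
  expect_lt(tt$p, 0.01)
})

test_that("fold-scoped CV refits text machinery without leakage errors", {
  synth <- small_cohort(n = 150, k = 3, seed = 61)
  variants <- list(
    cv_variant("baseline", "baseline"),
    cv_variant("ai_bot", "ai", embedder = embedder_spec("bot"),
               k = 4, n_init = 3))
  rep_ <- run_repeated_cv(synth$cohort, variants,
                          cv_config(repeats = 1, folds = 3, master_seed = 3),
                          scope = "fold")
  expect_identical(nrow(rep_$records), 6L)
  metrics <- c("roc_auc", "accuracy", "precision", "f1", "sensitivity",
               "specificity")
  expect_true(all(as.matrix(rep_$records[metrics]) >= 0 &
                    as.matrix(rep_$records[metrics]) <= 1))
})

test_that("ensembles combine stored component probabilities in-fold", {
  synth <- small_cohort(n = 120, k = 3, seed = 71)
  variants <- list(
    cv_variant("baseline", "baseline"),
    cv_variant("expert", "expert"),
    cv_variant("both", "ensemble", components = c("baseline", "expert"),
               weights = c(2, 1)))
  rep_ <- run_repeated_cv(synth$cohort, variants,
                          cv_config(repeats = 1, folds = 4, master_seed = 5))
  expect_setequal(unique(rep_$records$model),
                  c("baseline", "expert", "both"))
  expect_error(run_repeated_cv(synth$cohort, list(
    cv_variant("e", "ensemble", components = "ghost", weights = 1)),
    cv_config(repeats = 1, folds = 4)), "unknown components")
})

test_that("paired fold t-test behaves at the null and against pt()", {
  synth <- small_cohort(n = 100, k = 3, seed = 31)
  rep_ <- run_repeated_cv(synth$cohort,
                          list(cv_variant("baseline", "baseline")),
                          cv_config(repeats = 2, folds = 5, master_seed = 1))
  rep_$records <- rbind(rep_$records,
                        transform(rep_$records, model = "copy"))
  tt <- paired_fold_ttest(rep_, "baseline", "copy")
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  # shifted copy: one-sided p matches the t-distribution tail directly
  shifted <- rep_
  set.seed(9)
  noise <- rnorm(10, 0, 0.01)
  shifted$records$roc_auc[shifted$records$model == "copy"] <-
    shifted$records$roc_auc[shifted$records$model == "baseline"] -
    0.05 + noise
  tt2 <- paired_fold_ttest(shifted, "baseline", "copy",
                           alternative = "greater")
  d <- 0.05 - noise
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(tt2$t, t_manual, tolerance = 1e-8)
  expect_equal(tt2$p, stats::pt(t_manual, df = 9, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_lt(tt2$p, 0.05)
  expect_error(paired_fold_ttest(rep_, "baseline", "ghost"), "unknown model")
})
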