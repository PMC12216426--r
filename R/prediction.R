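#' Body mass index
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in metres (> 0).
#' @return `weight / height^2`. Vectorized.
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0) ||
      any(!is.finite(height)) || any(height <= 0))
    stop("weight and height must be positive", call. = FALSE)
  weight / height^2
}

#' Residual height: percent deviation from a per-gender growth smooth
#'
#' Fits a LOESS smooth of height on age separately within each gender
#' (degree 1, default span 0.75, direct surface so predictions extrapolate
#' beyond the fitted age range) and returns `(height - fit) / fit` per row.
#' Replaces raw height, which is almost collinear with age in a pediatric
#' cohort, with its age-and-gender-adjusted deviation.
#'
#' @param heights Heights (any consistent unit).
#' @param ages Ages in months.
#' @param genders Gender labels; each level needs at least `min_per_group`
#'   rows for a stable smooth.
#' @param span,degree LOESS parameters (defaults 0.75 and 1).
#' @param min_per_group Minimum rows per gender (default 30).
#' @param newdata Optional list `(heights, ages, genders)`: when supplied,
#'   smooths are fitted on the main arguments (training rows) and residuals
#'   are returned for `newdata` instead, supporting leakage-free
#'   cross-validation.
#' @return Numeric vector of fractional deviations (e.g. 0.05 = 5 percent
#'   above the growth curve).
#' @export
residual_height <- function(heights, ages, genders, span = 0.75, degree = 1,
                            min_per_group = 30L, newdata = NULL) {
  stopifnot(length(heights) == length(ages), length(ages) == length(genders))
  genders <- as.character(genders)
  counts <- table(genders)
  small <- names(counts)[counts < min_per_group]
  if (length(small))
    stop("too few rows for a stable height smooth in group(s): ",
         paste(small, collapse = ", "), call. = FALSE)
  fits <- lapply(split(data.frame(h = heights, a = ages), genders),
                 function(d) stats::loess(h ~ a, data = d, span = span,
                                          degree = degree,
                                          control = stats::loess.control(surface = "direct")))
  target <- if (is.null(newdata)) {
    list(heights = heights, ages = ages, genders = genders)
  } else {
    stopifnot(all(c("heights", "ages", "genders") %in% names(newdata)))
    newdata
  }
  g <- as.character(target$genders)
  if (any(!g %in% names(fits)))
    stop("unseen gender level(s) in newdata: ",
         paste(setdiff(unique(g), names(fits)), collapse = ", "),
         call. = FALSE)
  pred <- numeric(length(g))
  for (lev in names(fits)) {
    sel <- g == lev
    if (any(sel))
      pred[sel] <- stats::predict(fits[[lev]],
                                  newdata = data.frame(a = target$ages[sel]))
  }
  (target$heights - pred) / pred
}

# -- model variants ----------------------------------------------------------

#' Describe a model variant for cross-validated benchmarking
#'
#' Three feature families are benchmarked under identical folds:
#' * `baseline` — gender indicator, age, residual height, BMI, operation
#'   length (5 features);
#' * `expert` — baseline plus one-hot expert cluster labels, one submodel per
#'   text field, probabilities averaged;
#' * `ai` — baseline plus soft cluster memberships of a text embedding, one
#'   submodel per field, probabilities averaged;
#' * `ensemble` — weighted average of other variants' predicted
#'   probabilities.
#'
#' @param name Unique display name.
#' @param type One of `"baseline"`, `"expert"`, `"ai"`, `"ensemble"`.
#' @param fields Text fields used (`"diagnosis"`, `"operation"`); per-field
#'   submodel probabilities are averaged.
#' @param embedder An [embedder_spec()] (ai only).
#' @param k,n_init Clustering parameters for ai variants (defaults 10 and
#'   100, the predictive settings).
#' @param mode Clustering mode for ai variants; `"euclidean"` is used
#'   automatically for Bag-of-Terms embedders.
#' @param components,weights Ensemble constituents (names of other variants)
#'   and their non-negative weights.
#' @return A list of class `cv_variant`.
#' @export
cv_variant <- function(name, type = c("baseline", "expert", "ai", "ensemble"),
                       fields = c("diagnosis", "operation"), embedder = NULL,
                       k = 10L, n_init = 100L, mode = NULL,
                       components = NULL, weights = NULL) {
  type <- match.arg(type)
  if (type == "ai" && !inherits(embedder, "embedder_spec"))
    stop("ai variants need an embedder_spec", call. = FALSE)
  if (type == "ensemble") {
    if (is.null(components) || is.null(weights) ||
        length(components) != length(weights))
      stop("ensemble variants need matching components and weights",
           call. = FALSE)
    if (any(weights < 0) || sum(weights) <= 0)
      stop("ensemble weights must be non-negative with positive sum",
           call. = FALSE)
  }
  if (is.null(mode) && type == "ai")
    mode <- if (identical(embedder$kind, "bot")) "euclidean" else "spherical"
  structure(list(name = name, type = type, fields = fields,
                 embedder = embedder, k = as.integer(k),
                 n_init = as.integer(n_init), mode = mode,
                 components = components, weights = weights),
            class = "cv_variant")
}

#' Assemble a feature block for one model variant
#'
#' @param cohort Cohort data frame (columns `gender`, `age_months`,
#'   `height_cm`, `weight_kg`, `optime_min`, plus expert label columns for
#'   the expert variant).
#' @param variant `"baseline"`, `"expert"` or `"ai"`.
#' @param field Text field for expert/ai variants (`"diagnosis"` or
#'   `"operation"`).
#' @param clustering A [spherical_kmeans()] fit over that field's embeddings
#'   (ai variant); its soft memberships become features.
#' @param embeddings The field's [embedding_matrix()] for the same rows (ai
#'   variant); soft memberships are computed from it against the fit's
#'   centroids.
#' @param residual Optional precomputed residual-height vector (otherwise
#'   computed from the cohort itself).
#' @return A list of class `feature_block`: `matrix` (n x p, no missing
#'   values), `names`, `provenance`.
#' @export
assemble_features <- function(cohort, variant = c("baseline", "expert", "ai"),
                              field = NULL, clustering = NULL,
                              embeddings = NULL, residual = NULL) {
  variant <- match.arg(variant)
  need <- c("gender", "age_months", "height_cm", "weight_kg", "optime_min")
  stopifnot(all(need %in% names(cohort)))
  if (is.null(residual))
    residual <- residual_height(cohort$height_cm, cohort$age_months,
                                cohort$gender)
  base <- cbind(
    gender_male = as.numeric(cohort$gender == "male"),
    age_months = cohort$age_months,
    residual_height = residual,
    bmi = compute_bmi(cohort$weight_kg, cohort$height_cm / 100),
    optime_min = cohort$optime_min)
  prov <- "baseline"
  m <- base
  if (variant == "expert") {
    col <- paste0("expert_", field)
    if (is.null(field) || !col %in% names(cohort))
      stop("expert variant needs an expert label column '", col, "'",
           call. = FALSE)
    lab <- factor(cohort[[col]])
    onehot <- stats::model.matrix(~ lab - 1)
    colnames(onehot) <- paste0("expert_", field, "_", levels(lab))
    m <- cbind(base, onehot)
    prov <- paste0("expert-onehot:", field)
  } else if (variant == "ai") {
    if (is.null(clustering))
      stop("ai variant needs a clustering fit", call. = FALSE)
    soft <- if (is.null(embeddings)) clustering$soft
            else soft_membership(embeddings, clustering)
    if (nrow(soft) != nrow(cohort))
      stop("soft membership rows do not match the cohort", call. = FALSE)
    colnames(soft) <- paste0("soft_", field, "_", seq_len(ncol(soft)))
    m <- cbind(base, soft)
    prov <- paste0("soft-membership:", field)
  }
  if (anyNA(m)) stop("feature block contains missing values", call. = FALSE)
  structure(list(matrix = m, names = colnames(m), provenance = prov),
            class = "feature_block")
}

#' Fit a binary classifier and predict test-set probabilities
#'
#' Uniform contract over classifiers: train on `(x_train, y_train)`, return
#' positive-class probabilities for `x_test`. A training fold containing a
#' single class is recorded as degenerate and predicts the constant class
#' rate.
#'
#' @param x_train,x_test Numeric feature matrices with identical columns.
#' @param y_train Binary 0/1 labels.
#' @param classifier `"logistic"` (default, via `stats::glm.fit`) or
#'   `"random_forest"` (requires the randomForest package).
#' @return Numeric probabilities in \[0, 1\]; attribute `"degenerate"` is
#'   `TRUE` for a single-class fold.
#' @export
fit_predict_binary <- function(x_train, y_train, x_test,
                               classifier = c("logistic", "random_forest")) {
  classifier <- match.arg(classifier)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (length(unique(y_train)) < 2L) {
    p <- rep(mean(y_train), nrow(x_test))
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  if (classifier == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, x_train), y_train,
                     family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0  # collinear columns drop out
    p <- as.numeric(stats::plogis(cbind(1, x_test) %*% beta))
  } else {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("classifier 'random_forest' requires the randomForest package",
           call. = FALSE)
    fit <- randomForest::randomForest(x_train, factor(y_train, levels = 0:1))
    p <- stats::predict(fit, x_test, type = "prob")[, "1"]
  }
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Average the predicted probabilities of the two per-field models
#'
#' The diagnosis-based and operation-based submodels are combined by
#' elementwise averaging of their predicted probabilities.
#'
#' @param p_diagnosis,p_operation Probability vectors of equal length.
#' @return Elementwise mean.
#' @export
average_field_models <- function(p_diagnosis, p_operation) {
  if (length(p_diagnosis) != length(p_operation))
    stop("probability vectors must have equal length", call. = FALSE)
  (p_diagnosis + p_operation) / 2
}

#' Weighted-average probability ensemble
#'
#' @param probs List of probability vectors of equal length.
#' @param weights Non-negative weights, one per model, summing to > 0.
#'   The AI ensemble uses weights `c(2, 1)`; adding the expert model with a
#'   weight one tenth of the first AI weight gives `c(2, 1, 0.2)`.
#' @return Weighted elementwise mean.
#' @export
ensemble_predict <- function(probs, weights) {
  stopifnot(is.list(probs), length(probs) == length(weights))
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and sum to > 0", call. = FALSE)
  len <- unique(vapply(probs, length, integer(1)))
  if (length(len) != 1L)
    stop("probability vectors must have equal length", call. = FALSE)
  Reduce(`+`, Map(`*`, probs, weights)) / sum(weights)
}

# rank-based ROC-AUC (Mann-Whitney), ties handled by midranks
.roc_auc <- function(prob, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(prob)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold-averaged classification metrics
#'
#' ROC-AUC is threshold-free; accuracy, precision, F1, sensitivity and
#' specificity are computed at each probability cutoff (positive iff
#' probability >= threshold) and averaged across the cutoffs. When a cutoff
#' yields no predicted positives, precision (and hence F1) contributes 0 to
#' the average; the number of such cutoffs is recorded. Averaging over the
#' 0.1-0.9 grid deliberately includes non-optimal cutoffs, so averaged
#' precision/sensitivity/F1 run lower than their single-best-threshold
#' values.
#'
#' @param prob Predicted probabilities.
#' @param labels Binary 0/1 labels containing both classes.
#' @param thresholds Strictly increasing cutoffs in (0, 1); default
#'   `seq(0.1, 0.9, by = 0.1)`.
#' @return Named list: `roc_auc`, `accuracy`, `precision`, `f1`,
#'   `sensitivity`, `specificity`, `n_zero_positive_thresholds`.
#' @export
threshold_averaged_metrics <- function(prob, labels,
                                       thresholds = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(length(prob) == length(labels))
  if (!all(labels %in% 0:1)) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("labels contain a single class", call. = FALSE)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must be strictly increasing within (0, 1)",
         call. = FALSE)
  acc <- prec <- f1 <- sens <- spec <- numeric(length(thresholds))
  zero_pos <- 0L
  for (i in seq_along(thresholds)) {
    pred <- as.integer(prob >= thresholds[i])
    tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
    fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
    acc[i] <- (tp + tn) / length(labels)
    if (tp + fp == 0) { prec[i] <- 0; zero_pos <- zero_pos + 1L }
    else prec[i] <- tp / (tp + fp)
    sens[i] <- tp / (tp + fn)
    spec[i] <- tn / (tn + fp)
    f1[i] <- if (prec[i] + sens[i] == 0) 0
             else 2 * prec[i] * sens[i] / (prec[i] + sens[i])
  }
  list(roc_auc = .roc_auc(prob, labels), accuracy = mean(acc),
       precision = mean(prec), f1 = mean(f1), sensitivity = mean(sens),
       specificity = mean(spec), n_zero_positive_thresholds = zero_pos)
}

#' Configuration for repeated cross-validation
#'
#' @param repeats Number of repeats (default 250).
#' @param folds Folds per repeat (default 10).
#' @param master_seed Seed fixing the fold splits and any classifier
#'   randomness; identical seeds give identical reports.
#' @param classifier Classifier id for [fit_predict_binary()].
#' @param thresholds Cutoff grid for [threshold_averaged_metrics()].
#' @param stratified Stratify folds by outcome (default `FALSE`: plain
#'   repeated k-fold).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(repeats = 250L, folds = 10L, master_seed = 1L,
                      classifier = "logistic",
                      thresholds = seq(0.1, 0.9, by = 0.1),
                      stratified = FALSE) {
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must be strictly increasing within (0, 1)",
         call. = FALSE)
  structure(list(repeats = as.integer(repeats), folds = folds,
                 master_seed = as.integer(master_seed),
                 classifier = classifier, thresholds = thresholds,
                 stratified = stratified),
            class = "cv_config")
}

.fold_ids <- function(n, folds, stratified, labels) {
  if (!stratified) return(sample(rep_len(seq_len(folds), n)))
  ids <- integer(n)
  for (cl in unique(labels)) {
    sel <- which(labels == cl)
    ids[sel] <- sample(rep_len(seq_len(folds), length(sel)))
  }
  ids
}

# Build per-field prediction machinery for a variant within one fold (or
# globally). Returns test-set probabilities.
.variant_probs <- function(variant, cohort, labels, train, test, config,
                           global, residual_all) {
  if (variant$type == "baseline") {
    fb <- assemble_features(cohort, "baseline", residual = residual_all)
    return(fit_predict_binary(fb$matrix[train, , drop = FALSE],
                              labels[train],
                              fb$matrix[test, , drop = FALSE],
                              config$classifier))
  }
  per_field <- lapply(variant$fields, function(fl) {
    if (variant$type == "expert") {
      fb <- assemble_features(cohort, "expert", field = fl,
                              residual = residual_all)
      return(fit_predict_binary(fb$matrix[train, , drop = FALSE],
                                labels[train],
                                fb$matrix[test, , drop = FALSE],
                                config$classifier))
    }
    # ai variant
    g <- global[[variant$name]][[fl]]
    fb <- assemble_features(cohort, "ai", field = fl,
                            clustering = g$fit, embeddings = g$emb,
                            residual = residual_all)
    fit_predict_binary(fb$matrix[train, , drop = FALSE], labels[train],
                       fb$matrix[test, , drop = FALSE], config$classifier)
  })
  Reduce(`+`, per_field) / length(per_field)
}

# fold-scope version: refits text vocabulary, embedding, clustering and the
# height smooth on training rows only, projecting test rows onto them.
.variant_probs_fold <- function(variant, cohort, labels, train, test,
                                config) {
  res_train <- residual_height(cohort$height_cm[train],
                               cohort$age_months[train],
                               cohort$gender[train])
  res_test <- residual_height(cohort$height_cm[train],
                              cohort$age_months[train],
                              cohort$gender[train],
                              newdata = list(heights = cohort$height_cm[test],
                                             ages = cohort$age_months[test],
                                             genders = cohort$gender[test]))
  fit_one <- function(feats_train, feats_test)
    fit_predict_binary(feats_train, labels[train], feats_test,
                       config$classifier)
  base_tr <- assemble_features(cohort[train, ], "baseline",
                               residual = res_train)$matrix
  base_te <- assemble_features(cohort[test, ], "baseline",
                               residual = res_test)$matrix
  if (variant$type == "baseline") return(fit_one(base_tr, base_te))
  per_field <- lapply(variant$fields, function(fl) {
    if (variant$type == "expert") {
      lab <- factor(cohort[[paste0("expert_", fl)]])
      oh <- stats::model.matrix(~ lab - 1)
      return(fit_one(cbind(base_tr, oh[train, , drop = FALSE]),
                     cbind(base_te, oh[test, , drop = FALSE])))
    }
    spec <- variant$embedder
    if (identical(spec$kind, "bot")) {
      vocab <- build_vocabulary(lapply(cohort[[fl]][train], parse_field))
      spec <- embedder_spec("bot", name = spec$name,
                            hyperparameters = list(vocabulary = vocab))
    }
    emb_tr <- embed_texts(cohort[[fl]][train], spec)
    emb_te <- embed_texts(cohort[[fl]][test], spec)
    fit <- spherical_kmeans(emb_tr, k = variant$k, n_init = variant$n_init,
                            seed = config$master_seed, mode = variant$mode)
    fit_one(cbind(base_tr, fit$soft),
            cbind(base_te, soft_membership(emb_te, fit)))
  })
  Reduce(`+`, per_field) / length(per_field)
}

#' Repeated k-fold cross-validated benchmarking of model variants
#'
#' Runs `repeats` x `folds` cross-validation with fold memberships shared
#' across every variant (identical folds make paired comparisons valid) and
#' records threshold-averaged metrics per (repeat, fold, model). At the
#' defaults (250 repeats, 10 folds) this yields 2500 metric records per
#' variant.
#'
#' By default (`scope = "global"`) embeddings are clustered once on the full
#' cohort before cross-validation — matching the single pre-CV cluster set
#' of the benchmarked protocol, but letting test rows influence the cluster
#' geometry; a warning notes this. `scope = "fold"` refits the vocabulary,
#' embeddings, clustering and height smooth on each training fold only and
#' projects the test rows, at a leakage-free but slower setting.
#'
#' @param cohort Cohort data frame including the outcome column.
#' @param variants List of [cv_variant()]s (ensembles may reference earlier
#'   variants by name).
#' @param config A [cv_config()].
#' @param outcome Name of the binary outcome column (default
#'   `"kdigo_binary"`).
#' @param scope `"global"` or `"fold"` (see Details).
#' @return An object of class `cv_report`: long data frame `records` with
#'   columns repeat_, fold, model and the metric columns, plus `config`,
#'   `variants` and `fold_ids` (n x repeats matrix).
#' @export
run_repeated_cv <- function(cohort, variants, config = cv_config(),
                            outcome = "kdigo_binary",
                            scope = c("global", "fold")) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(cohort), length(variants) >= 1L)
  if (inherits(variants[[1L]], "cv_variant") == FALSE)
    stop("variants must be a list of cv_variant objects", call. = FALSE)
  if (!outcome %in% names(cohort))
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  labels <- cohort[[outcome]]
  if (!all(labels %in% 0:1)) stop("outcome must be binary 0/1", call. = FALSE)
  n <- nrow(cohort)
  if (n < config$folds) stop("fewer rows than folds", call. = FALSE)
  vnames <- vapply(variants, `[[`, character(1), "name")
  if (anyDuplicated(vnames)) stop("variant names must be unique", call. = FALSE)
  names(variants) <- vnames

  # global-scope preparation: one clustering per ai variant and field,
  # fitted on all rows before CV (the benchmarked protocol; leakage-prone)
  residual_all <- NULL
  global <- list()
  if (scope == "global") {
    residual_all <- residual_height(cohort$height_cm, cohort$age_months,
                                    cohort$gender)
    ai <- Filter(function(v) v$type == "ai", variants)
    if (length(ai))
      warning("scope = 'global' clusters embeddings on all rows before ",
              "cross-validation (the benchmarked protocol); use scope = ",
              "'fold' for a leakage-free refit", call. = FALSE)
    for (v in ai) {
      global[[v$name]] <- lapply(stats::setNames(v$fields, v$fields),
                                 function(fl) {
        emb <- embed_texts(cohort[[fl]], v$embedder)
        list(emb = emb,
             fit = spherical_kmeans(emb, k = v$k, n_init = v$n_init,
                                    seed = config$master_seed,
                                    mode = v$mode))
      })
    }
  }

  base_variants <- Filter(function(v) v$type != "ensemble", variants)
  ensembles <- Filter(function(v) v$type == "ensemble", variants)
  for (e in ensembles)
    if (!all(e$components %in% vnames))
      stop("ensemble '", e$name, "' references unknown components",
           call. = FALSE)

  records <- list()
  fold_matrix <- matrix(NA_integer_, n, config$repeats)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$master_seed)
  for (r in seq_len(config$repeats)) {
    fold_id <- .fold_ids(n, config$folds, config$stratified, labels)
    fold_matrix[, r] <- fold_id
    for (f in seq_len(config$folds)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      probs <- list()
      for (v in base_variants) {
        probs[[v$name]] <- if (scope == "global")
          .variant_probs(v, cohort, labels, train, test, config, global,
                         residual_all)
        else .variant_probs_fold(v, cohort, labels, train, test, config)
      }
      for (e in ensembles)
        probs[[e$name]] <- ensemble_predict(probs[e$components], e$weights)
      for (nm in names(probs)) {
        m <- threshold_averaged_metrics(probs[[nm]], labels[test],
                                        config$thresholds)
        records[[length(records) + 1L]] <- data.frame(
          repeat_ = r, fold = f, model = nm,
          roc_auc = m$roc_auc, accuracy = m$accuracy,
          precision = m$precision, f1 = m$f1,
          sensitivity = m$sensitivity, specificity = m$specificity)
      }
    }
  }
  structure(list(records = do.call(rbind, records), config = config,
                 variants = variants, fold_ids = fold_matrix,
                 scope = scope),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Repeated CV report: ", x$config$repeats, " x ", x$config$folds,
      " folds, ", length(unique(x$records$model)), " model(s), scope: ",
      x$scope, "\n", sep = "")
  print(summary(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize a CV report as a model-by-metric table
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return Data frame: one row per model, mean of each metric over all
#'   (repeat, fold) records.
#' @export
summary.cv_report <- function(object, ...) {
  metrics <- c("roc_auc", "accuracy", "precision", "f1", "sensitivity",
               "specificity")
  agg <- stats::aggregate(object$records[metrics],
                          by = list(model = object$records$model), mean)
  agg[order(-agg$roc_auc), ]
}

#' Write a CV report as delimited tables
#'
#' Emits the long per-(repeat, fold, model) record table and the
#' model-by-metric summary.
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$records, file.path(dir, "cv_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary(report), file.path(dir, "cv_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Paired t-test between two models' per-fold metrics
#'
#' Pairs the (repeat, fold) records of two models from the same report —
#' valid because fold memberships are identical across models — and tests
#' the mean difference `A - B` of the chosen metric.
#'
#' @param report A `cv_report`.
#' @param model_a,model_b Model names in the report.
#' @param metric Metric column (default `"roc_auc"`).
#' @param alternative `"two.sided"`, `"greater"` (A better) or `"less"`.
#' @return List with `t`, `p`, `mean_diff`, `df`, `alternative`.
#' @export
paired_fold_ttest <- function(report, model_a, model_b, metric = "roc_auc",
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(report, "cv_report"))
  rec <- report$records
  a <- rec[rec$model == model_a, ]
  b <- rec[rec$model == model_b, ]
  if (!nrow(a) || !nrow(b)) stop("unknown model name", call. = FALSE)
  key_a <- paste(a$repeat_, a$fold); key_b <- paste(b$repeat_, b$fold)
  if (!identical(sort(key_a), sort(key_b)))
    stop("records of the two models are not matched", call. = FALSE)
  a <- a[order(a$repeat_, a$fold), ]; b <- b[order(b$repeat_, b$fold), ]
  d <- a[[metric]] - b[[metric]]
  if (stats::sd(d) == 0) {
    return(list(t = 0, p = if (alternative == "two.sided") 1 else 0.5,
                mean_diff = mean(d), df = length(d) - 1,
                alternative = alternative))
  }
  tt <- stats::t.test(a[[metric]], b[[metric]], paired = TRUE,
                      alternative = alternative)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       df = unname(tt$parameter), alternative = alternative)
}
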