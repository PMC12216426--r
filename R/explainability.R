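# Reverse mapping from the numeric embedding space to natural language:
# clusters are presented as grouped member texts in a prompt, a
# text-completion model (or the deterministic stub labeler) returns one
# structured label per cluster, labels are aligned across runs, and cluster
# membership is rank-correlated with the AKI outcomes.

.field_prefix <- c(diagnosis = "Diagnoses", operation = "Operations")

#' Build a cluster-labeling prompt
#'
#' The preamble states the row count, describes the text fields, gives the
#' group count and asks for labels that are representative of their members
#' and distinct from each other. The body lists every member under its
#' `"Group N:"` heading; when both fields are used, each line prefixes the
#' field name and joins the fields with `" || "` (operations first, then
#' diagnoses, mirroring how the records read clinically). Output is
#' byte-deterministic for fixed inputs.
#'
#' @param cohort Cohort data frame with the text columns.
#' @param assignment Integer cluster assignment covering every row.
#' @param fields Subset of `c("diagnosis", "operation")`.
#' @param member_cap Optional per-cluster cap on listed members; capped
#'   groups end with a `"..."` marker (default `NULL`, no cap).
#' @return A list of class `label_prompt`: `text` (the full prompt),
#'   `preamble`, `k`, `token_estimate` (chars / 4).
#' @export
build_label_prompt <- function(cohort, assignment,
                               fields = c("operation", "diagnosis"),
                               member_cap = NULL) {
  stopifnot(is.data.frame(cohort),
            length(assignment) == nrow(cohort),
            all(fields %in% c("diagnosis", "operation")))
  k <- max(assignment)
  n <- nrow(cohort)
  fdesc <- c(
    operation = "one or more surgical procedures, separated by ';'",
    diagnosis = "one or more diagnoses, separated by ';'")
  preamble <- paste0(
    "The following is a list of ", n, " pediatric patients undergoing ",
    "cardiopulmonary bypass. Each row contains ",
    paste(fdesc[fields], collapse = ". These are followed by "),
    ". Patients have been grouped into ", k, " groups, according to their ",
    "diagnoses and procedures. Please suggest group labels that are ",
    "representative of their members, and also distinct from each other:")
  render_row <- function(i) {
    paste(vapply(fields, function(fl)
      paste0(.field_prefix[[fl]], ": ", cohort[[fl]][i]), character(1)),
      collapse = " || ")
  }
  sections <- character(k)
  for (g in seq_len(k)) {
    members <- which(assignment == g)
    if (!length(members))
      warning("cluster ", g, " has no members", call. = FALSE)
    lines <- vapply(members, render_row, character(1))
    capped <- FALSE
    if (!is.null(member_cap) && length(lines) > member_cap) {
      lines <- lines[seq_len(member_cap)]
      capped <- TRUE
    }
    sections[g] <- paste0("Group ", g, ":\n",
                          paste(lines, collapse = "\n"),
                          if (capped) "\n...")
  }
  text <- paste0(preamble, "\n\n", paste(sections, collapse = "\n=======\n"))
  structure(list(text = text, preamble = preamble, k = k,
                 token_estimate = ceiling(nchar(text) / 4)),
            class = "label_prompt")
}

#' @export
print.label_prompt <- function(x, ...) {
  cat("<label_prompt> ", x$k, " groups, ~", x$token_estimate, " tokens\n",
      sep = "")
  invisible(x)
}

#' Parse a structured cluster-label response
#'
#' Labelers (LLM adapters or the stub) must answer with a JSON array of
#' objects `{group_number, short_label, long_label}` — the minimal
#' structured-output schema — with exactly one label per cluster.
#'
#' @param response JSON string.
#' @param k Expected number of clusters.
#' @param source Provenance tag, e.g. `"stub"` or `"adapter:openai"`.
#' @param run_id Identifier for the clustering run being labelled.
#' @return A list of class `cluster_label_set`: data frame `labels`
#'   (group_number, short_label, long_label), `source`, `run_id`.
#' @export
parse_label_response <- function(response, k, source = "stub",
                                 run_id = 1L) {
  x <- tryCatch(jsonlite::fromJSON(response, simplifyDataFrame = TRUE),
                error = function(e)
                  stop("label response is not valid JSON: ",
                       conditionMessage(e), call. = FALSE))
  need <- c("group_number", "short_label", "long_label")
  if (!is.data.frame(x) || !all(need %in% names(x)))
    stop("label response must be an array of {group_number, short_label, ",
         "long_label} objects", call. = FALSE)
  if (anyDuplicated(x$group_number))
    stop("duplicate group_number(s): ",
         paste(unique(x$group_number[duplicated(x$group_number)]),
               collapse = ", "), call. = FALSE)
  if (!setequal(x$group_number, seq_len(k)))
    stop("expected exactly one label for each of groups 1..", k,
         call. = FALSE)
  x <- x[order(x$group_number), need]
  structure(list(labels = x, source = source, run_id = run_id),
            class = "cluster_label_set")
}

#' @export
print.cluster_label_set <- function(x, ...) {
  cat("<cluster_label_set> run ", x$run_id, " (", x$source, ")\n", sep = "")
  print(x$labels[c("group_number", "short_label")], row.names = FALSE)
  invisible(x)
}

#' Deterministic stub labeler
#'
#' Offline fallback behind the labeler contract: each cluster is labelled by
#' its three most over-represented codes, ranked by lift (within-cluster code
#' frequency over corpus frequency). Returns the same JSON schema an LLM
#' adapter would, so the prompt/parse round trip is exercised without any
#' network call — and the labels are genuinely informative on
#' standardized-code data.
#'
#' @param cohort Cohort data frame with the text columns.
#' @param assignment Integer cluster assignment.
#' @param fields Text fields to pool codes from.
#' @param top Number of codes per label (default 3).
#' @return JSON string parseable by [parse_label_response()].
#' @export
stub_labeler <- function(cohort, assignment,
                         fields = c("diagnosis", "operation"), top = 3L) {
  k <- max(assignment)
  seqs <- lapply(seq_len(nrow(cohort)), function(i)
    unique(unlist(lapply(fields, function(fl)
      parse_field(cohort[[fl]][i])$codes))))
  corpus_freq <- table(unlist(seqs)) / length(seqs)
  labels <- lapply(seq_len(k), function(g) {
    members <- seqs[assignment == g]
    if (!length(members))
      return(list(group_number = g, short_label = paste0("empty-", g),
                  long_label = "no members"))
    freq <- table(unlist(members)) / length(members)
    lift <- freq / as.numeric(corpus_freq[names(freq)])
    ord <- order(-lift, -freq, names(freq))
    picks <- names(freq)[ord][seq_len(min(top, length(freq)))]
    list(group_number = g,
         short_label = paste(picks, collapse = " + "),
         long_label = paste0("over-represented codes (by lift): ",
                             paste(picks, collapse = ", ")))
  })
  as.character(jsonlite::toJSON(labels, auto_unbox = TRUE))
}

#' Align cluster labels across repeated clustering runs
#'
#' Maps every run's clusters onto the first run's ids via
#' [greedy_cluster_mapping()] and tabulates the labels so that each row of
#' the result is one run-1 cluster and each column one run.
#'
#' @param runs List of `list(assignment = , labels = cluster_label_set)`;
#'   all assignments must cover the same rows.
#' @return A list of class `aligned_labels`: `table` (k x runs character
#'   matrix of short labels), `mappings`, `pair_overlap` (data frame of
#'   per-pair greedy overlap fractions).
#' @export
align_labels <- function(runs) {
  stopifnot(length(runs) >= 2L)
  n <- length(runs[[1L]]$assignment)
  if (!all(vapply(runs, function(r) length(r$assignment) == n, logical(1))))
    stop("assignments cover different row sets", call. = FALSE)
  k <- max(runs[[1L]]$assignment)
  mappings <- lapply(seq_along(runs), function(r)
    greedy_cluster_mapping(runs[[1L]]$assignment, runs[[r]]$assignment))
  tab <- matrix(NA_character_, k, length(runs),
                dimnames = list(paste0("cluster_", seq_len(k)),
                                vapply(runs, function(r)
                                  paste0("run_", r$labels$run_id),
                                  character(1))))
  for (r in seq_along(runs)) {
    map <- mappings[[r]]$mapping
    lab <- runs[[r]]$labels$labels
    for (g in seq_len(k)) {
      target <- map[as.character(g)]
      if (!is.na(target))
        tab[g, r] <- lab$short_label[lab$group_number == as.integer(target)]
    }
  }
  pr <- utils::combn(length(runs), 2)
  pair_overlap <- data.frame(
    run_a = pr[1, ], run_b = pr[2, ],
    overlap = apply(pr, 2, function(ij)
      greedy_cluster_mapping(runs[[ij[1]]]$assignment,
                             runs[[ij[2]]]$assignment)$overlap_fraction))
  structure(list(table = tab, mappings = mappings,
                 pair_overlap = pair_overlap),
            class = "aligned_labels")
}

#' @export
print.aligned_labels <- function(x, ...) {
  cat("<aligned_labels> ", nrow(x$table), " clusters x ", ncol(x$table),
      " runs; mean pairwise overlap ",
      sprintf("%.3f", mean(x$pair_overlap$overlap)), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Kendall rank correlation (tau-b)
#'
#' Tau-b handles the heavy ties that arise when one variable is a binary
#' membership indicator. For a binary `x` an O(n log n) rank formulation is
#' used; otherwise pairs are enumerated (quadratic, fine at cohort scale).
#' The p-value uses the normal approximation to the tau-b null distribution.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `tau`, `p` (two-sided), `n`; `tau` is `NA` when either
#'   variable is constant.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(tau = NA_real_, p = NA_real_, n = n))
  ux <- sort(unique(x))
  if (length(ux) == 2L) {
    g <- as.integer(x == ux[2L])
    n1 <- sum(g); n0 <- n - n1
    r <- rank(y)
    # C - D = 2 * (rank-sum of group 1 above its within-group expectation)
    s <- sum(r[g == 1L]) - n1 * (n1 + 1) / 2
    cd <- 2 * s - n0 * n1
    tx <- n0 * (n0 - 1) / 2 + n1 * (n1 - 1) / 2
  } else {
    cd <- 0
    for (i in seq_len(n - 1L)) {
      dx <- x[(i + 1L):n] - x[i]; dy <- y[(i + 1L):n] - y[i]
      cd <- cd + sum(sign(dx) * sign(dy))
    }
    tcnt <- table(x)
    tx <- sum(tcnt * (tcnt - 1) / 2)
  }
  tycnt <- table(y)
  ty <- sum(tycnt * (tycnt - 1) / 2)
  n_pairs <- n * (n - 1) / 2
  denom <- sqrt((n_pairs - tx) * (n_pairs - ty))
  if (denom == 0) return(list(tau = NA_real_, p = NA_real_, n = n))
  tau <- cd / denom
  # normal approximation with tie correction (as in cor.test's tau-b test)
  txc <- as.numeric(table(x)); tyc <- as.numeric(tycnt)
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(txc * (txc - 1) * (2 * txc + 5))
  vy <- sum(tyc * (tyc - 1) * (2 * tyc + 5))
  v1 <- sum(txc * (txc - 1)) * sum(tyc * (tyc - 1)) / (2 * n * (n - 1))
  v2 <- sum(txc * (txc - 1) * (txc - 2)) *
    sum(tyc * (tyc - 1) * (tyc - 2)) / (9 * n * (n - 1) * (n - 2))
  var_cd <- (v0 - vt - vy) / 18 + v1 + v2
  z <- cd / sqrt(var_cd)
  list(tau = tau, p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Rank correlation of cluster membership with AKI outcomes
#'
#' For every (outcome, cluster) pair, computes Kendall's tau-b between the
#' binary indicator of membership in that cluster and the outcome, with raw
#' and Bonferroni-adjusted significance at `m = outcomes x clusters` tests.
#' When operation times are supplied, clusters are ordered by decreasing
#' mean operation time (the display order linking cluster risk to bypass
#' duration).
#'
#' @param assignment Integer cluster assignment.
#' @param outcomes Data frame of outcome columns (defaults to the five AKI
#'   outcomes of [compute_aki_outcomes()], minus `row_id`).
#' @param outcome_cols Which columns of `outcomes` to use.
#' @param alpha Significance level before adjustment (default 0.05).
#' @param operation_time Optional per-row operation times for cluster
#'   ordering.
#' @return A list of class `correlation_table`: data frame `table` (outcome,
#'   cluster, tau, n, p, significant_raw, significant_bonferroni), `m`,
#'   `alpha`, `cluster_order`, `mean_optime`.
#' @export
outcome_cluster_correlation <- function(assignment, outcomes,
                                        outcome_cols = setdiff(names(outcomes),
                                                               "row_id"),
                                        alpha = 0.05,
                                        operation_time = NULL) {
  stopifnot(is.data.frame(outcomes),
            length(assignment) == nrow(outcomes))
  k <- max(assignment)
  m <- length(outcome_cols) * k
  rows <- list()
  for (oc in outcome_cols) {
    y <- outcomes[[oc]]
    for (g in seq_len(k)) {
      member <- as.integer(assignment == g)
      kt <- kendall_tau(member, y)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, cluster = g, tau = kt$tau, n = kt$n, p = kt$p,
        significant_raw = !is.na(kt$p) && kt$p < alpha,
        significant_bonferroni = !is.na(kt$p) && kt$p < alpha / m,
        note = if (is.na(kt$tau)) "constant variable: tau undefined" else "")
    }
  }
  tab <- do.call(rbind, rows)
  cluster_order <- seq_len(k)
  mean_optime <- NULL
  if (!is.null(operation_time)) {
    mean_optime <- tapply(operation_time, factor(assignment,
                                                 levels = seq_len(k)), mean)
    cluster_order <- order(-mean_optime)
  }
  structure(list(table = tab, m = m, alpha = alpha,
                 cluster_order = cluster_order, mean_optime = mean_optime),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("<correlation_table> ", x$m, " tests (Bonferroni threshold ",
      format(x$alpha / x$m, digits = 3), ")\n", sep = "")
  print(x$table[x$table$significant_bonferroni,
                c("outcome", "cluster", "tau", "p")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Build a blind partition-comparison prompt
#'
#' Presents two partitions of the same records as "Partition 1" and
#' "Partition 2" and asks for a summary of their differences. With
#' `blind = TRUE` (default) nothing in the prompt reveals which partition is
#' machine-derived and which is expert-derived.
#'
#' @param cohort Cohort data frame with the text columns.
#' @param assignment_a,assignment_b Cluster assignments over the same rows.
#' @param fields Text fields to render.
#' @param blind Suppress provenance (default `TRUE`).
#' @param names_ab Partition names used when `blind = FALSE`.
#' @return A single prompt string; deterministic for fixed inputs.
#' @export
build_partition_comparison_prompt <- function(cohort, assignment_a,
                                              assignment_b,
                                              fields = c("operation",
                                                         "diagnosis"),
                                              blind = TRUE,
                                              names_ab = c("AI", "expert")) {
  stopifnot(length(assignment_a) == nrow(cohort),
            length(assignment_b) == nrow(cohort))
  pnames <- if (blind) c("Partition 1", "Partition 2") else names_ab
  render <- function(assignment, label) {
    k <- max(assignment)
    sections <- vapply(seq_len(k), function(g) {
      members <- which(assignment == g)
      lines <- vapply(members, function(i)
        paste(vapply(fields, function(fl)
          paste0(.field_prefix[[fl]], ": ", cohort[[fl]][i]), character(1)),
          collapse = " || "), character(1))
      paste0("Group ", g, ":\n", paste(lines, collapse = "\n"))
    }, character(1))
    paste0("## ", label, " (", k, " groups)\n\n",
           paste(sections, collapse = "\n=======\n"))
  }
  paste0(
    "Two alternative groupings (partitions) of the same ", nrow(cohort),
    " pediatric cardiopulmonary-bypass patients are listed below. ",
    "Please summarise and explain the differences between ", pnames[1],
    " and ", pnames[2], ".\n\n",
    render(assignment_a, pnames[1]), "\n\n",
    render(assignment_b, pnames[2]))
}
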