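#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two labelings of the same items, adjusted
#' so that the expected value under random labellings (with the observed
#' cluster sizes) is 0 and the maximum is 1. Computed from the contingency
#' table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - E}{\tfrac12(\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}) - E},\quad
#'       E = \frac{\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}}{\binom{n}{2}}}
#'
#' Invariant to permutations of either labeling; symmetric in its arguments.
#'
#' @param a,b Label vectors of equal length (>= 2); any atomic type.
#' @return A number <= 1; 1 iff the partitions are identical up to
#'   relabeling, about 0 for independent partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  ct <- .contingency(a, b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions degenerate
  (sum_ij - expected) / (max_index - expected)
}

.contingency <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("need at least 2 items", call. = FALSE)
  table(factor(a), factor(b))
}

# Expected mutual information between two partitions under the permutation
# model (fixed marginals, random pairing), in nats. Hypergeometric sum over
# feasible cell counts, with lgamma for stability. Terms are accumulated and
# summed in sorted order so the result is bit-identical under argument swap
# (the term multiset is symmetric; the enumeration order is not).
.expected_mi <- function(a_sizes, b_sizes, n) {
  terms <- numeric(0)
  lg <- lgamma
  for (ai in a_sizes) {
    for (bj in b_sizes) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      # explicit pairwise grouping keeps each term bit-identical when the
      # roles of ai and bj swap (two-operand addition commutes exactly)
      num <- (lg(ai + 1) + lg(n - ai + 1)) + (lg(bj + 1) + lg(n - bj + 1))
      den <- (lg(n + 1) + lg(nij + 1)) +
        (lg(ai - nij + 1) + lg(bj - nij + 1)) + lg(n - ai - bj + nij + 1)
      log_term <- num - den
      terms <- c(terms, nij / n * log(n * nij / (ai * bj)) * exp(log_term))
    }
  }
  sum(sort(terms))
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information between the two labelings, corrected by its expected
#' value under the permutation model (random labellings with the observed
#' cluster sizes) and normalized by the maximum of the two cluster entropies:
#' \deqn{AMI = \frac{MI - E[MI]}{\max(H(A), H(B)) - E[MI]}}
#'
#' Upper bound 1 (identical partitions); close to 0 for partitions with no
#' concordance.
#'
#' @inheritParams adjusted_rand_index
#' @return A number <= 1.
#' @export
adjusted_mutual_information <- function(a, b) {
  ct <- .contingency(a, b)
  n <- sum(ct)
  pa <- rowSums(ct) / n
  pb <- colSums(ct) / n
  # sorted summation keeps every quantity bit-identical under argument swap
  ha <- -sum(sort(pa[pa > 0] * log(pa[pa > 0])))
  hb <- -sum(sort(pb[pb > 0] * log(pb[pb > 0])))
  p <- ct / n
  nz <- p > 0
  mi <- sum(sort(p[nz] * log(p[nz] / (pa[row(ct)[nz]] * pb[col(ct)[nz]]))))
  if (ha == 0 && hb == 0) return(1)  # both trivial partitions: identical
  emi <- .expected_mi(rowSums(ct), colSums(ct), n)
  denom <- max(ha, hb) - emi
  if (denom == 0) return(0)
  (mi - emi) / denom
}

#' Score the agreement of two partitions
#'
#' Convenience wrapper returning both chance-adjusted metrics at once.
#'
#' @inheritParams adjusted_rand_index
#' @return A list with `ari`, `ami` and `n`.
#' @export
partition_pair_score <- function(a, b) {
  list(ari = adjusted_rand_index(a, b),
       ami = adjusted_mutual_information(a, b),
       n = length(a))
}

#' Greedily align the clusters of two partitions by member overlap
#'
#' Repeatedly matches the (cluster-in-A, cluster-in-B) pair sharing the most
#' members among the still-unmatched clusters, until one side is exhausted.
#' Ties break to the lowest (A id, B id). The overlap fraction is the number
#' of items sitting in matched pairs divided by n, so it is 1 exactly when
#' the partitions are identical up to relabeling.
#'
#' @param a,b Label vectors of equal length.
#' @return A list of class `cluster_mapping`: `mapping` (named character
#'   vector, A-cluster id -> B-cluster id, injective), `overlap_fraction`,
#'   `unmatched_a`, `unmatched_b`, `n`.
#' @export
greedy_cluster_mapping <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors must have equal length", call. = FALSE)
  ct <- table(factor(a), factor(b))
  ra <- rownames(ct); cb <- colnames(ct)
  live_r <- rep(TRUE, nrow(ct)); live_c <- rep(TRUE, ncol(ct))
  mapping <- character(0)
  matched <- 0
  while (any(live_r) && any(live_c)) {
    sub <- ct[live_r, live_c, drop = FALSE]
    # ties break to the lowest (A id, B id), in that order
    hits <- which(sub == max(sub), arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]
    j <- hits[1L, 2L]
    ai <- rownames(sub)[i]; bj <- colnames(sub)[j]
    mapping[ai] <- bj
    matched <- matched + sub[i, j]
    live_r[match(ai, ra)] <- FALSE
    live_c[match(bj, cb)] <- FALSE
  }
  structure(list(mapping = mapping,
                 overlap_fraction = matched / length(a),
                 unmatched_a = ra[live_r], unmatched_b = cb[live_c],
                 n = length(a)),
            class = "cluster_mapping")
}

#' @export
print.cluster_mapping <- function(x, ...) {
  cat("<cluster_mapping> ", length(x$mapping), " matched pair(s), overlap ",
      sprintf("%.3f", x$overlap_fraction), "\n", sep = "")
  for (i in seq_along(x$mapping))
    cat("  ", names(x$mapping)[i], " -> ", x$mapping[i], "\n", sep = "")
  invisible(x)
}

.seed_stream <- function(seed, i) {
  as.integer((as.numeric(seed) * 131071 + i * 7919) %% 2147483629)
}

#' Benchmark clustering consistency against expert labels
#'
#' Runs spherical (or standard) k-means `runs` times, each run keeping the
#' best of `inits_per_run` random centroid initializations, scores every run
#' against a reference expert partition with ARI and AMI, and summarizes the
#' scores with means and 95 percent t-based confidence intervals. By default
#' k matches the number of expert clusters, removing cluster count as a
#' confounder of the consistency metrics.
#'
#' @param X An [embedding_matrix()].
#' @param expert Reference label vector (one label per row of `X`).
#' @param k Number of clusters; defaults to the number of expert clusters.
#' @param runs Number of independent clustering runs (default 10).
#' @param inits_per_run Restarts within each run (default 10).
#' @param seed Master seed; per-run seeds derive from it.
#' @param mode Clustering mode; use `"euclidean"` for Bag-of-Terms input.
#' @return A list of class `consistency_benchmark`: per-run `scores` data
#'   frame and a `summary` data frame (metric, mean, ci_lo, ci_hi).
#' @export
consistency_benchmark <- function(X, expert, k = NULL, runs = 10L,
                                  inits_per_run = 10L, seed = 1L,
                                  mode = c("spherical", "euclidean")) {
  mode <- match.arg(mode)
  if (is.null(expert) || !length(expert))
    stop("expert labels are required", call. = FALSE)
  n <- if (inherits(X, "embedding_matrix")) nrow(X$values) else nrow(X)
  if (length(expert) != n)
    stop("expert labels must match the number of rows", call. = FALSE)
  if (is.null(k)) k <- length(unique(expert))
  scores <- data.frame(run = seq_len(runs), ari = NA_real_, ami = NA_real_)
  for (r in seq_len(runs)) {
    fit <- spherical_kmeans(X, k = k, n_init = inits_per_run,
                            seed = .seed_stream(seed, r), mode = mode)
    scores$ari[r] <- adjusted_rand_index(fit$assignment, expert)
    scores$ami[r] <- adjusted_mutual_information(fit$assignment, expert)
  }
  structure(list(scores = scores, summary = .ci_summary(scores[c("ari", "ami")]),
                 k = k, runs = runs, mode = mode),
            class = "consistency_benchmark")
}

.ci_summary <- function(df) {
  do.call(rbind, lapply(names(df), function(m) {
    x <- df[[m]]
    se <- stats::sd(x) / sqrt(length(x))
    half <- if (length(x) > 1 && se > 0)
      stats::qt(0.975, length(x) - 1) * se else 0
    data.frame(metric = m, mean = mean(x),
               ci_lo = mean(x) - half, ci_hi = mean(x) + half)
  }))
}

#' @export
print.consistency_benchmark <- function(x, ...) {
  cat("Consistency vs expert clusters (k = ", x$k, ", ", x$runs,
      " runs, mode: ", x$mode, ")\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Stability of repeated clustering runs
#'
#' Refits the clustering `runs` times with different restart seeds, scores
#' every unordered pair of runs with ARI and AMI (`runs (runs-1) / 2` pairs),
#' and reports the mean member overlap after greedily aligning each pair's
#' clusters. All runs are additionally aligned to run 1 so labels can be
#' compared across runs.
#'
#' @inheritParams consistency_benchmark
#' @param runs Number of clustering runs (>= 2; default 10).
#' @param inits_per_run Restarts within each run (default 100).
#' @param k Number of clusters (default 10).
#' @return A list of class `stability_analysis`: `pairs` data frame (run_a,
#'   run_b, ari, ami, overlap), `summary`, `assignments` (n x runs matrix),
#'   `alignment_to_first` (list of cluster mappings onto run 1).
#' @export
stability_analysis <- function(X, k = 10L, runs = 10L, inits_per_run = 100L,
                               seed = 1L, mode = c("spherical", "euclidean")) {
  mode <- match.arg(mode)
  runs <- as.integer(runs)
  if (runs < 2L) stop("runs must be >= 2", call. = FALSE)
  fits <- lapply(seq_len(runs), function(r)
    spherical_kmeans(X, k = k, n_init = inits_per_run,
                     seed = .seed_stream(seed, 1000L + r), mode = mode))
  A <- vapply(fits, `[[`, integer(length(fits[[1L]]$assignment)),
              "assignment")
  pr <- utils::combn(runs, 2)
  pairs <- data.frame(run_a = pr[1, ], run_b = pr[2, ],
                      ari = NA_real_, ami = NA_real_, overlap = NA_real_)
  for (i in seq_len(ncol(pr))) {
    a <- A[, pr[1, i]]; b <- A[, pr[2, i]]
    pairs$ari[i] <- adjusted_rand_index(a, b)
    pairs$ami[i] <- adjusted_mutual_information(a, b)
    pairs$overlap[i] <- greedy_cluster_mapping(a, b)$overlap_fraction
  }
  structure(list(
    pairs = pairs,
    summary = .ci_summary(pairs[c("ari", "ami", "overlap")]),
    assignments = A,
    alignment_to_first = lapply(seq_len(runs), function(r)
      greedy_cluster_mapping(A[, r], A[, 1L]))),
    class = "stability_analysis")
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat("Clustering stability over ", ncol(x$assignments), " runs (",
      nrow(x$pairs), " pairs)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a benchmark summary as a delimited table
#'
#' @param x A `consistency_benchmark` or `stability_analysis`.
#' @param path Output file; tab-separated.
#' @param model,field Optional identifiers recorded in the table.
#' @return The path, invisibly.
#' @export
write_benchmark_summary <- function(x, path, model = NA, field = NA) {
  s <- x$summary
  s$model <- model; s$field <- field
  utils::write.table(s[c("model", "field", "metric", "mean", "ci_lo", "ci_hi")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
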