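# Independent oracles used across the suite. Each is deliberately written
# against a different formulation than the implementation it checks.

# Exhaustive spherical k-means: minimum total within-cluster cosine distance
# over every assignment of n points to at most k clusters. Uses the closed
# form sum_c (n_c - ||s_c||) for the optimal (normalized-mean) centroid of a
# fixed partition, so the search is over partitions only. Point 1 is pinned
# to cluster 1 (label symmetry).
brute_force_spherical_objective <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 12, k <= 4)
  A <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), n - 1L)))
  A <- cbind(1L, A)
  obj <- rep(n, nrow(A))
  for (cl in seq_len(k)) {
    S <- ((A == cl) * 1) %*% X
    obj <- obj - sqrt(rowSums(S^2))
  }
  min(obj)
}

# and the best assignment itself (for small fixtures)
brute_force_spherical_assignment <- function(X, k) {
  n <- nrow(X)
  A <- as.matrix(do.call(expand.grid, rep(list(seq_len(k)), n - 1L)))
  A <- cbind(1L, A)
  obj <- rep(n, nrow(A))
  for (cl in seq_len(k)) {
    S <- ((A == cl) * 1) %*% X
    obj <- obj - sqrt(rowSums(S^2))
  }
  A[which.min(obj), ]
}

# ARI by direct pair counting (quadratic; independent of the contingency
# formula used in the package).
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  s_ab <- s_a <- s_b <- 0
  for (i in seq_len(n - 1L)) {
    sa <- a[(i + 1L):n] == a[i]
    sb <- b[(i + 1L):n] == b[i]
    s_ab <- s_ab + sum(sa & sb)
    s_a <- s_a + sum(sa)
    s_b <- s_b + sum(sb)
  }
  pairs <- n * (n - 1) / 2
  expected <- s_a * s_b / pairs
  (s_ab - expected) / ((s_a + s_b) / 2 - expected)
}

# Reference ARI/AMI from scikit-learn (same image provides `python`). AMI is
# requested with max normalization to match the package's stated variant.
# One interpreter launch scores all cases.
sklearn_partition_scores <- function(pairs) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(pairs, infile, auto_unbox = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "from sklearn.metrics import adjusted_rand_score as ari",
    "from sklearn.metrics import adjusted_mutual_info_score as ami",
    "pairs = json.load(open(sys.argv[1]))",
    "out = [{'ari': ari(p['a'], p['b']),",
    "        'ami': ami(p['a'], p['b'], average_method='max')}",
    "       for p in pairs]",
    "json.dump(out, open(sys.argv[2], 'w'))"), script)
  status <- system2("python", c(script, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  jsonlite::fromJSON(outfile)
}

# Optimal one-to-one cluster matching by exhaustive permutation search
# (oracle for the greedy mapper on small instances).
best_mapping_overlap <- function(a, b) {
  ct <- table(factor(a), factor(b))
  small <- min(dim(ct))
  if (nrow(ct) <= ncol(ct)) {
    perms <- .permutations(seq_len(ncol(ct)))
    best <- 0
    for (p in perms) {
      tot <- sum(ct[cbind(seq_len(nrow(ct)), p[seq_len(nrow(ct))])])
      best <- max(best, tot)
    }
  } else {
    perms <- .permutations(seq_len(nrow(ct)))
    best <- 0
    for (p in perms) {
      tot <- sum(ct[cbind(p[seq_len(ncol(ct))], seq_len(ncol(ct)))])
      best <- max(best, tot)
    }
  }
  best / length(a)
}

.permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# tight unit-norm bundles around k orthogonal directions, one per label
planted_bundle_embedding <- function(labels, d = 16L, noise = 0.01,
                                     seed = 1L) {
  set.seed(seed)
  k <- length(unique(labels))
  stopifnot(d >= k)
  idx <- as.integer(factor(labels))
  base <- diag(1, k, d)
  X <- base[idx, , drop = FALSE] + matrix(rnorm(length(labels) * d, 0, noise),
                                          ncol = d)
  l2_normalize(X)
}
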