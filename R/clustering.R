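#' Cosine distance between two vectors
#'
#' \deqn{D_C(x, y) = 1 - \frac{x^\top y}{\|x\|\,\|y\|}}
#'
#' Invariant to vector length, so it depends only on the angle; ranges over
#' \[0, 2\] with 0 for parallel, 1 for orthogonal and 2 for antipodal vectors.
#'
#' @param x,y Non-zero numeric vectors of equal length.
#' @return A number in \[0, 2\].
#' @export
cosine_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("cosine distance is undefined for a zero vector", call. = FALSE)
  d <- 1 - sum(x * y) / (nx * ny)
  min(max(d, 0), 2)  # clamp fp noise to the metric's range
}

# distance matrix points x centroids for a given mode; rows of X unit-norm in
# spherical mode are not assumed here (only at the fit entry point).
.dist_to_centroids <- function(X, C, mode) {
  if (mode == "spherical") {
    nx <- sqrt(rowSums(X^2)); nc <- sqrt(rowSums(C^2))
    D <- 1 - (X %*% t(C)) / outer(nx, nc)
    pmin(pmax(D, 0), 2)
  } else {
    # squared Euclidean distance (standard k-means objective)
    outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
      outer(rep(1, nrow(X)), rowSums(C^2))
  }
}

# One Lloyd run from given initial centroid indices. Ties in assignment break
# to the lowest cluster index; empty clusters are re-seeded with the point
# farthest from its current centroid.
.lloyd_once <- function(X, k, init_idx, mode, max_iter = 300L,
                        debug = FALSE) {
  C <- X[init_idx, , drop = FALSE]
  n <- nrow(X)
  assign_prev <- rep.int(0L, n)
  prev_obj <- Inf
  for (it in seq_len(max_iter)) {
    D <- .dist_to_centroids(X, C, mode)
    assign_cur <- max.col(-D, ties.method = "first")
    own <- D[cbind(seq_len(n), assign_cur)]
    # re-seed empty clusters from the farthest point (guarded: duplicated
    # rows can make an empty cluster unfillable, e.g. k close to n)
    guard <- 0L
    repeat {
      sizes <- tabulate(assign_cur, nbins = k)
      empty <- which(sizes == 0L)
      if (!length(empty) || (guard <- guard + 1L) > k) break
      far <- which.max(own)
      C[empty[1L], ] <- X[far, ]
      D[, empty[1L]] <- .dist_to_centroids(X, C[empty[1L], , drop = FALSE],
                                           mode)[, 1L]
      assign_cur <- max.col(-D, ties.method = "first")
      own <- D[cbind(seq_len(n), assign_cur)]
    }
    obj <- sum(own)
    if (debug && obj > prev_obj + 1e-8)
      stop("internal error: objective increased across Lloyd iteration")
    prev_obj <- obj
    if (identical(assign_cur, assign_prev)) {
      return(list(centroids = C, assignment = assign_cur, objective = obj,
                  iterations = it, converged = TRUE))
    }
    assign_prev <- assign_cur
    # centroid update: member mean, re-normalized in spherical mode
    for (j in seq_len(k)) {
      mem <- assign_cur == j
      if (!any(mem)) next  # unfillable empty cluster keeps its centroid
      m <- colMeans(X[mem, , drop = FALSE])
      if (mode == "spherical") {
        nm <- sqrt(sum(m^2))
        if (nm > 0) m <- m / nm else m <- X[which(mem)[1L], ]
      }
      C[j, ] <- m
    }
  }
  D <- .dist_to_centroids(X, C, mode)
  assign_cur <- max.col(-D, ties.method = "first")
  list(centroids = C, assignment = assign_cur,
       objective = sum(D[cbind(seq_len(n), assign_cur)]),
       iterations = max_iter, converged = FALSE)
}

#' Spherical k-means clustering
#'
#' k-means in which the distance between points and centroids is the cosine
#' distance of [cosine_distance()] rather than squared Euclidean distance;
#' centroids are updated as the member mean re-normalized to unit length.
#' Because cosine distance depends only on angles, the algorithm suits
#' L2-normalized text embedding vectors; on unit-norm data the two metrics
#' induce identical point-to-cluster assignments and differ only in the
#' centroid update. `mode = "euclidean"` gives standard k-means (used for
#' Bag-of-Terms vectors, whose L1 norm — the number of codes — is
#' informative and should not be normalized away).
#'
#' The fit is restarted `n_init` times from uniformly drawn distinct seed
#' points and the run with the smallest total within-cluster distance is
#' kept.
#'
#' @param X An [embedding_matrix()] (or plain matrix). Spherical mode requires
#'   `normalized = TRUE` (or, for a plain matrix, unit-norm rows).
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param n_init Number of random restarts (>= 1).
#' @param seed Integer master seed; restart initializations are drawn from it
#'   via a counter, so a fixed `(X, k, n_init, seed)` gives an identical fit.
#' @param mode `"spherical"` (cosine distance) or `"euclidean"` (squared L2).
#' @param max_iter Iteration cap per restart (default 300).
#' @param debug Assert the objective is non-increasing across iterations.
#' @return An object of class `spherical_kmeans` with components `centroids`
#'   (k x d), `assignment` (1-based hard cluster per point), `soft` (n x k
#'   matrix of distances to every centroid), `objective` (total
#'   within-cluster distance), `n_init_used`, `seed`, `mode`, `converged`,
#'   `iterations`, `row_ids`.
#' @seealso [soft_membership()], [hard_membership()],
#'   [predict.spherical_kmeans()]
#' @examples
#' X <- l2_normalize(matrix(rnorm(40), 10, 4))
#' fit <- spherical_kmeans(X, k = 2, n_init = 5, seed = 1)
#' fit$assignment
#' @export
spherical_kmeans <- function(X, k, n_init = 10L, seed = 1L,
                             mode = c("spherical", "euclidean"),
                             max_iter = 300L, debug = FALSE) {
  mode <- match.arg(mode)
  em <- if (inherits(X, "embedding_matrix")) X else
    embedding_matrix(X, normalized = all(abs(sqrt(rowSums(as.matrix(X)^2)) - 1) < 1e-9))
  V <- em$values
  n <- nrow(V)
  k <- as.integer(k); n_init <- as.integer(n_init)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n", call. = FALSE)
  if (n_init < 1L) stop("n_init must be >= 1", call. = FALSE)
  if (mode == "spherical" && !em$normalized)
    stop("spherical mode requires L2-normalized input; call l2_normalize()",
         call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  best <- NULL
  for (r in seq_len(n_init)) {
    set.seed(as.integer((seed + (r - 1L)) %% .Machine$integer.max))
    init_idx <- sample.int(n, k, replace = FALSE)
    run <- .lloyd_once(V, k, init_idx, mode, max_iter = max_iter,
                       debug = debug)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  soft <- .dist_to_centroids(V, best$centroids, mode)
  rownames(soft) <- em$row_ids
  structure(
    list(centroids = best$centroids, assignment = best$assignment,
         soft = soft, objective = best$objective, n_init_used = n_init,
         seed = seed, mode = mode, converged = best$converged,
         iterations = best$iterations, row_ids = em$row_ids, k = k),
    class = "spherical_kmeans")
}

#' @export
print.spherical_kmeans <- function(x, ...) {
  cat("Spherical k-means fit (mode: ", x$mode, ")\n",
      "  k = ", x$k, ", n = ", length(x$assignment),
      ", d = ", ncol(x$centroids), "\n",
      "  total within-cluster distance: ", format(x$objective, digits = 6),
      "\n  restarts: ", x$n_init_used,
      if (!x$converged) "  (iteration cap reached)", "\n",
      "  cluster sizes: ", paste(tabulate(x$assignment, x$k), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
fitted.spherical_kmeans <- function(object, ...) object$assignment

#' Predict cluster membership for new data
#'
#' @param object A `spherical_kmeans` fit.
#' @param newdata An `embedding_matrix` or matrix with the centroid dimension;
#'   defaults to the training data's stored soft matrix.
#' @param type `"soft"` (distance to every centroid), `"hard"` (one-hot of the
#'   nearest centroid) or `"assignment"` (nearest centroid index).
#' @param ... Unused.
#' @return Per `type`: an n x k numeric matrix, an n x k binary matrix, or an
#'   integer vector.
#' @export
predict.spherical_kmeans <- function(object, newdata = NULL,
                                     type = c("soft", "hard", "assignment"),
                                     ...) {
  type <- match.arg(type)
  soft <- if (is.null(newdata)) object$soft
          else soft_membership(newdata, object)
  if (type == "soft") return(soft)
  a <- max.col(-soft, ties.method = "first")
  if (type == "assignment") return(a)
  h <- matrix(0L, nrow(soft), object$k)
  h[cbind(seq_len(nrow(soft)), a)] <- 1L
  rownames(h) <- rownames(soft)
  h
}

#' Soft cluster membership: distances to every centroid
#'
#' The soft membership vector for a record is its distance (in the fit's
#' mode) to each of the k cluster centres; used directly as k predictive
#' features per text field.
#'
#' @param X `embedding_matrix` or matrix whose columns match the centroid
#'   dimension.
#' @param result A `spherical_kmeans` fit.
#' @return n x k numeric matrix; rows follow `X`, columns the clusters.
#' @export
soft_membership <- function(X, result) {
  stopifnot(inherits(result, "spherical_kmeans"))
  V <- if (inherits(X, "embedding_matrix")) X$values else as.matrix(X)
  if (ncol(V) != ncol(result$centroids))
    stop("dimension mismatch: data has ", ncol(V), " columns, centroids ",
         ncol(result$centroids), call. = FALSE)
  D <- .dist_to_centroids(V, result$centroids, result$mode)
  rownames(D) <- if (inherits(X, "embedding_matrix")) X$row_ids else rownames(V)
  D
}

#' Hard cluster membership: one-hot encoding of the assignment
#'
#' @param result A `spherical_kmeans` fit.
#' @return n x k binary matrix with exactly one 1 per row.
#' @export
hard_membership <- function(result) {
  stopifnot(inherits(result, "spherical_kmeans"))
  n <- length(result$assignment)
  h <- matrix(0L, n, result$k)
  h[cbind(seq_len(n), result$assignment)] <- 1L
  rownames(h) <- result$row_ids
  h
}

#' Serialize a clustering fit to JSON (+ numeric arrays)
#'
#' @param result A `spherical_kmeans` fit.
#' @return A JSON string carrying assignments, objective and configuration,
#'   with centroids and the soft matrix as nested arrays.
#' @export
clustering_to_json <- function(result) {
  stopifnot(inherits(result, "spherical_kmeans"))
  jsonlite::toJSON(list(
    k = result$k, mode = result$mode, seed = result$seed,
    n_init_used = result$n_init_used, objective = result$objective,
    assignment = result$assignment, row_ids = result$row_ids,
    centroids = result$centroids, soft = result$soft),
    auto_unbox = TRUE, digits = NA)
}
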