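#' Construct an embedding matrix
#'
#' Light container for an n x d numeric matrix of text embeddings with a flag
#' recording whether every row has unit L2 norm. Spherical clustering refuses
#' input whose flag is `FALSE`, so embedders must set it truthfully.
#'
#' @param values Numeric matrix, one row per text.
#' @param row_ids Optional record identifiers (defaults to rownames or 1..n).
#' @param normalized Logical: are all rows unit L2 norm?
#' @return An object of class `embedding_matrix`.
#' @export
embedding_matrix <- function(values, row_ids = NULL, normalized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(row_ids)) row_ids <- rownames(values)
  if (is.null(row_ids)) row_ids <- as.character(seq_len(nrow(values)))
  stopifnot(length(row_ids) == nrow(values))
  if (isTRUE(normalized)) {
    nrm <- sqrt(rowSums(values^2))
    if (any(abs(nrm - 1) > 1e-9))
      stop("normalized = TRUE but some rows are not unit L2 norm",
           call. = FALSE)
  }
  structure(list(values = values, row_ids = as.character(row_ids),
                 normalized = isTRUE(normalized)),
            class = "embedding_matrix")
}

#' @export
print.embedding_matrix <- function(x, ...) {
  cat("<embedding_matrix> ", nrow(x$values), " x ", ncol(x$values),
      if (x$normalized) " (rows unit L2 norm)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.embedding_matrix <- function(x) dim(x$values)

#' @export
as.matrix.embedding_matrix <- function(x, ...) x$values

#' L2-normalize the rows of an embedding matrix
#'
#' Scales each row to unit Euclidean length, the form spherical k-means
#' expects. Rows that are exactly zero carry no direction and are rejected.
#'
#' @param x An `embedding_matrix` or plain numeric matrix.
#' @return An `embedding_matrix` with `normalized = TRUE`.
#' @export
l2_normalize <- function(x) {
  em <- if (inherits(x, "embedding_matrix")) x else embedding_matrix(x)
  nrm <- sqrt(rowSums(em$values^2))
  zero <- nrm == 0
  if (any(zero))
    stop("cannot L2-normalize all-zero row(s): ",
         paste(em$row_ids[zero], collapse = ", "), call. = FALSE)
  embedding_matrix(em$values / nrm, row_ids = em$row_ids, normalized = TRUE)
}

#' Concatenate two embedding matrices row-wise
#'
#' Used for clustering on both text fields at once (diagnosis + operation).
#' The concatenated vector is re-normalized by default so it satisfies the
#' spherical k-means contract.
#'
#' @param a,b `embedding_matrix` objects over the same rows.
#' @param renormalize Re-scale concatenated rows to unit norm (default TRUE).
#' @return An `embedding_matrix`.
#' @export
concat_embeddings <- function(a, b, renormalize = TRUE) {
  stopifnot(inherits(a, "embedding_matrix"), inherits(b, "embedding_matrix"),
            nrow(a$values) == nrow(b$values))
  if (!identical(a$row_ids, b$row_ids))
    stop("row ids differ between the two embedding matrices", call. = FALSE)
  m <- cbind(a$values, b$values)
  out <- embedding_matrix(m, row_ids = a$row_ids, normalized = FALSE)
  if (renormalize) l2_normalize(out) else out
}

# ---------------------------------------------------------------------------
# Embedder contract: a registry of kinds, each a function
# (texts, spec) -> embedding_matrix.

.embedders <- new.env(parent = emptyenv())

#' Register an embedder implementation
#'
#' External models (Doc2Vec, sentence-transformer checkpoints, commercial
#' APIs) plug in behind the same contract as the built-in offline embedders.
#' The function receives `(texts, spec)` and must return an
#' [embedding_matrix()] whose `normalized` flag is truthful.
#'
#' @param kind Identifier, e.g. `"doc2vec"`.
#' @param fn Function `(texts, spec) -> embedding_matrix`, or `NULL` to
#'   unregister.
#' @return Invisibly, the previous registration (or `NULL`).
#' @export
register_embedder <- function(kind, fn) {
  stopifnot(is.character(kind), length(kind) == 1L)
  old <- if (exists(kind, envir = .embedders, inherits = FALSE))
    get(kind, envir = .embedders) else NULL
  if (is.null(fn)) {
    if (!is.null(old)) rm(list = kind, envir = .embedders)
  } else {
    stopifnot(is.function(fn))
    assign(kind, fn, envir = .embedders)
  }
  invisible(old)
}

#' List registered embedder kinds
#' @return Character vector.
#' @export
list_embedders <- function() sort(ls(envir = .embedders))

#' Describe an embedder configuration
#'
#' @param kind One of the registered kinds: `"bot"`, `"hash"`, `"doc2vec"`,
#'   `"external-adapter"`, or any kind added via [register_embedder()].
#' @param dimension Output dimension (ignored by `"bot"`, whose dimension is
#'   the vocabulary size).
#' @param name Display name; defaults to the kind.
#' @param hyperparameters Named list. For `"doc2vec"` the accepted grid is
#'   `variant` in \{"dbow", "dm"\}, `epochs` in \{10, 100, 1000\} and
#'   `dimension` in \{40, 400, 4000\}. For `"hash"`: `seed`. For `"bot"`:
#'   optionally a `vocabulary` (see [encode_bot_matrix()]).
#' @return An object of class `embedder_spec`.
#' @export
embedder_spec <- function(kind, dimension = NULL, name = kind,
                          hyperparameters = list()) {
  stopifnot(is.character(kind), length(kind) == 1L)
  if (!is.null(dimension)) {
    dimension <- as.integer(dimension)
    if (dimension < 1L) stop("dimension must be >= 1", call. = FALSE)
  }
  if (identical(kind, "doc2vec")) {
    hp <- hyperparameters
    if (!is.null(hp$variant) && !hp$variant %in% c("dbow", "dm"))
      stop("doc2vec variant must be 'dbow' or 'dm'", call. = FALSE)
    if (!is.null(hp$epochs) && !hp$epochs %in% c(10, 100, 1000))
      stop("doc2vec epochs must be one of 10, 100, 1000", call. = FALSE)
    if (!is.null(hp$dimension) && !hp$dimension %in% c(40, 400, 4000))
      stop("doc2vec dimension must be one of 40, 400, 4000", call. = FALSE)
  }
  structure(list(name = name, kind = kind, dimension = dimension,
                 hyperparameters = hyperparameters),
            class = "embedder_spec")
}

#' @export
print.embedder_spec <- function(x, ...) {
  cat("<embedder_spec> ", x$name, " (kind: ", x$kind,
      if (!is.null(x$dimension)) paste0(", d = ", x$dimension), ")\n",
      sep = "")
  invisible(x)
}

#' Serialize / restore an embedder spec
#'
#' Specs round-trip through JSON so that a stored embedding matrix can name
#' the configuration that produced it.
#'
#' @param spec An `embedder_spec`.
#' @return `embedder_spec_to_json()`: a JSON string;
#'   `embedder_spec_from_json()`: an `embedder_spec`.
#' @export
embedder_spec_to_json <- function(spec) {
  stopifnot(inherits(spec, "embedder_spec"))
  jsonlite::toJSON(unclass(spec), auto_unbox = TRUE, null = "null")
}

#' @rdname embedder_spec_to_json
#' @param json JSON string produced by `embedder_spec_to_json()`.
#' @export
embedder_spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  embedder_spec(kind = x$kind, dimension = x$dimension, name = x$name,
                hyperparameters = as.list(x$hyperparameters))
}

#' Embed a vector of texts under a given embedder configuration
#'
#' Uniform entry point over all embedder kinds. Identical input strings always
#' produce identical rows. Dense embedders return unit-norm rows
#' (`normalized = TRUE`); Bag-of-Terms returns raw binary rows
#' (`normalized = FALSE`) since the L1 norm — the number of codes — carries
#' information.
#'
#' @param texts Non-empty character vector of ';'-separated code strings.
#' @param spec An [embedder_spec()].
#' @return An [embedding_matrix()].
#' @export
embed_texts <- function(texts, spec) {
  stopifnot(inherits(spec, "embedder_spec"))
  if (!length(texts)) stop("texts must be non-empty", call. = FALSE)
  if (!exists(spec$kind, envir = .embedders, inherits = FALSE))
    stop("unknown embedder kind '", spec$kind,
         "'; registered kinds: ", paste(list_embedders(), collapse = ", "),
         call. = FALSE)
  fn <- get(spec$kind, envir = .embedders)
  out <- fn(texts, spec)
  if (!inherits(out, "embedding_matrix"))
    stop("embedder '", spec$kind, "' did not return an embedding_matrix",
         call. = FALSE)
  out
}

# -- built-in kinds ---------------------------------------------------------

.embed_bot <- function(texts, spec) {
  encode_bot_matrix(texts, vocab = spec$hyperparameters$vocabulary,
                    warn_oov = isTRUE(spec$hyperparameters$warn_oov))
}

# Deterministic 31-ary rolling hash of a code string, folded with the seed.
# Stays below 2^53 so double arithmetic is exact.
.hash_code <- function(code, seed) {
  h <- 0
  for (b in utf8ToInt(code)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 69069) %% 2147483647)
}

.hash_unit_vector <- function(code, dimension, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.hash_code(code, seed))
  v <- stats::rnorm(dimension)
  v / sqrt(sum(v^2))
}

#' Deterministic hash embedder
#'
#' Offline stand-in for dense text embedders: every distinct code maps, via a
#' seeded hash, to a fixed random direction on the unit sphere, and a text's
#' embedding is the normalized sum of its codes' vectors. Cluster structure in
#' code usage therefore propagates into embedding geometry, while code order
#' (beyond the primary position) is deliberately ignored — a documented
#' limitation relative to contextual language models.
#'
#' @param texts Character vector of ';'-separated code strings.
#' @param dimension Embedding dimension (>= 2).
#' @param seed Integer seed fixing the code -> direction map.
#' @return An [embedding_matrix()] with `normalized = TRUE`. Texts that parse
#'   to no codes are flagged (attribute `"empty_rows"`) and mapped to a fixed
#'   "null" unit vector so downstream clustering never sees a zero row.
#' @export
hash_embed <- function(texts, dimension = 64L, seed = 1L) {
  dimension <- as.integer(dimension)
  if (dimension < 2L) stop("dimension must be >= 2", call. = FALSE)
  seqs <- lapply(texts, parse_field)
  codes <- unique(unlist(lapply(seqs, `[[`, "codes"), use.names = FALSE))
  basis <- if (length(codes)) {
    do.call(rbind, lapply(codes, .hash_unit_vector,
                          dimension = dimension, seed = seed))
  } else matrix(numeric(0), 0L, dimension)
  rownames(basis) <- codes
  null_vec <- c(1, rep(0, dimension - 1L))
  empty <- logical(length(seqs))
  m <- t(vapply(seq_along(seqs), function(i) {
    cs <- seqs[[i]]$codes
    if (!length(cs)) { empty[i] <<- TRUE; return(null_vec) }
    s <- colSums(basis[cs, , drop = FALSE])
    s / sqrt(sum(s^2))
  }, numeric(dimension)))
  if (any(empty))
    warning(sum(empty), " empty text(s) mapped to the null unit vector",
            call. = FALSE)
  out <- embedding_matrix(m, row_ids = names(texts), normalized = TRUE)
  attr(out, "empty_rows") <- which(empty)
  out
}

.embed_hash <- function(texts, spec) {
  hash_embed(texts,
             dimension = if (is.null(spec$dimension)) 64L else spec$dimension,
             seed = if (is.null(spec$hyperparameters$seed)) 1L
                    else spec$hyperparameters$seed)
}

.embed_missing_adapter <- function(texts, spec) {
  stop("embedder kind '", spec$kind, "' requires an installed adapter; ",
       "register one with register_embedder(\"", spec$kind, "\", fn)",
       call. = FALSE)
}

# Built-in registrations happen at load so user-registered adapters survive.
.register_builtin_embedders <- function() {
  register_embedder("bot", .embed_bot)
  register_embedder("hash", .embed_hash)
  if (!exists("doc2vec", envir = .embedders, inherits = FALSE))
    register_embedder("doc2vec", .embed_missing_adapter)
  if (!exists("external-adapter", envir = .embedders, inherits = FALSE))
    register_embedder("external-adapter", .embed_missing_adapter)
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_embedders()
}

#' Build diagnosis-operation fine-tuning pairs
#'
#' Constructs the contrastive fine-tuning task for sentence-embedding models:
#' one (diagnosis text, operation text) pair per operation record, on the
#' assumption that a patient's diagnoses drive the procedures performed. Rows
#' with an empty field are skipped with a warning. The training loop itself is
#' out of scope; this produces the pair set an adapter would consume.
#'
#' @param cohort A data frame with `diagnosis` and `operation` character
#'   columns (a `CohortTable`).
#' @return A data frame with columns `patient_id`, `diagnosis_text`,
#'   `operation_text`; attribute `"n_skipped"` records exclusions.
#' @export
build_finetune_pairs <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("diagnosis", "operation") %in% names(cohort)))
  id <- if ("patient_id" %in% names(cohort)) cohort$patient_id
        else seq_len(nrow(cohort))
  dx <- trimws(ifelse(is.na(cohort$diagnosis), "", cohort$diagnosis))
  op <- trimws(ifelse(is.na(cohort$operation), "", cohort$operation))
  keep <- nzchar(dx) & nzchar(op)
  if (any(!keep))
    warning("skipping ", sum(!keep), " row(s) with an empty text field",
            call. = FALSE)
  out <- data.frame(patient_id = id[keep], diagnosis_text = dx[keep],
                    operation_text = op[keep], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!keep)
  out
}
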