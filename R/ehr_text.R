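#' Parse a ';'-separated string of standardized medical codes
#'
#' EHR text fields handled by this package are not free text: each field is an
#' ordered list of standardized medical codes joined by `';'`, with the first
#' entry the primary code. Parsing splits on `';'`, trims whitespace,
#' lowercases, drops empty fragments and removes duplicates while keeping the
#' first occurrence (so the primary code keeps its position).
#'
#' @param text A character scalar (any string; `NA` is treated as empty).
#' @return An object of class `code_sequence`: a list with `codes` (character
#'   vector, possibly empty) and `primary` (first code, or `NA_character_` when
#'   the sequence is empty).
#' @examples
#' parse_field("mitral regurgitation; mitral valvar abnormality")
#' parse_field("")   # empty sequence
#' @export
parse_field <- function(text) {
  if (length(text) != 1L)
    stop("parse_field() expects a single string; use lapply() for vectors",
         call. = FALSE)
  if (is.na(text)) text <- ""
  parts <- strsplit(text, ";", fixed = TRUE)[[1L]]
  parts <- tolower(trimws(parts))
  parts <- parts[nzchar(parts)]
  parts <- parts[!duplicated(parts)]
  structure(
    list(codes = parts,
         primary = if (length(parts)) parts[[1L]] else NA_character_),
    class = "code_sequence"
  )
}

#' @export
print.code_sequence <- function(x, ...) {
  cat("<code_sequence> ", length(x$codes), " code(s)\n", sep = "")
  if (length(x$codes))
    cat("  primary: ", x$primary, "\n  codes:   ",
        paste(x$codes, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Join a code sequence back into its text representation
#'
#' Inverse of [parse_field()] up to normalization: re-parsing the joined
#' string yields the same sequence.
#'
#' @param seq A `code_sequence`.
#' @return A single string, codes joined by `"; "` (empty string for an empty
#'   sequence).
#' @export
join_codes <- function(seq) {
  stopifnot(inherits(seq, "code_sequence"))
  paste(seq$codes, collapse = "; ")
}

#' Build a code vocabulary from a corpus of code sequences
#'
#' The vocabulary is the lexicographically sorted union of all codes in the
#' corpus; its size is the number of distinct codes, which dictates the
#' Bag-of-Terms dimension for that field.
#'
#' @param corpus A non-empty list of `code_sequence` objects (or raw strings,
#'   which are parsed first).
#' @return An object of class `code_vocabulary`: list with `codes` (sorted
#'   character vector) and `index` (named integer vector, code -> column).
#' @export
build_vocabulary <- function(corpus) {
  if (!length(corpus)) stop("corpus must be non-empty", call. = FALSE)
  seqs <- lapply(corpus, function(x)
    if (inherits(x, "code_sequence")) x else parse_field(x))
  codes <- sort(unique(unlist(lapply(seqs, `[[`, "codes"), use.names = FALSE)))
  idx <- seq_along(codes)
  names(idx) <- codes
  structure(list(codes = codes, index = idx), class = "code_vocabulary")
}

#' @export
print.code_vocabulary <- function(x, ...) {
  cat("<code_vocabulary> ", length(x$codes), " distinct codes\n", sep = "")
  invisible(x)
}

#' Bag-of-Terms encoding of a code sequence
#'
#' Each code in the vocabulary gets a binary indicator: 1 if present in the
#' sequence, 0 otherwise. Entries are binary by construction (codes are
#' deduplicated at parse time). Codes absent from the vocabulary are ignored
#' with a warning, so a vocabulary built on training rows can encode unseen
#' rows.
#'
#' @param seq A `code_sequence` (or raw string).
#' @param vocab A `code_vocabulary`.
#' @param warn_oov Warn when out-of-vocabulary codes are dropped
#'   (default `TRUE`).
#' @return Integer vector of length `length(vocab$codes)` with values in
#'   \{0, 1\}.
#' @export
encode_bot <- function(seq, vocab, warn_oov = TRUE) {
  stopifnot(inherits(vocab, "code_vocabulary"))
  if (!length(vocab$codes)) stop("vocabulary is empty", call. = FALSE)
  if (!inherits(seq, "code_sequence")) seq <- parse_field(seq)
  v <- integer(length(vocab$codes))
  hit <- vocab$index[seq$codes]
  oov <- is.na(hit)
  if (any(oov) && warn_oov)
    warning("ignoring ", sum(oov), " out-of-vocabulary code(s): ",
            paste(seq$codes[oov], collapse = ", "), call. = FALSE)
  v[hit[!oov]] <- 1L
  v
}

#' Bag-of-Terms matrix for a whole text column
#'
#' @param texts Character vector of ';'-separated code strings.
#' @param vocab Optional `code_vocabulary`; built from `texts` when `NULL`
#'   (the default, matching a fixed hospital-wide code system).
#' @param warn_oov Passed to [encode_bot()].
#' @return An [embedding_matrix()] with `normalized = FALSE`, one row per
#'   input text, one column per vocabulary code.
#' @export
encode_bot_matrix <- function(texts, vocab = NULL, warn_oov = TRUE) {
  seqs <- lapply(texts, parse_field)
  if (is.null(vocab)) vocab <- build_vocabulary(seqs)
  m <- t(vapply(seqs, encode_bot, integer(length(vocab$codes)),
                vocab = vocab, warn_oov = warn_oov))
  colnames(m) <- vocab$codes
  embedding_matrix(m, row_ids = names(texts), normalized = FALSE)
}
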