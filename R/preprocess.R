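#' Character-level tokenization
#'
#' One token per Unicode code point; whitespace is dropped. Intended for
#' unsegmented Chinese text, where characters sidestep word-segmentation
#' errors on clinical terms.
#'
#' @param text a single string (cleaned).
#' @return Character vector of single-character tokens.
#' @export
tokenize_chars <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(text, "", fixed = FALSE)[[1]]
  toks[!grepl("^[[:space:]]$", toks)]
}

#' Word-level tokenization of pre-segmented text
#'
#' The toolkit does not bundle a Chinese word segmenter; word-level input is
#' text already segmented externally, with segments separated by whitespace
#' or "/".
#'
#' @param text a single pre-segmented string.
#' @return Character vector of non-empty tokens in order.
#' @export
tokenize_words <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(text, "[[:space:]/]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a frequency-thresholded vocabulary
#'
#' Tokens occurring at least `min_count` times across the streams receive
#' dense indices starting at 2; index 0 is reserved for PAD and index 1 for
#' OOV. Indices are assigned by decreasing corpus frequency, ties broken by
#' first occurrence, so the result is invariant to stream order up to that
#' tie-break.
#'
#' @param streams a list of token vectors (or one token vector).
#' @param min_count minimum corpus frequency to enter the vocabulary
#'   (default 2, dropping hapax tokens).
#' @return A `vocabulary` object: `token_to_index` (named integer vector
#'   including `<PAD>` = 0 and `<OOV>` = 1), `min_count`, `size`.
#' @export
build_vocab <- function(streams, min_count = 2L) {
  stopifnot(min_count >= 1L)
  if (!is.list(streams)) streams <- list(streams)
  toks <- unlist(streams, use.names = FALSE)
  if (length(toks) == 0L) {
    map <- c("<PAD>" = 0L, "<OOV>" = 1L)
  } else {
    first_pos <- tapply(seq_along(toks), factor(toks, levels = unique(toks)), min)
    counts <- table(factor(toks, levels = unique(toks)))
    keep <- names(counts)[counts >= min_count]
    ord <- order(-as.integer(counts[keep]), as.integer(first_pos[keep]))
    keep <- keep[ord]
    map <- c("<PAD>" = 0L, "<OOV>" = 1L,
             stats::setNames(seq_along(keep) + 1L, keep))
  }
  structure(list(token_to_index = map, min_count = as.integer(min_count),
                 size = length(map)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary>", x$size, "entries (incl. PAD/OOV), min_count =",
      x$min_count, "\n")
  invisible(x)
}

#' Encode tokens as a fixed-length index sequence
#'
#' Maps tokens to vocabulary indices (unknown tokens to OOV = 1), truncates
#' to `max_len` keeping the head of the sequence, and right-pads with
#' PAD = 0 to exactly `max_len`. Truncation keeps the head because the
#' opening of a consultancy question carries the complaint.
#'
#' @param tokens character vector of tokens.
#' @param vocab a `vocabulary`.
#' @param max_len target length (>= 1).
#' @return Integer vector of length `max_len`.
#' @export
encode <- function(tokens, vocab, max_len) {
  stopifnot(max_len >= 1L)
  ids <- unname(vocab$token_to_index[tokens])
  ids[is.na(ids)] <- 1L
  if (length(ids) > max_len) ids <- ids[seq_len(max_len)]
  c(ids, rep(0L, max_len - length(ids)))
}

#' Randomly initialized embedding table
#'
#' Entries are drawn i.i.d. uniform on \[-0.1, 0.1\]; the PAD row (row 1,
#' index 0) is zeroed. Reproducible given the seed.
#'
#' @param vocab_size number of rows (vocabulary entries including specials).
#' @param k embedding dimension (default 200).
#' @param seed integer seed.
#' @return A `vocab_size` x `k` numeric matrix.
#' @export
init_embeddings <- function(vocab_size, k = 200L, seed = 1L) {
  stopifnot(k >= 1L, vocab_size >= 2L)
  with_seed(seed, {
    E <- matrix(stats::runif(vocab_size * k, -0.1, 0.1), vocab_size, k)
    E[1L, ] <- 0
    E
  })
}

#' Look up embeddings for an encoded sequence
#'
#' Drops trailing PAD positions (padding is always at the tail under
#' [encode()]), so downstream models see only the real token prefix. An
#' all-PAD sequence yields a single zero row so every model has a non-empty
#' input.
#'
#' @param ids integer index vector (0-based indices into the table).
#' @param E embedding matrix (row 1 = PAD).
#' @return List with `X` (n x k matrix) and `ids` (the retained 0-based ids).
#' @keywords internal
embed_sequence <- function(ids, E) {
  n <- length(ids)
  while (n > 1L && ids[n] == 0L) n <- n - 1L
  ids <- ids[seq_len(n)]
  list(X = E[ids + 1L, , drop = FALSE], ids = ids)
}

#' Serialize a vocabulary to a two-column text file
#'
#' @param vocab a `vocabulary`.
#' @param path output path; written as `token<TAB>index`, UTF-8.
#' @return `path`, invisibly.
#' @export
write_vocab <- function(vocab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(vocab$token_to_index), vocab$token_to_index, sep = "\t"),
             con)
  invisible(path)
}

#' Read a vocabulary written by [write_vocab()]
#'
#' @param path two-column token/index text file.
#' @param min_count recorded threshold (metadata only; default 2).
#' @return A `vocabulary`.
#' @export
read_vocab <- function(path, min_count = 2L) {
  lines <- readLines(path, encoding = "UTF-8")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  map <- stats::setNames(vapply(parts, function(p) as.integer(p[2]), integer(1)),
                         vapply(parts, `[[`, character(1), 1))
  structure(list(token_to_index = map, min_count = as.integer(min_count),
                 size = length(map)),
            class = "vocabulary")
}

#' Tokenize with the configured input unit
#'
#' @param text a string.
#' @param unit `"char"` or `"word"`.
#' @return Token vector.
#' @export
tokenize <- function(text, unit = c("char", "word")) {
  unit <- match.arg(unit)
  if (unit == "char") tokenize_chars(text) else tokenize_words(text)
}
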