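# Embedding backends.
#
# Three interchangeable routes produce the vectors that are scored:
#   * static   — lookup in a word2vec/GloVe-style vector file (one vector per
#                word type; misses are counted as dropped, not imputed);
#   * contextual — per-sentence extraction from an encoder object exposing
#                per-layer hidden states (the shipped implementation is the
#                deterministic synthetic encoder; real transformer weights can
#                be plugged in through the same interface);
#   * synthetic — deterministic pseudo-random unit vectors keyed by
#                (token, seed), used for offline testing and simulation.

#' Load a word-vector file
#'
#' Reads whitespace-delimited text vector files in either the word2vec text
#' dialect (first line `"<vocab> <dim>"`) or the headerless GloVe dialect.
#' Dialect is auto-detected unless forced.
#'
#' @param path Path to the vector file.
#' @param dialect `"auto"` (default), `"word2vec"` or `"glove"`.
#' @return A `vector_table`: list with `vectors` (matrix, rownames = lowercased
#'   tokens), `d` (dimension) and `source`.
#' @details Duplicate tokens keep the first occurrence (with a warning);
#'   lookups are case-normalized. Inconsistent row dimensions raise a format
#'   error naming the offending line.
#' @export
load_vector_file <- function(path, dialect = c("auto", "word2vec", "glove")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_input(paste0("vector file not found: ", path),
                                      class = "dsitext_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort_input("empty vector file",
                                       class = "dsitext_format_error")
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  skip <- 0L
  if (dialect != "glove") {
    f1 <- fields[[1]]
    is_header <- length(f1) == 2L && !anyNA(suppressWarnings(as.integer(f1))) &&
      all(grepl("^[0-9]+$", f1))
    if (dialect == "word2vec" && !is_header) {
      abort_input("word2vec dialect requires a '<vocab> <dim>' header line",
                  class = "dsitext_format_error")
    }
    if (is_header) skip <- 1L
  }
  rows <- fields[(skip + 1L):length(fields)]
  if (length(rows) == 0L) abort_input("vector file has a header but no rows",
                                      class = "dsitext_format_error")
  d <- length(rows[[1]]) - 1L
  if (d < 1L) abort_input("vector rows must hold a token plus >= 1 value",
                          class = "dsitext_format_error")
  lens <- lengths(rows)
  bad <- which(lens != d + 1L)
  if (length(bad) > 0L) {
    abort_input(sprintf("inconsistent vector dimension at line %d (expected %d values)",
                        bad[1] + skip, d), class = "dsitext_format_error")
  }
  tokens <- tolower(vapply(rows, `[[`, "", 1L))
  vals <- vapply(rows, function(r) as.numeric(r[-1L]), numeric(d))
  m <- if (d == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(m)) abort_input("non-numeric vector values in file",
                            class = "dsitext_format_error")
  dup <- duplicated(tokens)
  if (any(dup)) {
    warning(sprintf("%d duplicate token(s) in vector file; first occurrence kept",
                    sum(dup)), call. = FALSE)
    m <- m[!dup, , drop = FALSE]
    tokens <- tokens[!dup]
  }
  rownames(m) <- tokens
  structure(list(vectors = m, d = d, source = basename(path)),
            class = "vector_table")
}

#' Build a vector table from a matrix
#'
#' Convenience constructor used by the synthetic backend and by tests.
#'
#' @param m Numeric matrix with one row per token; rownames are the vocabulary.
#' @param source Label recorded in the table.
#' @return A `vector_table`.
#' @export
vector_table <- function(m, source = "matrix") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), nrow(m) > 0L)
  rownames(m) <- tolower(rownames(m))
  structure(list(vectors = m, d = ncol(m), source = source),
            class = "vector_table")
}

new_embedding_set <- function(story_id, vectors, provenance, dropped) {
  n <- nrow(vectors)
  if (n > 0L) {
    nrm <- sqrt(rowSums(vectors^2))
    if (any(!is.finite(nrm)) || any(nrm == 0)) {
      abort_input("embedding set contains non-finite or zero-norm vectors")
    }
  }
  structure(list(story_id = story_id, vectors = vectors, provenance = provenance,
                 n = n, dropped = dropped),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set '%s': n=%d vectors (d=%d), dropped=%d>\n",
              x$story_id, x$n, if (x$n > 0) ncol(x$vectors) else NA_integer_,
              x$dropped))
  invisible(x)
}

#' Look up static embeddings for a tokenized story
#'
#' Each token occurrence is matched to its word vector; out-of-vocabulary
#' tokens are dropped and counted (they are treated as missing data, not
#' corrected). Duplicate tokens keep separate vectors.
#'
#' @param ts A `tokenized_story`, normally from [prepare_static()].
#' @param table A `vector_table`.
#' @return An `embedding_set`. If fewer than two tokens survive, the set is
#'   returned with a `dsi_undefined` attribute set (scoring yields `NA`).
#' @export
embed_static <- function(ts, table) {
  stopifnot(inherits(ts, "tokenized_story"), inherits(table, "vector_table"))
  toks <- story_tokens(ts)
  sent_idx <- rep(seq_along(ts$sentences), vapply(ts$sentences, nrow, 1L))
  idx <- match(toks, rownames(table$vectors))
  hit <- !is.na(idx)
  vectors <- table$vectors[idx[hit], , drop = FALSE]
  prov <- data.frame(token = toks[hit], sentence = sent_idx[hit],
                     layer = NA_integer_, stringsAsFactors = FALSE)
  es <- new_embedding_set(ts$story_id, vectors, prov, dropped = sum(!hit))
  if (es$n < 2L) attr(es, "dsi_undefined") <- TRUE
  es
}

#' Construct a deterministic synthetic encoder
#'
#' Implements the contextual-encoder interface offline: a 24-block encoder
#' whose "hidden states" are deterministic functions of (token, sentence,
#' layer, seed). Layer l returns
#' `normalize((1 - lambda) * v_token + lambda * v_sentence) ` plus a small
#' layer-keyed perturbation, so layers are distinct but correlated, mimicking
#' the depth profile of a real transformer.
#'
#' @param seed Integer seed keying every vector.
#' @param d Embedding dimension (default 300).
#' @param n_layers Number of transformer blocks (default 24).
#' @param lambda Context mixing weight in `[0, 1]`; 0 = purely lexical.
#' @param max_tokens Input budget per sentence; longer sentences are chunked.
#' @param anchor_sep Separator marking cluster-anchored synthetic tokens
#'   (`"anchorxxvariant"`-style names).
#' @param dispersion Within-cluster dispersion for anchored tokens.
#' @return A `dsi_encoder` object usable with [embed_contextual()].
#' @export
synthetic_encoder <- function(seed, d = 300L, n_layers = 24L, lambda = 0.3,
                              max_tokens = 512L, anchor_sep = "xx",
                              dispersion = 0.3) {
  if (lambda < 0 || lambda > 1) abort_input("lambda must be in [0, 1]",
                                            class = "dsitext_invalid_parameter")
  structure(list(seed = as.integer(seed), d = as.integer(d),
                 n_layers = as.integer(n_layers), lambda = lambda,
                 max_tokens = as.integer(max_tokens),
                 anchor_sep = anchor_sep, dispersion = dispersion,
                 label = sprintf("synthetic-%d", as.integer(seed))),
            class = "dsi_encoder")
}

# Deterministic unit vector for a string key under a seed, with caching.
synthetic_unit_vector <- function(key, seed, d, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  v <- with_local_seed(mix_seed(key, seed), stats::rnorm(d))
  v <- v / sqrt(sum(v^2))
  if (!is.null(cache)) cache[[key]] <- v
  v
}

# Token-level synthetic vector honouring cluster-anchored "anchor<sep>variant"
# token names: the anchor centroid plus dispersion-scaled variant noise.
synthetic_token_vector <- function(token, seed, d, anchor_sep = "xx",
                                   dispersion = 0.3, cache = NULL) {
  ck <- paste0("tok\r", token)
  if (!is.null(cache) && !is.null(cache[[ck]])) return(cache[[ck]])
  sep_pos <- regexpr(anchor_sep, token, fixed = TRUE)
  if (sep_pos > 0L) {
    anchor <- substr(token, 1L, sep_pos - 1L)
    v <- synthetic_unit_vector(paste0("anchor\r", anchor), seed, d, cache) +
      dispersion * synthetic_unit_vector(paste0("variant\r", token), seed, d, cache)
  } else {
    v <- synthetic_unit_vector(paste0("plain\r", token), seed, d, cache)
  }
  v <- v / sqrt(sum(v^2))
  if (!is.null(cache)) cache[[ck]] <- v
  v
}

# Encode one sentence with the synthetic encoder: list of per-layer matrices.
encode_sentence_synthetic <- function(enc, tokens, cache) {
  d <- enc$d
  tok_m <- t(vapply(tokens, synthetic_token_vector, numeric(d),
                    seed = enc$seed, d = d, anchor_sep = enc$anchor_sep,
                    dispersion = enc$dispersion, cache = cache))
  sent_vec <- synthetic_unit_vector(paste0("sent\r", paste(tokens, collapse = " ")),
                                    enc$seed, d, cache = NULL)
  base <- (1 - enc$lambda) * tok_m +
    matrix(enc$lambda * sent_vec, nrow(tok_m), d, byrow = TRUE)
  lapply(seq_len(enc$n_layers), function(l) {
    pert <- synthetic_unit_vector(paste0("layer\r", l), enc$seed, d, cache)
    m <- base + 0.05 * (l - 1) * matrix(pert, nrow(tok_m), d, byrow = TRUE)
    normalize_rows(m)
  })
}

#' Extract contextual embeddings for a story
#'
#' Encodes each sentence independently and collects, for every requested
#' layer, one vector per token piece. Special/sequence-delimiter positions are
#' excluded by construction; punctuation pieces are included by default (a
#' flag excludes them). Sentences longer than the encoder's input budget are
#' chunked at the budget boundary with a warning.
#'
#' @param ts A `tokenized_story`, normally from [prepare_contextual()].
#' @param encoder A `dsi_encoder` (see [synthetic_encoder()]).
#' @param layers Integer vector of hidden-layer indices, 1-indexed over the
#'   transformer blocks (the input-embedding layer is not counted). Default
#'   `c(6, 7)`, the early-to-middle layers used for scoring.
#' @param include_punctuation Keep punctuation pieces in the scored set.
#' @return An `embedding_set` whose provenance records token, sentence and
#'   layer for every vector.
#' @export
embed_contextual <- function(ts, encoder, layers = c(6L, 7L),
                             include_punctuation = TRUE) {
  stopifnot(inherits(ts, "tokenized_story"))
  if (!inherits(encoder, "dsi_encoder")) {
    abort_input("encoder must be a 'dsi_encoder' object",
                class = "dsitext_configuration_error")
  }
  layers <- as.integer(layers)
  if (length(layers) == 0L || any(layers < 1L) || any(layers > encoder$n_layers)) {
    abort_input(sprintf("layers must be in 1..%d", encoder$n_layers),
                class = "dsitext_invalid_parameter")
  }
  cache <- new.env(parent = emptyenv())
  vecs <- list()
  prov <- list()
  for (si in seq_along(ts$sentences)) {
    sent <- ts$sentences[[si]]
    if (!include_punctuation) sent <- sent[!sent$is_punctuation, , drop = FALSE]
    toks <- sent$token
    if (length(toks) == 0L) {
      warning(sprintf("sentence %d of story '%s' empty after filtering; skipped",
                      si, ts$story_id), call. = FALSE)
      next
    }
    chunks <- split(toks, ceiling(seq_along(toks) / encoder$max_tokens))
    if (length(chunks) > 1L) {
      warning(sprintf("sentence %d exceeds encoder budget (%d tokens); chunked",
                      si, encoder$max_tokens), call. = FALSE)
    }
    for (chunk in chunks) {
      states <- encode_sentence_synthetic(encoder, chunk, cache)
      for (l in layers) {
        vecs[[length(vecs) + 1L]] <- states[[l]]
        prov[[length(prov) + 1L]] <- data.frame(
          token = chunk, sentence = si, layer = l, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(vecs) == 0L) {
    es <- new_embedding_set(ts$story_id,
                            matrix(numeric(), 0L, encoder$d),
                            data.frame(token = character(), sentence = integer(),
                                       layer = integer()), dropped = 0L)
    attr(es, "dsi_undefined") <- TRUE
    return(es)
  }
  es <- new_embedding_set(ts$story_id, do.call(rbind, vecs),
                          do.call(rbind, prov), dropped = 0L)
  if (es$n < 2L) attr(es, "dsi_undefined") <- TRUE
  es
}

#' Synthetic embeddings for a tokenized story
#'
#' Deterministic test backend: every token maps to a unit pseudo-random
#' vector keyed by (token, seed). In contextual mode each requested layer
#' contributes `normalize((1 - lambda) * v_token + lambda * v_sentence)` with
#' a distinct per-layer perturbation. Identical inputs and seed give
#' bit-identical output.
#'
#' @param ts A `tokenized_story`.
#' @param seed Integer seed.
#' @param mode `"static"` (one vector per token) or `"contextual"`
#'   (per-layer sentence-mixed vectors).
#' @param lambda Context mixing weight in `[0, 1]` (contextual mode).
#' @param d Embedding dimension.
#' @param layers Layers extracted in contextual mode.
#' @param anchor_sep,dispersion Cluster-anchor handling, see
#'   [synthetic_encoder()].
#' @return An `embedding_set`.
#' @export
embed_synthetic <- function(ts, seed, mode = c("static", "contextual"),
                            lambda = 0.3, d = 300L, layers = c(6L, 7L),
                            anchor_sep = "xx", dispersion = 0.3) {
  mode <- match.arg(mode)
  if (lambda < 0 || lambda > 1) abort_input("lambda must be in [0, 1]",
                                            class = "dsitext_invalid_parameter")
  enc <- synthetic_encoder(seed, d = d, lambda = if (mode == "static") 0 else lambda,
                           anchor_sep = anchor_sep, dispersion = dispersion)
  if (mode == "static") {
    cache <- new.env(parent = emptyenv())
    toks <- story_tokens(ts)
    sent_idx <- rep(seq_along(ts$sentences), vapply(ts$sentences, nrow, 1L))
    if (length(toks) == 0L) {
      es <- new_embedding_set(ts$story_id, matrix(numeric(), 0L, d),
                              data.frame(token = character(), sentence = integer(),
                                         layer = integer()), dropped = 0L)
      attr(es, "dsi_undefined") <- TRUE
      return(es)
    }
    m <- t(vapply(toks, synthetic_token_vector, numeric(d),
                  seed = as.integer(seed), d = d, anchor_sep = anchor_sep,
                  dispersion = dispersion, cache = cache))
    prov <- data.frame(token = toks, sentence = sent_idx, layer = NA_integer_,
                       stringsAsFactors = FALSE)
    es <- new_embedding_set(ts$story_id, m, prov, dropped = 0L)
    if (es$n < 2L) attr(es, "dsi_undefined") <- TRUE
    return(es)
  }
  embed_contextual(ts, enc, layers = layers)
}
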