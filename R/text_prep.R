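# Deterministic text preparation for the two scoring routes.
#
# Static embedding models score content words only: the text is lowercased,
# tokenized, and stripped of stop words, numbers and punctuation (no stemming,
# no spell correction).  Contextual models see the text almost verbatim:
# sentences are preserved and only non-printable/control characters are
# removed, because the encoder needs the full sentence context.

abort_input <- function(msg, class = "dsitext_invalid_input") {
  stop(errorCondition(msg, class = c(class, "dsitext_error", "error", "condition")))
}

#' Create a story object
#'
#' A story is an identifier plus a non-empty narrative text. All scoring
#' entry points accept stories created with this constructor.
#'
#' @param id Unique identifier (coerced to character).
#' @param text Narrative text; must be non-empty after whitespace stripping.
#' @return An object of class `dsi_story`.
#' @export
story <- function(id, text) {
  id <- as.character(id)
  if (length(id) != 1L || is.na(id) || !nzchar(id)) {
    abort_input("story id must be a single non-empty string")
  }
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    abort_input("story text must be non-empty")
  }
  structure(list(id = id, text = as.character(text)), class = "dsi_story")
}

as_story <- function(x, id = "story") {
  if (inherits(x, "dsi_story")) return(x)
  story(id, x)
}

# Abbreviations whose trailing period does not end a sentence.  Single capital
# initials ("A.") are deliberately NOT excepted: a terminal period after a
# single letter splits.
SENTENCE_ABBREVIATIONS <- c(
  "dr", "mr", "mrs", "ms", "prof", "rev", "hon", "jr", "sr", "st", "mt",
  "vs", "etc", "e.g", "i.e", "cf", "fig", "no", "dept", "inc", "ltd", "co",
  "approx", "al"
)

# Token pattern: a word (with internal apostrophes/hyphens), a number
# (with internal decimal/grouping marks), or a single punctuation character.
TOKEN_PATTERN <- "[[:alpha:]]+(?:['’-][[:alpha:]]+)*|[0-9]+(?:[.,][0-9]+)*|[^[:space:][:alnum:]]"

strip_control <- function(text) {
  gsub("[[:cntrl:]\uFFFD]", " ", text)
}

tokenize_text <- function(text) {
  m <- gregexpr(TOKEN_PATTERN, text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  if (length(toks) == 0L) {
    return(data.frame(token = character(), is_stopword = logical(),
                      is_number = logical(), is_punctuation = logical(),
                      stringsAsFactors = FALSE))
  }
  toks <- tolower(toks)
  is_num <- grepl("^[0-9]", toks)
  is_word <- grepl("^[[:alpha:]]", toks)
  data.frame(token = toks,
             is_stopword = FALSE,
             is_number = is_num,
             is_punctuation = !is_num & !is_word,
             stringsAsFactors = FALSE)
}

split_sentence_strings <- function(text) {
  text <- strip_control(text)
  chars <- nchar(text)
  m <- gregexpr("[.!?]+", text)[[1]]
  bounds <- integer()
  if (m[1] != -1L) {
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      s <- m[k]
      e <- s + lens[k] - 1L
      after <- if (e < chars) substr(text, e + 1L, e + 1L) else ""
      if (nzchar(after) && !grepl("[[:space:]\"')”’]", after)) next
      terminator <- substr(text, s, e)
      if (terminator == ".") {
        before <- substr(text, max(1L, s - 12L), s - 1L)
        prev <- regmatches(before, regexpr("[[:alpha:].]+$", before))
        if (length(prev) == 1L &&
            tolower(sub("\\.$", "", prev)) %in% SENTENCE_ABBREVIATIONS) next
      }
      # extend past trailing close-quotes/brackets
      while (e < chars && grepl("[\"')”’]", substr(text, e + 1L, e + 1L))) {
        e <- e + 1L
      }
      bounds <- c(bounds, e)
    }
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, chars)
  keep <- starts <= ends
  pieces <- trimws(substring(text, starts[keep], ends[keep]))
  pieces[nzchar(pieces)]
}

#' Split a story into sentences
#'
#' Rule-based deterministic splitter: a run of `.`, `!` or `?` followed by
#' whitespace (or end of text) ends a sentence, except when a lone period
#' follows a known abbreviation (Dr., Mr., e.g., ...). Texts with no terminal
#' punctuation form a single sentence.
#'
#' @param x A `dsi_story` (or a character scalar, given an id of "story").
#' @return A `tokenized_story`: ordered sentences, each an ordered token table
#'   with `is_stopword`, `is_number`, `is_punctuation` flags.
#' @export
split_sentences <- function(x) {
  st <- as_story(x)
  pieces <- split_sentence_strings(st$text)
  if (length(pieces) == 0L) abort_input("story text contains no sentences")
  sentences <- lapply(pieces, tokenize_text)
  sentences <- sentences[vapply(sentences, nrow, 1L) > 0L]
  if (length(sentences) == 0L) abort_input("story text contains no tokens")
  structure(list(story_id = st$id, sentences = sentences),
            class = "tokenized_story")
}

#' Read a stop-word list
#'
#' One token per line, UTF-8. The packaged default replicates the 174-word
#' English snowball list distributed with the R `tm` package.
#'
#' @param path Path to a stop-word file; default is the packaged English list.
#' @return Character vector of lowercased stop words.
#' @export
read_stopwords <- function(path = system.file("extdata", "stopwords_en.txt",
                                              package = "dsitext")) {
  if (!file.exists(path)) abort_input(paste0("stop-word file not found: ", path))
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- tolower(trimws(words))
  words[nzchar(words)]
}

#' Prepare a story for a static (context-independent) embedding model
#'
#' Lowercases and tokenizes, then removes stop words, numbers and punctuation.
#' Words are not stemmed and not spell-corrected; out-of-vocabulary forms are
#' handled downstream at embedding lookup.
#'
#' @param x A `dsi_story` or character scalar.
#' @param stopwords Character vector of stop words (see [read_stopwords()]).
#' @return A `tokenized_story` whose sentences contain only content-word
#'   tokens. A warning is raised if every token was removed.
#' @export
prepare_static <- function(x, stopwords = read_stopwords()) {
  ts <- split_sentences(x)
  ts$sentences <- lapply(ts$sentences, function(s) {
    s$is_stopword <- s$token %in% stopwords
    s[!s$is_stopword & !s$is_number & !s$is_punctuation, , drop = FALSE]
  })
  ts$sentences <- ts$sentences[vapply(ts$sentences, nrow, 1L) > 0L]
  if (length(ts$sentences) == 0L) {
    warning("all tokens removed by static preprocessing; DSI will be undefined",
            call. = FALSE)
    ts$sentences <- list()
  }
  ts
}

#' Prepare a story for a contextual embedding model
#'
#' Keeps everything except non-printable/control characters: sentences,
#' punctuation and numbers are preserved because contextual encoders use the
#' whole sentence.
#'
#' @inheritParams prepare_static
#' @return A `tokenized_story` with all tokens retained.
#' @export
prepare_contextual <- function(x) {
  split_sentences(x)
}

#' Flatten a tokenized story to a single token vector
#'
#' @param ts A `tokenized_story`.
#' @param drop_punctuation Drop punctuation tokens.
#' @return Character vector of tokens in document order.
#' @export
story_tokens <- function(ts, drop_punctuation = FALSE) {
  stopifnot(inherits(ts, "tokenized_story"))
  if (length(ts$sentences) == 0L) return(character())
  out <- do.call(rbind, ts$sentences)
  if (drop_punctuation) out <- out[!out$is_punctuation, , drop = FALSE]
  out$token
}

#' @export
print.tokenized_story <- function(x, ...) {
  n <- sum(vapply(x$sentences, nrow, 1L))
  cat(sprintf("<tokenized_story '%s': %d sentence(s), %d token(s)>\n",
              x$story_id, length(x$sentences), n))
  invisible(x)
}

#' Read a table of stories from a delimited file
#'
#' @param path CSV/TSV file with a header row.
#' @param id_col,text_col Column names holding the identifier and the text.
#' @param delimiter Field delimiter; `","` by default, use `"\t"` for TSV.
#' @return A data.frame with columns `id` and `text`.
#' @export
read_stories <- function(path, id_col = "id", text_col = "text",
                         delimiter = ",") {
  if (!file.exists(path)) abort_input(paste0("story file not found: ", path),
                                      class = "dsitext_io_error")
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          quote = "\"", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", comment.char = "")
  missing_cols <- setdiff(c(id_col, text_col), names(df))
  if (length(missing_cols) > 0L) {
    abort_input(sprintf(
      "column(s) %s not found; available columns: %s",
      paste(missing_cols, collapse = ", "), paste(names(df), collapse = ", ")))
  }
  out <- data.frame(id = as.character(df[[id_col]]),
                    text = as.character(df[[text_col]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$id)) abort_input("story ids must be unique")
  out
}
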