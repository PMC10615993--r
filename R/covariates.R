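# Lexical covariates entered before DSI in the incremental-validity model:
# word count, Flesch-Kincaid grade level, mean log word frequency, mean word
# prevalence, mean age of acquisition, and MTLD lexical diversity.

#' Count word tokens in a story
#'
#' Counts non-punctuation tokens; hyphenated forms ("one-word") count once
#' because the tokenizer treats word-internal hyphens as part of the word.
#'
#' @param ts A `tokenized_story`.
#' @return Integer count.
#' @export
word_count <- function(ts) {
  length(story_tokens(ts, drop_punctuation = TRUE))
}

# Rule-based syllable counter: count vowel groups (a,e,i,o,u,y), subtract a
# silent final "e" (kept in consonant-"le" endings), floor at one syllable.
# Small exception table for common irregulars.
SYLLABLE_EXCEPTIONS <- c(
  "business" = 2L, "every" = 2L, "different" = 3L, "interesting" = 3L,
  "evening" = 2L, "people" = 2L, "area" = 3L, "idea" = 3L, "being" = 2L,
  "science" = 2L, "quiet" = 2L, "create" = 2L
)

#' Count syllables in a word
#'
#' Vowel-group heuristic with silent-e handling and a small exception table.
#' Absolute counts can differ from dictionary syllabification for unusual
#' words; rank order across texts is stable.
#'
#' @param word A single lowercase word.
#' @return Integer syllable count (>= 1).
#' @export
count_syllables <- function(word) {
  word <- tolower(gsub("[^a-z]", "", tolower(word)))
  if (!nzchar(word)) return(0L)
  if (word %in% names(SYLLABLE_EXCEPTIONS)) {
    return(unname(SYLLABLE_EXCEPTIONS[word]))
  }
  groups <- gregexpr("[aeiouy]+", word)[[1]]
  n <- if (groups[1] == -1L) 0L else length(groups)
  # silent final e: "time" -> 1, but keep "le" after a consonant: "table" -> 2
  if (grepl("[^aeiou]e$", word) && !grepl("[^aeiouy]le$", word) && n > 1L) {
    n <- n - 1L
  }
  max(n, 1L)
}

#' Flesch-Kincaid grade level of a story
#'
#' `0.39 * words/sentences + 11.8 * syllables/words - 15.59`, computed over
#' word tokens (punctuation and numbers excluded from the syllable ratio;
#' numbers count as one-syllable words).
#'
#' @param ts A `tokenized_story` with sentence structure preserved (use
#'   [prepare_contextual()] / [split_sentences()], not the static filter).
#' @return Grade-level estimate (can be negative for very simple text).
#' @export
readability_fk <- function(ts) {
  stopifnot(inherits(ts, "tokenized_story"))
  n_sent <- length(ts$sentences)
  toks <- story_tokens(ts, drop_punctuation = TRUE)
  n_words <- length(toks)
  if (n_sent == 0L || n_words == 0L) {
    abort_input("readability undefined for empty story")
  }
  syl <- vapply(toks, function(w) {
    if (grepl("^[0-9]", w)) 1L else count_syllables(w)
  }, 0L)
  0.39 * (n_words / n_sent) + 11.8 * (sum(syl) / n_words) - 15.59
}

#' Read a lexical norm table
#'
#' CSV with header `token,frequency,prevalence,aoa`. Values must be finite;
#' duplicate tokens are an error.
#'
#' @param path Path to the CSV file.
#' @return A `norm_table`: data.frame keyed by lowercased token.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) abort_input(paste0("norm table not found: ", path),
                                      class = "dsitext_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("token", "frequency", "prevalence", "aoa")
  if (!all(need %in% names(df))) {
    abort_input(paste0("norm table must have columns: ",
                       paste(need, collapse = ", ")),
                class = "dsitext_format_error")
  }
  df$token <- tolower(df$token)
  if (anyDuplicated(df$token)) abort_input("duplicate tokens in norm table",
                                           class = "dsitext_format_error")
  structure(df[need], class = c("norm_table", "data.frame"))
}

#' Mean lexical norm over a story's tokens
#'
#' Tokens are matched against the norm table (case-normalized); repeated
#' tokens count once per occurrence. Tokens absent from the table are skipped
#' and reflected in `coverage`.
#'
#' @param ts A `tokenized_story` (static preprocessing recommended so that
#'   function words do not dominate).
#' @param norms A `norm_table` from [read_norms()].
#' @param field `"frequency"`, `"prevalence"` or `"aoa"`.
#' @return List with `mean` (NA when coverage is zero) and `coverage`
#'   (fraction of tokens found).
#' @export
mean_norm <- function(ts, norms, field = c("frequency", "prevalence", "aoa")) {
  if (length(field) != 1L || !field %in% c("frequency", "prevalence", "aoa")) {
    abort_input("field must be one of frequency, prevalence, aoa",
                class = "dsitext_invalid_parameter")
  }
  toks <- story_tokens(ts, drop_punctuation = TRUE)
  if (length(toks) == 0L) return(list(mean = NA_real_, coverage = 0))
  idx <- match(toks, norms$token)
  vals <- norms[[field]][idx]
  hit <- !is.na(vals)
  list(mean = if (any(hit)) mean(vals[hit]) else NA_real_,
       coverage = mean(hit))
}

# One MTLD directional pass: factor count with partial remainder.
mtld_pass <- function(tokens, threshold) {
  factors <- 0
  types <- new.env(parent = emptyenv())
  n_types <- 0L
  n_toks <- 0L
  ttr <- 1
  for (tok in tokens) {
    n_toks <- n_toks + 1L
    if (is.null(types[[tok]])) {
      types[[tok]] <- TRUE
      n_types <- n_types + 1L
    }
    ttr <- n_types / n_toks
    if (ttr < threshold) {
      factors <- factors + 1
      types <- new.env(parent = emptyenv())
      n_types <- 0L
      n_toks <- 0L
      ttr <- 1
    }
  }
  if (n_toks > 0L) factors <- factors + (1 - ttr) / (1 - threshold)
  factors
}

#' MTLD lexical diversity
#'
#' Measure of Textual Lexical Diversity (mean factor length): a forward pass
#' accumulates a "factor" each time the running type-token ratio drops below
#' the threshold (0.72), resetting afterwards; the remainder adds the partial
#' factor `(1 - TTR_end) / (1 - threshold)`. The score is token count divided
#' by factor count, averaged over forward and reverse passes.
#'
#' @param ts A `tokenized_story`, or a character vector of tokens.
#' @param threshold TTR threshold, 0.72 by convention.
#' @return MTLD value, or `NA` (with a warning) when no factor completes in
#'   either direction (e.g., a short all-unique text).
#' @export
mtld <- function(ts, threshold = 0.72) {
  tokens <- if (inherits(ts, "tokenized_story")) {
    story_tokens(ts, drop_punctuation = TRUE)
  } else as.character(ts)
  if (length(tokens) == 0L) abort_input("MTLD requires at least one token")
  fwd <- mtld_pass(tokens, threshold)
  rev_ <- mtld_pass(rev(tokens), threshold)
  if (fwd == 0 && rev_ == 0) {
    warning("MTLD undefined: no factor completed in either direction",
            call. = FALSE)
    return(NA_real_)
  }
  vals <- c(if (fwd > 0) length(tokens) / fwd,
            if (rev_ > 0) length(tokens) / rev_)
  mean(vals)
}

#' Compute the full covariate battery for a batch of stories
#'
#' @param stories Data.frame with `id` and `text` columns.
#' @param norms Optional `norm_table`; when `NULL` the norm-based covariates
#'   are `NA` with a warning.
#' @param stopwords Stop-word list used for the norm/MTLD token stream.
#' @return Data.frame with columns `id`, `word_count`, `readability`, `freq`,
#'   `prev`, `aoa`, `mtld`, plus `norm_coverage`.
#' @export
covariate_table <- function(stories, norms = NULL, stopwords = read_stopwords()) {
  stopifnot(is.data.frame(stories), all(c("id", "text") %in% names(stories)))
  if (is.null(norms)) {
    warning("no norm table supplied; freq/prev/aoa will be missing", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(stories)), function(i) {
    st <- story(stories$id[i], stories$text[i])
    full <- split_sentences(st)
    content <- suppressWarnings(prepare_static(st, stopwords))
    has_content <- length(content$sentences) > 0L
    nm <- function(field) {
      if (is.null(norms) || !has_content) list(mean = NA_real_, coverage = NA_real_)
      else mean_norm(content, norms, field)
    }
    fr <- nm("frequency"); pv <- nm("prevalence"); ao <- nm("aoa")
    data.frame(
      id = st$id,
      word_count = word_count(full),
      readability = readability_fk(full),
      freq = fr$mean, prev = pv$mean, aoa = ao$mean,
      mtld = if (has_content) suppressWarnings(mtld(content)) else NA_real_,
      norm_coverage = fr$coverage,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
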