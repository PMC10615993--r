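# Text-length bias audit.
#
# A scoring metric that drifts with text length would confound creativity
# with verbosity.  The audit truncates every story in a corpus to a common
# token length L, draws k = floor(L/w) disjoint random subsections of w tokens
# (without replacement, covering the text up to the L mod w remainder),
# scores each subsection, and averages them into one score per story per w.
# Comparing per-length score distributions and the cross-length correlation
# matrix reveals any length artifact.

#' Randomly partition a token stream into fixed-size subsections
#'
#' Draws `k = floor(length(tokens)/w)` disjoint subsections of exactly `w`
#' tokens each, sampling positions uniformly without replacement; the
#' `length(tokens) - k*w` leftover positions are unused. Tokens within a
#' subsection keep their original relative order. Deterministic given `seed`.
#'
#' @param tokens Character vector of tokens.
#' @param w Subsection length in tokens (>= 2).
#' @param seed Integer seed.
#' @return List of `k` character vectors.
#' @export
sample_subsections <- function(tokens, w, seed) {
  L <- length(tokens)
  w <- as.integer(w)
  if (w < 2L) abort_input("subsection length must be >= 2",
                          class = "dsitext_invalid_design")
  if (w > L) abort_input(sprintf("subsection length %d exceeds story length %d",
                                 w, L), class = "dsitext_invalid_design")
  k <- L %/% w
  perm <- with_local_seed(as.integer(seed), sample.int(L))
  lapply(seq_len(k), function(j) {
    pos <- sort(perm[((j - 1L) * w + 1L):(j * w)])
    tokens[pos]
  })
}

# Score a bare token vector as a single pseudo-sentence with the synthetic
# backend (subsections destroy sentence integrity, so the subsection is
# treated as one sentence).
score_token_set <- function(tokens, seed, d = 50L, dispersion = 0.3,
                            mode = "static", lambda = 0.3, layers = c(6L, 7L),
                            cache = NULL) {
  if (length(tokens) < 2L) return(NA_real_)
  if (mode == "static") {
    m <- t(vapply(tokens, synthetic_token_vector, numeric(d),
                  seed = as.integer(seed), d = d, anchor_sep = "xx",
                  dispersion = dispersion, cache = cache))
    mean_pairwise_distance(normalize_rows(m))
  } else {
    ts <- structure(list(story_id = "subsection",
                         sentences = list(data.frame(
                           token = tokens, is_stopword = FALSE,
                           is_number = FALSE, is_punctuation = FALSE,
                           stringsAsFactors = FALSE))),
                    class = "tokenized_story")
    es <- embed_synthetic(ts, seed = seed, mode = "contextual",
                          lambda = lambda, d = d, layers = layers,
                          dispersion = dispersion)
    dsi(es)$value
  }
}

#' Length-stability curve for a corpus
#'
#' For every story (tokenized, truncated to `truncate_to` tokens) and every
#' subsection length `w`, draws the without-replacement subsections, scores
#' each with the synthetic backend, and averages. Returns per-story scores,
#' per-length distribution summaries and the cross-length Pearson correlation
#' matrix. At `w = truncate_to` the score equals the full-story score exactly.
#'
#' @param stories Data.frame with `id`, `text`.
#' @param lengths Integer vector of subsection lengths; `truncate_to` is
#'   always included.
#' @param truncate_to Common story length L in tokens; stories shorter than L
#'   after preprocessing are excluded (logged via warning).
#' @param seed Integer seed controlling both sampling and the synthetic
#'   embedding backend.
#' @param d Synthetic embedding dimension.
#' @param dispersion Within-cluster dispersion of the synthetic backend.
#' @param mode `"static"` or `"contextual"` synthetic scoring.
#' @param stopwords Stop-word list applied before truncation (word counts are
#'   taken after stop-word removal).
#' @return A `length_curve`: list with `scores` (stories x lengths matrix),
#'   `summary` (per-length mean/sd/quantiles), `correlations`, `design`.
#' @export
length_curve <- function(stories, lengths, truncate_to, seed, d = 50L,
                         dispersion = 0.3, mode = "static", lambda = 0.3,
                         stopwords = read_stopwords()) {
  lengths <- sort(unique(c(as.integer(lengths), as.integer(truncate_to))))
  if (any(lengths < 2L)) abort_input("all subsection lengths must be >= 2",
                                     class = "dsitext_invalid_design")
  if (max(lengths) > truncate_to) {
    abort_input("subsection lengths cannot exceed the truncation length",
                class = "dsitext_invalid_design")
  }
  tok_sets <- list()
  keep_ids <- character()
  for (i in seq_len(nrow(stories))) {
    st <- story(stories$id[i], stories$text[i])
    toks <- story_tokens(suppressWarnings(prepare_static(st, stopwords)))
    if (length(toks) < truncate_to) {
      warning(sprintf("story '%s' shorter than %d tokens after preprocessing; excluded",
                      st$id, truncate_to), call. = FALSE)
      next
    }
    tok_sets[[st$id]] <- toks[seq_len(truncate_to)]
    keep_ids <- c(keep_ids, st$id)
  }
  if (length(keep_ids) == 0L) abort_input("no story long enough for the design",
                                          class = "dsitext_invalid_design")
  cache <- new.env(parent = emptyenv())
  scores <- matrix(NA_real_, length(keep_ids), length(lengths),
                   dimnames = list(keep_ids, paste0("w", lengths)))
  for (si in seq_along(keep_ids)) {
    toks <- tok_sets[[keep_ids[si]]]
    for (li in seq_along(lengths)) {
      w <- lengths[li]
      sub_seed <- mix_seed(paste0(keep_ids[si], "\r", w), seed)
      subs <- sample_subsections(toks, w, sub_seed)
      vals <- vapply(subs, score_token_set, 0, seed = seed, d = d,
                     dispersion = dispersion, mode = mode, lambda = lambda,
                     cache = cache)
      scores[si, li] <- mean(vals)
    }
  }
  qs <- t(apply(scores, 2, stats::quantile, probs = c(.25, .5, .75), na.rm = TRUE))
  summary_df <- data.frame(
    w = lengths,
    mean = colMeans(scores),
    sd = apply(scores, 2, stats::sd),
    q25 = qs[, 1], median = qs[, 2], q75 = qs[, 3],
    row.names = NULL)
  cors <- suppressWarnings(stats::cor(scores))
  if (any(!is.finite(cors))) {
    warning("zero-variance column(s): some cross-length correlations undefined",
            call. = FALSE)
  }
  structure(list(scores = scores, summary = summary_df, correlations = cors,
                 design = list(lengths = lengths, truncate_to = truncate_to,
                               seed = seed, d = d, dispersion = dispersion,
                               mode = mode, n_stories = length(keep_ids))),
            class = "length_curve")
}

#' @export
print.length_curve <- function(x, ...) {
  cat(sprintf("<length_curve: %d stories, L=%d, lengths {%s}>\n",
              x$design$n_stories, x$design$truncate_to,
              paste(x$design$lengths, collapse = ", ")))
  print(x$summary)
  invisible(x)
}
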