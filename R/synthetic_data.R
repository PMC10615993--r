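# Synthetic fixtures with known ground truth.
#
# Stories are symbolic token streams drawn from k topic clusters.  Tokens are
# purely alphabetic ("anchorC xx vV", digits letter-encoded) so they survive
# the real tokenizer; the synthetic embedding backend maps the part before
# the "xx" separator to a cluster centroid and the full token to
# dispersion-scaled within-cluster noise, so a story's true topical
# divergence (its cluster count) controls the DSI it will receive.  Raters
# are simulated as a linear function of the standardized true score plus
# independent noise.

# letter-encode an integer so synthetic tokens stay purely alphabetic
letter_encode <- function(x) chartr("0123456789", "abcdefghij", as.character(x))

#' Specification for a synthetic story corpus
#'
#' @param n_stories Number of stories.
#' @param words_per_story Tokens per story.
#' @param n_clusters Cluster count per story: a single value, or a vector
#'   recycled across stories (each story records its own true count).
#' @param dispersion Within-cluster dispersion passed to the synthetic
#'   backend (0 = all cluster tokens collapse onto the centroid).
#' @param n_anchor_pool Size of the global pool of cluster anchors.
#' @param n_variants Variant tokens available per anchor.
#' @param seed Integer seed; the corpus is bit-reproducible from (spec, seed).
#' @return A `synthetic_corpus_spec`.
#' @export
synthetic_corpus_spec <- function(n_stories = 60L, words_per_story = 100L,
                                  n_clusters = 3L, dispersion = 0.3,
                                  n_anchor_pool = 12L, n_variants = 40L,
                                  seed = 1L) {
  if (any(n_clusters < 1L)) abort_input("n_clusters must be >= 1")
  if (max(n_clusters) > n_anchor_pool) {
    abort_input("cluster count exceeds the anchor vocabulary pool")
  }
  structure(list(n_stories = as.integer(n_stories),
                 words_per_story = as.integer(words_per_story),
                 n_clusters = as.integer(n_clusters),
                 dispersion = dispersion,
                 n_anchor_pool = as.integer(n_anchor_pool),
                 n_variants = as.integer(n_variants),
                 seed = as.integer(seed)),
            class = "synthetic_corpus_spec")
}

#' Generate a synthetic story corpus
#'
#' Each story draws `words_per_story` tokens from its `n_clusters` topic
#' clusters (anchors sampled from the global pool). Token text is symbolic
#' (`"anchorK~vJ"`), broken into sentences of 8-12 tokens so the full
#' preprocessing path can run. The true cluster count is carried in the
#' `true_clusters` column.
#'
#' @param spec A `synthetic_corpus_spec`.
#' @return Data.frame with columns `id`, `text`, `true_clusters`.
#' @export
generate_stories <- function(spec) {
  stopifnot(inherits(spec, "synthetic_corpus_spec"))
  ks <- rep_len(spec$n_clusters, spec$n_stories)
  with_local_seed(spec$seed, {
    rows <- lapply(seq_len(spec$n_stories), function(i) {
      k <- ks[i]
      anchors <- sample.int(spec$n_anchor_pool, k)
      cl <- anchors[sample.int(k, spec$words_per_story, replace = TRUE)]
      variant <- sample.int(spec$n_variants, spec$words_per_story, replace = TRUE)
      toks <- sprintf("anchor%sxxv%s", letter_encode(cl), letter_encode(variant))
      # sentence lengths 8-12 tokens, terminal periods so splitting works
      sents <- character()
      j <- 1L
      while (j <= length(toks)) {
        len <- sample(8:12, 1L)
        sents <- c(sents, paste0(paste(toks[j:min(j + len - 1L, length(toks))],
                                       collapse = " "), "."))
        j <- j + len
      }
      data.frame(id = sprintf("story%04d", i),
                 text = paste(sents, collapse = " "),
                 true_clusters = k, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a rater matrix from true scores
#'
#' Each rater's raw score is `a * z(score) + e`, with rater noise
#' `e ~ N(0, noise_sd^2)` drawn independently per rater and story. Raw scores
#' are mapped onto the 1-5 rating scale by a single linear rescaling of the
#' whole matrix (range to `[1, 5]`), which preserves rank order and Pearson
#' correlations exactly.
#'
#' @param scores Numeric vector of true scores (e.g., DSI values).
#' @param a Loading of the true score (finite).
#' @param noise_sd Rater noise standard deviation (>= 0).
#' @param n_raters Number of raters (>= 1).
#' @param seed Integer seed.
#' @return Matrix stories x raters on the 1-5 scale.
#' @export
generate_ratings <- function(scores, a, noise_sd, n_raters, seed = 1L) {
  if (!is.finite(a)) abort_input("loading a must be finite")
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  if (n_raters < 1L) abort_input("n_raters must be >= 1")
  n <- length(scores)
  z <- if (stats::sd(scores) > 0) as.numeric(scale(scores)) else rep(0, n)
  raw <- with_local_seed(as.integer(seed), {
    matrix(a * z, n, n_raters) +
      matrix(stats::rnorm(n * n_raters, sd = noise_sd), n, n_raters)
  })
  rng <- range(raw)
  out <- if (rng[2] > rng[1]) 1 + 4 * (raw - rng[1]) / (rng[2] - rng[1])
         else matrix(3, n, n_raters)
  colnames(out) <- sprintf("rater%d", seq_len(n_raters))
  rownames(out) <- names(scores)
  out
}
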