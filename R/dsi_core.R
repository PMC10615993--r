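# The scoring function.
#
# DSI is the mean cosine distance over all unordered pairs of embeddings in a
# story.  The printed formula sums Dcos over the C(n,2) pairs; the divisor is
# the pair count, so the score is a mean bounded in [0, 2].  For normalized
# rows u_i the pooled mean follows from the identity
#   sum_{i<j} u_i.u_j = (||sum_i u_i||^2 - n) / 2,
# which avoids materialising the O(n^2) distance matrix.

#' Cosine distance between two vectors
#'
#' `1 - (x . y) / (||x|| ||y||)`; symmetric, in `[0, 2]`.
#'
#' @param x,y Numeric vectors of equal length, nonzero norm.
#' @return Scalar distance.
#' @export
cosine_distance <- function(x, y) {
  if (length(x) != length(y)) abort_input("vectors must share a dimension")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (!is.finite(nx) || !is.finite(ny) || nx == 0 || ny == 0) {
    abort_input("cosine distance undefined for zero-norm vectors",
                class = "dsitext_undefined_distance")
  }
  1 - sum(x * y) / (nx * ny)
}

# Mean pairwise cosine distance of the rows of a (>=2 row) matrix whose rows
# are already unit-normalized (callers normalize exactly once).
mean_pairwise_distance <- function(u) {
  n <- nrow(u)
  s <- colSums(u)
  sum_cos <- (sum(s^2) - n) / 2
  1 - sum_cos / (n * (n - 1) / 2)
}

#' Divergent semantic integration of an embedding set
#'
#' Mean pairwise cosine distance over the story's embeddings. When the set
#' carries vectors from several encoder layers, three pairings are available:
#' `"pooled"` (default; all pairs among the union of layers, the scheme used
#' for the contextual score), `"within_layer"` (mean of the per-layer pooled
#' scores), and `"cross_layer"` (pairs spanning different layers only).
#'
#' @param es An `embedding_set`.
#' @param pairing `"pooled"`, `"within_layer"` or `"cross_layer"`.
#' @return A `dsi_score`: list with `story_id`, `value`, `n`, `pair_count`,
#'   `dropped`. `value` is `NA` (not an error) when fewer than two vectors are
#'   available.
#' @export
dsi <- function(es, pairing = c("pooled", "within_layer", "cross_layer")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(es, "embedding_set"))
  n <- es$n
  if (n < 2L) {
    return(structure(list(story_id = es$story_id, value = NA_real_,
                          n = n, pair_count = 0L, dropped = es$dropped,
                          pairing = pairing),
                     class = "dsi_score"))
  }
  u <- normalize_rows(es$vectors)
  layer <- es$provenance$layer
  value <- switch(pairing,
    pooled = mean_pairwise_distance(u),
    within_layer = {
      if (all(is.na(layer))) mean_pairwise_distance(u) else {
        per <- vapply(split(seq_len(n), layer), function(ix) {
          if (length(ix) < 2L) NA_real_ else mean_pairwise_distance(u[ix, , drop = FALSE])
        }, 0)
        mean(per, na.rm = TRUE)
      }
    },
    cross_layer = {
      if (all(is.na(layer)) || length(unique(layer)) < 2L) {
        abort_input("cross_layer pairing requires >= 2 layers",
                    class = "dsitext_invalid_parameter")
      }
      groups <- split(seq_len(n), layer)
      sums <- lapply(groups, function(ix) colSums(u[ix, , drop = FALSE]))
      sizes <- lengths(groups)
      total_s <- Reduce(`+`, sums)
      # cross-layer cosine sum = (||S||^2 - sum_l ||S_l||^2) / 2
      cross_cos <- (sum(total_s^2) - sum(vapply(sums, function(s) sum(s^2), 0))) / 2
      cross_pairs <- (n^2 - sum(sizes^2)) / 2
      1 - cross_cos / cross_pairs
    })
  pair_count <- switch(pairing,
    pooled = n * (n - 1L) / 2,
    within_layer = n * (n - 1L) / 2,
    cross_layer = {
      sizes <- lengths(split(seq_len(n), layer))
      as.integer((n^2 - sum(sizes^2)) / 2)
    })
  # numeric guard: clamp negligible excursions outside [0, 2]
  if (is.finite(value)) value <- min(max(value, 0), 2)
  structure(list(story_id = es$story_id, value = value, n = n,
                 pair_count = as.integer(pair_count), dropped = es$dropped,
                 pairing = pairing),
            class = "dsi_score")
}

#' @export
print.dsi_score <- function(x, ...) {
  cat(sprintf("<dsi_score '%s': value=%s n=%d pairs=%d dropped=%d (%s)>\n",
              x$story_id,
              if (is.na(x$value)) "NA" else formatC(x$value, digits = 4, format = "f"),
              x$n, x$pair_count, x$dropped, x$pairing))
  invisible(x)
}

#' Score a batch of stories
#'
#' Runs preprocessing, embedding and scoring for every story and every model
#' in the model specification; a missing score (too few scorable tokens) is
#' emitted as `NA` with diagnostics, never dropped.
#'
#' @param stories A data.frame with columns `id` and `text`
#'   (see [read_stories()]).
#' @param models Named list of model specifications. Each element is a list
#'   with `backend` (`"static"`, `"contextual"` or `"synthetic"`) plus
#'   backend-specific fields: `table` (a `vector_table`) for static;
#'   `encoder` and `layers` for contextual; `seed`, `mode`, `lambda`, `d`,
#'   `layers`, `dispersion` for synthetic.
#' @param pairing Pairing mode passed to [dsi()].
#' @param stopwords Stop-word vector for static preprocessing.
#' @return A data.frame with one row per story x model: columns `id`, `model`,
#'   `dsi`, `n`, `pair_count`, `dropped`.
#' @export
dsi_batch <- function(stories, models, pairing = "pooled",
                      stopwords = read_stopwords()) {
  stopifnot(is.data.frame(stories), all(c("id", "text") %in% names(stories)))
  if (length(models) == 0L || is.null(names(models)) || any(!nzchar(names(models)))) {
    abort_input("models must be a non-empty named list",
                class = "dsitext_invalid_parameter")
  }
  rows <- vector("list", nrow(stories) * length(models))
  k <- 0L
  for (i in seq_len(nrow(stories))) {
    st <- story(stories$id[i], stories$text[i])
    for (mname in names(models)) {
      spec <- models[[mname]]
      es <- withCallingHandlers(
        score_one(st, spec, stopwords),
        warning = function(w) invokeRestart("muffleWarning"))
      sc <- dsi(es, pairing = pairing)
      k <- k + 1L
      rows[[k]] <- data.frame(id = st$id, model = mname, dsi = sc$value,
                              n = sc$n, pair_count = sc$pair_count,
                              dropped = sc$dropped, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

score_one <- function(st, spec, stopwords) {
  backend <- spec$backend %||% "synthetic"
  switch(backend,
    static = {
      ts <- prepare_static(st, stopwords)
      embed_static(ts, spec$table)
    },
    contextual = {
      ts <- prepare_contextual(st)
      embed_contextual(ts, spec$encoder, layers = spec$layers %||% c(6L, 7L),
                       include_punctuation = spec$include_punctuation %||% TRUE)
    },
    synthetic = {
      mode <- spec$mode %||% "static"
      ts <- if (mode == "static") prepare_static(st, stopwords)
            else prepare_contextual(st)
      embed_synthetic(ts, seed = spec$seed %||% 1L, mode = mode,
                      lambda = spec$lambda %||% 0.3, d = spec$d %||% 300L,
                      layers = spec$layers %||% c(6L, 7L),
                      anchor_sep = spec$anchor_sep %||% "xx",
                      dispersion = spec$dispersion %||% 0.3)
    },
    abort_input(sprintf("unknown backend '%s'", backend),
                class = "dsitext_configuration_error"))
}

#' Average DSI across models (composite score)
#'
#' Per-story arithmetic mean over the listed models, skipping missing scores;
#' stories missing every model stay missing. This is the composite used to
#' pool the context-independent models into a single score.
#'
#' @param scores A data.frame as returned by [dsi_batch()].
#' @param models Character vector of model labels to average; default all.
#' @param label Label of the composite in the output.
#' @return A data.frame `id`, `model`, `dsi`, `n_models` (models contributing).
#' @export
composite_mean <- function(scores, models = unique(scores$model),
                           label = "composite_ave") {
  if (length(models) == 0L) abort_input("empty model set",
                                        class = "dsitext_invalid_parameter")
  missing_models <- setdiff(models, unique(scores$model))
  if (length(missing_models) > 0L) {
    abort_input(paste0("model(s) not present in scores: ",
                       paste(missing_models, collapse = ", ")),
                class = "dsitext_invalid_parameter")
  }
  sub <- scores[scores$model %in% models, , drop = FALSE]
  ids <- unique(sub$id)
  vals <- vapply(ids, function(i) {
    v <- sub$dsi[sub$id == i]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  nmod <- vapply(ids, function(i) sum(!is.na(sub$dsi[sub$id == i])), 0L)
  data.frame(id = ids, model = label, dsi = unname(vals),
             n_models = unname(nmod), stringsAsFactors = FALSE)
}
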