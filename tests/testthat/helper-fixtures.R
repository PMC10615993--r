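# Shared fixture builders. Everything is generated in code; no binary data.

# Embedding set straight from a matrix (bypasses text preprocessing).
make_embedding_set <- function(m, layer = NA_integer_, story_id = "fixture") {
  n <- nrow(m)
  structure(list(story_id = story_id, vectors = m,
                 provenance = data.frame(token = paste0("t", seq_len(n)),
                                         sentence = 1L,
                                         layer = rep_len(layer, n),
                                         stringsAsFactors = FALSE),
                 n = n, dropped = 0L),
            class = "embedding_set")
}

# Brute-force DSI oracle: double loop over all unordered pairs.
dsi_oracle <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + cosine_distance(m[i, ], m[j, ])
    }
  }
  tot / (n * (n - 1) / 2)
}

# Small in-memory word-vector file.
write_vector_file <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

# Tiny orthogonal vector table covering a few test words.
toy_table <- function() {
  m <- diag(4)
  rownames(m) <- c("cat", "sat", "dog", "ran")
  vector_table(m, source = "toy")
}

toy_stopwords <- c("the", "a", "an", "and", "he", "it")

# Stories data.frame from texts.
stories_df <- function(texts, ids = sprintf("s%02d", seq_along(texts))) {
  data.frame(id = ids, text = texts, stringsAsFactors = FALSE)
}
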