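test_that("vector file dialects are auto-detected", {
  p1 <- write_vector_file(c("2 3", "a 1 0 0", "b 0 1 0"))
  t1 <- load_vector_file(p1)
  expect_equal(t1$d, 3L)
  expect_equal(nrow(t1$vectors), 2L)

  p2 <- write_vector_file(c("a 1 0", "b 0 1"))
  t2 <- load_vector_file(p2)
  expect_equal(t2$d, 2L)
  expect_equal(rownames(t2$vectors), c("a", "b"))
})

test_that("vector file format errors are reported with line numbers", {
  p <- write_vector_file(c("a 1 0", "b 0 1 0"))
  expect_error(load_vector_file(p), "line 2", class = "dsitext_format_error")
  p_empty <- write_vector_file(character())
  expect_error(load_vector_file(p_empty), class = "dsitext_format_error")
  p_dup <- write_vector_file(c("a 1 0", "A 0 1", "b 1 1"))
  expect_warning(tab <- load_vector_file(p_dup), "duplicate")
  expect_equal(unname(tab$vectors["a", ]), c(1, 0))
})

test_that("static embedding drops OOV tokens and keeps duplicates", {
  tab <- toy_table()
  ts <- prepare_static(story("x", "Cat sat."), toy_stopwords)
  es <- embed_static(ts, tab)
  expect_equal(es$n, 2L)
  expect_equal(es$dropped, 0L)

  ts2 <- prepare_static(story("x", "Cat qwzx."), toy_stopwords)
  es2 <- embed_static(ts2, tab)
  expect_equal(es2$n, 1L)
  expect_equal(es2$dropped, 1L)
  expect_true(isTRUE(attr(es2, "dsi_undefined")))

  ts3 <- prepare_static(story("x", "Cat cat."), toy_stopwords)
  es3 <- embed_static(ts3, tab)
  expect_equal(es3$n, 2L)
  expect_identical(es3$vectors[1, ], es3$vectors[2, ])
})

test_that("synthetic embeddings are deterministic and unit norm", {
  ts <- prepare_static(story("x", "Cat dog moon."), character())
  a <- embed_synthetic(ts, seed = 7, d = 32L)
  b <- embed_synthetic(ts, seed = 7, d = 32L)
  expect_identical(a$vectors, b$vectors)
  expect_equal(unname(sqrt(rowSums(a$vectors^2))), rep(1, a$n), tolerance = 1e-12)
  c2 <- embed_synthetic(ts, seed = 8, d = 32L)
  expect_false(identical(a$vectors, c2$vectors))
})

test_that("random-seed synthetic vectors behave like random unit vectors", {
  # mean cosine distance between the same token under different seeds ~ 1
  ts <- prepare_static(story("x", "cat."), character())
  d <- 100L
  vs <- vapply(1:300, function(s) embed_synthetic(ts, seed = s, d = d)$vectors[1, ],
               numeric(d))
  dists <- vapply(2:300, function(i) cosine_distance(vs[, 1], vs[, i]), 0)
  expect_equal(mean(dists), 1, tolerance = 0.05)
})

test_that("contextual extraction yields one vector per piece per layer", {
  enc <- synthetic_encoder(1, d = 16L)
  ts <- prepare_contextual(story("x", "One two three four"))
  expect_equal(embed_contextual(ts, enc, layers = c(6, 7))$n, 8L)
  expect_equal(embed_contextual(ts, enc, layers = 6)$n, 4L)
  ts2 <- prepare_contextual(story("x", "One two three. Four five six seven eight."))
  es2 <- embed_contextual(ts2, enc, layers = c(6, 7))
  expect_equal(es2$n, 2L * (4L + 6L))  # includes the two period tokens
  expect_equal(embed_contextual(ts2, enc, layers = c(6, 7),
                                include_punctuation = FALSE)$n, 16L)
})

test_that("contextual sentences are independent", {
  enc <- synthetic_encoder(3, d = 16L)
  a <- embed_contextual(prepare_contextual(story("x", "Cats sleep. Dogs run.")),
                        enc, layers = 6)
  b <- embed_contextual(prepare_contextual(story("x", "Cats sleep. Fish swim.")),
                        enc, layers = 6)
  first_a <- a$vectors[a$provenance$sentence == 1, ]
  first_b <- b$vectors[b$provenance$sentence == 1, ]
  expect_identical(first_a, first_b)
})

test_that("lambda = 0 contextual layer 1 equals the static embedding", {
  ts <- prepare_contextual(story("x", "alpha beta gamma"))
  ctx <- embed_synthetic(ts, seed = 5, mode = "contextual", lambda = 0,
                         d = 24L, layers = 1L)
  stat <- embed_synthetic(ts, seed = 5, mode = "static", d = 24L)
  expect_equal(ctx$vectors, stat$vectors, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("over-budget sentences are chunked with a warning", {
  enc <- synthetic_encoder(1, d = 8L, max_tokens = 5L)
  long <- paste(rep("word", 12), collapse = " ")
  expect_warning(es <- embed_contextual(prepare_contextual(story("x", long)),
                                        enc, layers = 6), "chunked")
  expect_equal(es$n, 12L)
})

test_that("permuting tokens permutes static embeddings identically", {
  tab <- vector_table({
    m <- matrix(rnorm(5 * 6), 5, 6); rownames(m) <- letters[1:5]; m
  })
  ts <- prepare_static(story("x", "a b c d e."), character())
  es <- embed_static(ts, tab)
  ts_rev <- prepare_static(story("x", "e d c b a."), character())
  es_rev <- embed_static(ts_rev, tab)
  expect_equal(es$vectors[5:1, ], es_rev$vectors, ignore_attr = TRUE)
})

test_that("invalid lambda and layers are rejected", {
  ts <- prepare_contextual(story("x", "one two"))
  expect_error(embed_synthetic(ts, 1, lambda = 1.5),
               class = "dsitext_invalid_parameter")
  enc <- synthetic_encoder(1, d = 8L)
  expect_error(embed_contextual(ts, enc, layers = 99),
               class = "dsitext_invalid_parameter")
  expect_error(embed_contextual(ts, encoder = list()),
               class = "dsitext_configuration_error")
})
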