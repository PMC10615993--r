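test_that("cosine distance matches the analytic cases", {
  expect_equal(cosine_distance(c(1, 0), c(2, 0)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  expect_error(cosine_distance(c(0, 0), c(1, 0)),
               class = "dsitext_undefined_distance")
  expect_error(cosine_distance(c(1, 0), c(1, 0, 0)),
               class = "dsitext_invalid_input")
})

test_that("dsi matches enumerated analytic cases", {
  expect_equal(dsi(make_embedding_set(rbind(c(1, 0), c(0, 1))))$value, 1)
  expect_equal(dsi(make_embedding_set(rbind(c(1, 0), c(1, 0), c(0, 1))))$value,
               2 / 3)
  two_layer <- make_embedding_set(rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1)),
                                  layer = c(6L, 6L, 7L, 7L))
  expect_equal(dsi(two_layer, "pooled")$value, 2 / 3)
  expect_equal(dsi(two_layer, "pooled")$pair_count, 6L)
})

test_that("layer pairings agree with pair enumeration", {
  set.seed(11)
  m <- matrix(rnorm(6 * 4), 6, 4)
  es <- make_embedding_set(m, layer = c(6L, 6L, 6L, 7L, 7L, 7L))
  u <- m / sqrt(rowSums(m^2))
  # within_layer: mean of the two per-layer pooled means
  w_or <- mean(c(dsi_oracle(u[1:3, ]), dsi_oracle(u[4:6, ])))
  expect_equal(dsi(es, "within_layer")$value, w_or, tolerance = 1e-12)
  # cross_layer: pairs spanning layers only
  cross <- outer(1:3, 4:6, Vectorize(function(i, j) cosine_distance(u[i, ], u[j, ])))
  expect_equal(dsi(es, "cross_layer")$value, mean(cross), tolerance = 1e-12)
  expect_equal(dsi(es, "cross_layer")$pair_count, 9L)
  expect_error(dsi(make_embedding_set(m), "cross_layer"),
               class = "dsitext_invalid_parameter")
})

test_that("dsi equals the brute-force oracle on random sets", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    d <- sample(2:20, 1)
    m <- matrix(rnorm(n * d), n, d)
    expect_equal(dsi(make_embedding_set(m))$value, dsi_oracle(m),
                 tolerance = 1e-10)
  }
})

test_that("dsi is permutation- and scale-invariant, bounded, zero iff parallel", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    m <- matrix(rnorm(n * 8), n, 8)
    v <- dsi(make_embedding_set(m))$value
    expect_gte(v, 0); expect_lte(v, 2)
    perm <- sample(n)
    expect_equal(dsi(make_embedding_set(m[perm, ]))$value, v, tolerance = 1e-12)
    expect_equal(dsi(make_embedding_set(m * 3.7))$value, v, tolerance = 1e-10)
  }
  parallel <- make_embedding_set(rbind(c(1, 1), c(2, 2), c(0.5, 0.5)))
  expect_equal(dsi(parallel)$value, 0, tolerance = 1e-12)
})

test_that("appending a duplicate changes the score exactly as the oracle predicts", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(3:15, 1)
    m <- matrix(rnorm(n * 5), n, 5)
    m2 <- rbind(m, m[sample(n, 1), ])
    expect_equal(dsi(make_embedding_set(m2))$value, dsi_oracle(m2),
                 tolerance = 1e-10)
  }
})

test_that("undefined scores surface as NA, not errors", {
  one <- make_embedding_set(matrix(c(1, 0), 1, 2))
  sc <- dsi(one)
  expect_true(is.na(sc$value))
  expect_equal(sc$pair_count, 0L)
})

test_that("dsi_batch scores every story x model and is reproducible", {
  stories <- stories_df(c("The cat sat on the mat today.",
                          "Dogs run. Cats sleep.",
                          "qq."))  # one token -> NA score
  models <- list(syn1 = list(backend = "synthetic", seed = 5, d = 16L),
                 syn2 = list(backend = "synthetic", seed = 9, d = 16L))
  out <- dsi_batch(stories, models, stopwords = toy_stopwords)
  expect_equal(nrow(out), 6L)
  expect_true(is.na(out$dsi[out$id == "s03" & out$model == "syn1"]))
  out2 <- dsi_batch(stories, models, stopwords = toy_stopwords)
  expect_identical(out, out2)
  expect_error(dsi_batch(stories, list()), class = "dsitext_invalid_parameter")
})

test_that("composite_mean averages models and respects missingness", {
  scores <- data.frame(
    id = rep(c("a", "b", "c"), each = 2),
    model = rep(c("m1", "m2"), 3),
    dsi = c(0.8, 0.6, 0.5, NA, NA, NA))
  comp <- composite_mean(scores, c("m1", "m2"))
  expect_equal(comp$dsi[comp$id == "a"], 0.7)
  expect_equal(comp$dsi[comp$id == "b"], 0.5)
  expect_equal(comp$n_models[comp$id == "b"], 1L)
  expect_true(is.na(comp$dsi[comp$id == "c"]))
  expect_error(composite_mean(scores, character()),
               class = "dsitext_invalid_parameter")
  expect_error(composite_mean(scores, "nope"),
               class = "dsitext_invalid_parameter")
})
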