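test_that("pearson_ci matches the Fisher-z arithmetic and degenerate cases", {
  expect_equal(round(fisher_ci(0.77, 179), 2), c(0.70, 0.82))
  set.seed(1)
  x <- rnorm(60); y <- x + rnorm(60)
  out <- pearson_ci(x, y)
  expect_equal(out$r, cor(x, y))
  expect_equal(out$ci, tanh(atanh(out$r) + c(-1, 1) * qnorm(.975) / sqrt(57)),
               tolerance = 1e-12)
  expect_equal(pearson_ci(x, 2 * x + 5)$r, 1)
  expect_error(pearson_ci(x, rep(1, 60)), class = "dsitext_invalid_input")
})

test_that("pearson_ci is invariant under positive affine transforms", {
  set.seed(2)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  a <- pearson_ci(x, y)
  b <- pearson_ci(3 * x + 2, 10 * y - 4)
  expect_equal(a$r, b$r, tolerance = 1e-12)
  expect_equal(a$ci, b$ci, tolerance = 1e-12)
})

test_that("dependent-correlation comparison: nulls, signs, and input checks", {
  expect_equal(compare_dependent_correlations(.6, .6, .4, 100)$z, 0)
  out <- compare_dependent_correlations(.8, .5, .6, 200)
  expect_gt(out$z, 0)
  expect_equal(out$diff, 0.3)
  flipped <- compare_dependent_correlations(.5, .8, .6, 200)
  expect_equal(flipped$z, -out$z, tolerance = 1e-12)
  expect_error(compare_dependent_correlations(.9, .9, -.9, 100),
               "positive semidefinite")
  expect_error(compare_dependent_correlations(.5, .4, .3, 5),
               class = "dsitext_invalid_input")
})

test_that("dependent-correlation z is calibrated against a simulation oracle", {
  # Under rho1y = rho2y the test should reject at ~ alpha.
  set.seed(99)
  n <- 120; reps <- 800
  R <- matrix(c(1, .6, .5, .6, 1, .5, .5, .5, 1), 3, 3)
  ch <- chol(R)
  rejections <- 0
  for (i in seq_len(reps)) {
    z <- matrix(rnorm(n * 3), n, 3) %*% ch
    rs <- cor(z)
    out <- compare_dependent_correlations(rs[1, 3], rs[2, 3], rs[1, 2], n)
    if (out$p < .05) rejections <- rejections + 1
  }
  expect_lt(abs(rejections / reps - 0.05), 0.025)
})

test_that("independent-correlation comparison matches the closed form", {
  out <- compare_independent_correlations(.66, 107, .52, 119)
  expect_equal(out$z,
               (atanh(.66) - atanh(.52)) / sqrt(1 / 104 + 1 / 116),
               tolerance = 1e-12)
  expect_equal(compare_independent_correlations(.5, 50, .5, 80)$z, 0)
  sw <- compare_independent_correlations(.52, 119, .66, 107)
  expect_equal(sw$z, -out$z)
  expect_equal(sw$p, out$p)
})

test_that("sr_ave: identical raters give 1; two-rater closed form holds", {
  m <- matrix(rep(rnorm(30), 3), 30, 3)
  expect_equal(single_rater_average(m)$sr_ave, 1)
  # two independent raters: each correlates sqrt((1 + r12)/2) with the mean
  set.seed(5)
  n <- 10000
  m2 <- cbind(rnorm(n), rnorm(n))
  out <- single_rater_average(m2)
  expect_equal(out$sr_ave, sqrt(0.5), tolerance = 0.03)
  # a constant rater is excluded with a warning
  m3 <- cbind(rnorm(50), rnorm(50), rep(2, 50))
  expect_warning(o3 <- single_rater_average(m3), "zero variance")
  expect_true(is.na(o3$per_rater[3]))
})

test_that("omega recovers the equal-loading closed form", {
  set.seed(31)
  n <- 20000; k <- 7; lambda <- 0.8
  f <- rnorm(n)
  x <- matrix(lambda * f, n, k) + matrix(rnorm(n * k, sd = sqrt(1 - lambda^2)), n, k)
  out <- omega_single_factor(x)
  target <- (k * lambda)^2 / ((k * lambda)^2 + k * (1 - lambda^2))
  expect_equal(out$omega, target, tolerance = 0.01)
  expect_false(out$heywood)
})

test_that("omega of independent indicators is near zero; degenerate inputs flagged", {
  # ML factor analysis can hit a boundary (Heywood) solution on pure noise;
  # the near-zero expectation applies to non-degenerate fits, which the
  # function distinguishes via the heywood flag.
  set.seed(32)
  x <- matrix(rnorm(20000 * 7), 20000, 7)
  out <- suppressWarnings(omega_single_factor(x))
  expect_false(out$heywood)
  expect_lt(out$omega, 0.05)
  expect_error(omega_single_factor(matrix(rnorm(30), 10, 3)[, 1:2]),
               class = "dsitext_invalid_input")
})

test_that("icc: perfect agreement, pure noise, and Spearman-Brown ordering", {
  base <- rnorm(20)
  perfect <- cbind(base, base, base)
  out <- icc(perfect)
  expect_equal(out$icc_single, 1)
  expect_equal(out$icc_average, 1)
  set.seed(77)
  noise <- matrix(rnorm(5000 * 3), 5000, 3)
  out2 <- icc(noise)
  expect_lt(abs(out2$icc_single), 0.03)
  set.seed(78)
  mixed <- rnorm(200) + matrix(rnorm(200 * 4, sd = 1), 200, 4)
  out3 <- icc(mixed)
  expect_gt(out3$icc_average, out3$icc_single)
  expect_warning(icc(rbind(mixed, c(NA, 1, 1, 1))), "dropped")
})

test_that("hierarchical regression: exact nested-R2 identities", {
  set.seed(8)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  d_exact <- data.frame(y = x1, x1 = x1, x2 = x2)
  # lm warns about the (intentional) perfect fit
  out <- suppressWarnings(hierarchical_regression(d_exact, "y", "x1", "x2",
                                                  n_boot = 0))
  expect_equal(unname(out$r2["step1"]), 1, tolerance = 1e-12)
  expect_equal(out$delta_r2, 0, tolerance = 1e-12)
  d2 <- data.frame(y = x1 + x2, x1 = x1, x2 = x2)
  out2 <- suppressWarnings(hierarchical_regression(d2, "y", "x1", "x2",
                                                   n_boot = 0))
  expect_equal(out2$delta_r2,
               unname(out2$r2["step2"] - out2$r2["step1"]), tolerance = 1e-12)
  expect_gte(out2$r2["step2"], out2$r2["step1"])
  d3 <- data.frame(y = rnorm(n), x1 = x1, x2 = 2 * x1)
  expect_error(hierarchical_regression(d3, "y", "x1", "x2", n_boot = 0),
               "collinearity")
})

test_that("hierarchical regression recovers standardized effects", {
  set.seed(9)
  n <- 5000
  z1 <- rnorm(n); z2 <- rnorm(n)
  y <- 0.3 * z1 + 0.6 * z2 + rnorm(n, sd = sqrt(1 - 0.09 - 0.36))
  dat <- data.frame(y = y, z1 = z1, z2 = z2)
  out <- hierarchical_regression(dat, "y", "z1", "z2", n_boot = 200, seed = 4)
  b_std <- out$step2$b_std[match(c("z1", "z2"), out$step2$term)]
  expect_equal(b_std, c(0.3, 0.6), tolerance = 0.03)
  expect_true(out$delta_r2_ci[1] <= out$delta_r2 &&
                out$delta_r2 <= out$delta_r2_ci[2])
})

test_that("group comparison: raw data equals the summary-statistic formula", {
  set.seed(10)
  xA <- rnorm(40, 1, 2); xB <- rnorm(55, 0, 1.5)
  raw <- group_comparison(xA, xB)
  summ <- group_comparison_stats(mean(xA), sd(xA), 40, mean(xB), sd(xB), 55)
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$d, summ$d, tolerance = 1e-12)
  ident <- group_comparison(xA, xA)
  expect_equal(ident$t, 0)
  expect_equal(ident$d, 0)
  sw <- group_comparison(xB, xA)
  expect_equal(sw$t, -raw$t)
  expect_equal(sw$d, -raw$d)
  expect_error(group_comparison(rep(1, 5), rep(1, 6)),
               class = "dsitext_invalid_input")
})
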