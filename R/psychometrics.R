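# Validation statistics: correlation CIs, dependent and independent
# correlation comparisons, rater-agreement indices, one-factor omega
# reliability, intraclass correlations, hierarchical (incremental-validity)
# regression, and two-group comparisons.

#' Fisher-z confidence interval for a correlation
#'
#' @param r Pearson correlation.
#' @param n Sample size (>= 4).
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n < 4L) abort_input("Fisher CI requires n >= 4")
  if (abs(r) >= 1) return(c(r, r))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Numeric vectors.
#' @param level Confidence level.
#' @return List with `r`, `ci`, `n`, `p` (two-sided t test).
#' @export
pearson_ci <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) abort_input("pearson_ci requires n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_input("correlation undefined: zero variance")
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) < 1) {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  } else 0
  list(r = r, ci = fisher_ci(r, n, level), n = n, p = p)
}

#' Compare two dependent overlapping correlations (Steiger's z)
#'
#' Tests r(1,y) against r(2,y) measured on the same sample, sharing variable
#' y, using the Fisher-z statistic with the back-transformed mean correlation
#' (Steiger's Z1* form):
#' `z = (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2*s)` where `s` is the covariance
#' term evaluated at `rbar = tanh((z1 + z2)/2)`. The confidence interval for
#' the difference uses Zou's (2007) method.
#'
#' @param r1y,r2y Correlations of predictors 1 and 2 with the shared variable.
#' @param r12 Correlation between the two predictors.
#' @param n Sample size (>= 10).
#' @param level Confidence level for the difference CI.
#' @return List with `z`, `p` (two-sided), `diff`, `ci`.
#' @export
compare_dependent_correlations <- function(r1y, r2y, r12, n, level = 0.95) {
  if (any(abs(c(r1y, r2y, r12)) >= 1)) abort_input("correlations must satisfy |r| < 1")
  if (n < 10L) abort_input("compare_dependent_correlations requires n >= 10")
  R <- matrix(c(1, r12, r1y, r12, 1, r2y, r1y, r2y, 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort_input("correlation matrix not positive semidefinite")
  z1 <- atanh(r1y); z2 <- atanh(r2y)
  rbar <- tanh((z1 + z2) / 2)
  s <- (r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)) /
    (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2 * s)
  p <- 2 * stats::pnorm(-abs(z))
  # Zou (2007) CI for the difference of two dependent correlations
  ci1 <- fisher_ci(r1y, n, level); ci2 <- fisher_ci(r2y, n, level)
  cterm <- ((r12 - 0.5 * r1y * r2y) * (1 - r1y^2 - r2y^2 - r12^2) + r12^3) /
    ((1 - r1y^2) * (1 - r2y^2))
  L <- r1y - r2y - sqrt((r1y - ci1[1])^2 + (ci2[2] - r2y)^2 -
                          2 * cterm * (r1y - ci1[1]) * (ci2[2] - r2y))
  U <- r1y - r2y + sqrt((ci1[2] - r1y)^2 + (r2y - ci2[1])^2 -
                          2 * cterm * (ci1[2] - r1y) * (r2y - ci2[1]))
  list(z = z, p = p, diff = r1y - r2y, ci = c(L, U))
}

#' Compare two independent correlations
#'
#' Fisher-z test: `z = (atanh(rA) - atanh(rB)) / sqrt(1/(nA-3) + 1/(nB-3))`.
#'
#' @param rA,rB Correlations from the two independent groups.
#' @param nA,nB Group sample sizes (>= 4 each).
#' @return List with `z`, `p` (two-sided), `diff`.
#' @export
compare_independent_correlations <- function(rA, nA, rB, nB) {
  if (any(abs(c(rA, rB)) >= 1)) abort_input("correlations must satisfy |r| < 1")
  if (nA < 4L || nB < 4L) abort_input("each group requires n >= 4")
  z <- (atanh(rA) - atanh(rB)) / sqrt(1 / (nA - 3) + 1 / (nB - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), diff = rA - rB)
}

#' Average single-rater correlation with the rater mean
#'
#' For each rater, the Pearson correlation between that rater's scores and
#' the across-rater mean score; the statistic is the mean of those
#' correlations. It benchmarks how well one typical human rater tracks the
#' rater consensus, a ceiling for automated scores. By default each rater is
#' included in the mean they are correlated with; `leave_one_out = TRUE`
#' correlates each rater with the mean of the others.
#'
#' @param ratings Numeric matrix or data.frame, stories x raters.
#' @param leave_one_out Exclude the rater from the consensus mean.
#' @return List with `sr_ave` and `per_rater` correlations.
#' @export
single_rater_average <- function(ratings, leave_one_out = FALSE) {
  m <- as.matrix(ratings)
  if (ncol(m) < 2L) abort_input("sr_ave requires >= 2 raters")
  rs <- vapply(seq_len(ncol(m)), function(j) {
    target <- if (leave_one_out) rowMeans(m[, -j, drop = FALSE], na.rm = TRUE)
              else rowMeans(m, na.rm = TRUE)
    ok <- is.finite(m[, j]) & is.finite(target)
    if (sum(ok) < 4L || stats::sd(m[ok, j]) == 0 || stats::sd(target[ok]) == 0) {
      warning(sprintf("rater %d has zero variance or too few ratings; excluded", j),
              call. = FALSE)
      return(NA_real_)
    }
    stats::cor(m[ok, j], target[ok])
  }, 0)
  list(sr_ave = mean(rs, na.rm = TRUE), per_rater = rs)
}

#' Omega reliability from a single-factor model
#'
#' Fits a one-factor model by maximum likelihood (via [stats::factanal()]) to
#' the standardized indicators and returns McDonald's omega,
#' `(sum lambda)^2 / ((sum lambda)^2 + sum theta)`, with `lambda` the
#' standardized loadings and `theta` the unique variances. A Heywood solution
#' (uniqueness at the lower bound) is flagged with a warning.
#'
#' @param indicators Numeric matrix/data.frame, observations x k indicators
#'   (k >= 3).
#' @return List with `omega`, `loadings`, `uniquenesses`, `heywood`.
#' @export
omega_single_factor <- function(indicators) {
  m <- as.matrix(indicators)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 3L) abort_input("omega requires >= 3 indicators")
  if (nrow(m) <= k) abort_input("omega requires more observations than indicators")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant indicator(s): omega at the degenerate boundary", call. = FALSE)
  }
  fit <- tryCatch(
    stats::factanal(covmat = stats::cov2cor(stats::cov(m)), factors = 1,
                    n.obs = nrow(m)),
    error = function(e) abort_input(paste0("one-factor model failed: ",
                                           conditionMessage(e))))
  lambda <- abs(as.numeric(fit$loadings))
  theta <- as.numeric(fit$uniquenesses)
  heywood <- any(theta <= 0.005 + 1e-12)
  if (heywood) {
    warning("Heywood case: uniqueness at lower bound; omega near boundary",
            call. = FALSE)
    theta <- pmax(theta, 0)
  }
  omega <- sum(lambda)^2 / (sum(lambda)^2 + sum(theta))
  list(omega = omega, loadings = lambda, uniquenesses = theta, heywood = heywood)
}

#' Intraclass correlations for a rating matrix
#'
#' Two-way random-effects, absolute-agreement ICCs from the standard
#' mean-squares decomposition: `ICC(2,1)` for a single rater and `ICC(2,k)`
#' for the k-rater average. Stories with any missing rating are dropped
#' (listwise) with a warning.
#'
#' @param ratings Numeric matrix/data.frame, stories x raters.
#' @return List with `icc_single`, `icc_average`, `n`, `k`.
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  if (ncol(m) < 2L || nrow(m) < 2L) abort_input("ICC requires >= 2 raters and >= 2 stories")
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sprintf("%d incomplete story row(s) dropped for ICC", sum(!complete)),
            call. = FALSE)
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) abort_input("ICC requires >= 2 complete stories")
  row_means <- rowMeans(m); col_means <- colMeans(m); grand <- mean(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  list(icc_single = icc1, icc_average = icck, n = n, k = k)
}

#' Hierarchical (incremental-validity) regression
#'
#' Ordinary least squares in two nested steps: the baseline covariates are
#' entered first, then the focal predictors. Reports unstandardized and
#' standardized coefficients with confidence intervals, per-step R-squared,
#' and the R-squared increment with a seeded percentile-bootstrap confidence
#' interval.
#'
#' @param data Data.frame holding all variables; complete cases are used.
#' @param outcome Name of the criterion column.
#' @param step1,step2 Character vectors of predictor names; step 2 is added
#'   on top of step 1.
#' @param n_boot Bootstrap resamples for the delta-R-squared CI (0 skips it).
#' @param seed Seed for the bootstrap.
#' @param level Confidence level.
#' @return A `hierarchical_regression` object: per-step coefficient tables
#'   (`b`, CI, `b_std`, std CI), `r2`, `delta_r2`, `delta_r2_ci`.
#' @export
hierarchical_regression <- function(data, outcome, step1, step2,
                                    n_boot = 2000L, seed = 1L, level = 0.95) {
  vars <- c(outcome, step1, step2)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0L) {
    abort_input(paste0("variable(s) not in data: ",
                       paste(missing_vars, collapse = ", ")))
  }
  df <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n <- nrow(df)
  if (n <= length(c(step1, step2)) + 1L) abort_input("too few complete cases")
  qrX <- qr(as.matrix(cbind(1, df[c(step1, step2)])))
  if (qrX$rank < length(c(step1, step2)) + 1L) {
    abort_input("perfect collinearity among predictors")
  }
  fit_step <- function(preds) {
    f <- stats::as.formula(paste(outcome, "~", paste(preds, collapse = " + ")))
    fit <- stats::lm(f, data = df)
    zdf <- as.data.frame(lapply(df, function(v) as.numeric(scale(v))))
    fitz <- stats::lm(f, data = zdf)
    ci <- stats::confint(fit, level = level)
    ciz <- stats::confint(fitz, level = level)
    coefs <- data.frame(
      term = names(stats::coef(fit)),
      b = as.numeric(stats::coef(fit)),
      b_lo = ci[, 1], b_hi = ci[, 2],
      b_std = as.numeric(stats::coef(fitz)),
      b_std_lo = ciz[, 1], b_std_hi = ciz[, 2],
      row.names = NULL, stringsAsFactors = FALSE)
    list(fit = fit, coefs = coefs, r2 = summary(fit)$r.squared)
  }
  s1 <- fit_step(step1)
  s2 <- fit_step(c(step1, step2))
  delta <- s2$r2 - s1$r2
  delta_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    boot_delta <- with_local_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(b) {
        ix <- sample.int(n, replace = TRUE)
        db <- df[ix, , drop = FALSE]
        f1 <- stats::lm(stats::as.formula(
          paste(outcome, "~", paste(step1, collapse = " + "))), data = db)
        f2 <- stats::lm(stats::as.formula(
          paste(outcome, "~", paste(c(step1, step2), collapse = " + "))), data = db)
        summary(f2)$r.squared - summary(f1)$r.squared
      }, 0)
    })
    delta_ci <- unname(stats::quantile(boot_delta,
                                       c((1 - level) / 2, 1 - (1 - level) / 2)))
  }
  structure(list(step1 = s1$coefs, step2 = s2$coefs,
                 r2 = c(step1 = s1$r2, step2 = s2$r2),
                 delta_r2 = delta, delta_r2_ci = delta_ci,
                 n = n, n_boot = n_boot),
            class = "hierarchical_regression")
}

#' @export
print.hierarchical_regression <- function(x, ...) {
  cat(sprintf("Hierarchical regression (n = %d)\n", x$n))
  cat(sprintf("Step 1 R^2 = %.3f; Step 2 R^2 = %.3f; Delta R^2 = %.3f",
              x$r2["step1"], x$r2["step2"], x$delta_r2))
  if (!is.na(x$delta_r2_ci[1])) {
    cat(sprintf(" [%.3f, %.3f]", x$delta_r2_ci[1], x$delta_r2_ci[2]))
  }
  cat("\n\nStep 2 coefficients:\n")
  print(x$step2, digits = 3)
  invisible(x)
}

#' Two-group comparison (Welch t and Cohen's d)
#'
#' Welch's t with Satterthwaite degrees of freedom; Cohen's d with the pooled
#' standard deviation. The d confidence interval uses the noncentral-t
#' method, falling back to the normal approximation if inversion fails.
#'
#' @param xA,xB Numeric vectors for the two groups.
#' @return List with `t`, `df`, `p`, `d`, `d_ci`, group summaries.
#' @export
group_comparison <- function(xA, xB) {
  xA <- xA[is.finite(xA)]; xB <- xB[is.finite(xB)]
  nA <- length(xA); nB <- length(xB)
  if (nA < 2L || nB < 2L) abort_input("each group requires n >= 2")
  sA <- stats::sd(xA); sB <- stats::sd(xB)
  if (sA == 0 && sB == 0) abort_input("comparison undefined: zero variance in both groups")
  res <- group_comparison_stats(mean(xA), sA, nA, mean(xB), sB, nB)
  res$summary <- data.frame(group = c("A", "B"),
                            mean = c(mean(xA), mean(xB)),
                            sd = c(sA, sB), n = c(nA, nB))
  res
}

#' Two-group comparison from summary statistics
#'
#' Same statistics as [group_comparison()] computed from printed means,
#' standard deviations and sample sizes.
#'
#' @param mA,sdA,nA,mB,sdB,nB Group means, SDs and sizes.
#' @param level Confidence level for the d CI.
#' @return List with `t`, `df`, `p`, `d`, `d_ci`.
#' @export
group_comparison_stats <- function(mA, sdA, nA, mB, sdB, nB, level = 0.95) {
  seA2 <- sdA^2 / nA; seB2 <- sdB^2 / nB
  t <- (mA - mB) / sqrt(seA2 + seB2)
  df <- (seA2 + seB2)^2 / (seA2^2 / (nA - 1) + seB2^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  sp <- sqrt(((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2))
  d <- (mA - mB) / sp
  d_ci <- d_ci_noncentral(d, nA, nB, level)
  list(t = t, df = df, p = p, d = d, d_ci = d_ci)
}

# Cohen's d CI by inverting the noncentral-t distribution of
# t* = d * sqrt(nA*nB/(nA+nB)); normal approximation as fallback.
d_ci_noncentral <- function(d, nA, nB, level = 0.95) {
  mult <- sqrt(nA * nB / (nA + nB))
  tstar <- d * mult
  dfp <- nA + nB - 2
  alpha <- (1 - level) / 2
  pt_nc <- function(q, ncp) suppressWarnings(stats::pt(q, dfp, ncp = ncp))
  lo <- tryCatch(
    stats::uniroot(function(nc) pt_nc(tstar, nc) - (1 - alpha),
                   interval = tstar + c(-8, 8) * max(1, abs(tstar)))$root,
    error = function(e) NA_real_)
  hi <- tryCatch(
    stats::uniroot(function(nc) pt_nc(tstar, nc) - alpha,
                   interval = tstar + c(-8, 8) * max(1, abs(tstar)))$root,
    error = function(e) NA_real_)
  if (is.na(lo) || is.na(hi)) {
    se_d <- sqrt((nA + nB) / (nA * nB) + d^2 / (2 * (nA + nB)))
    q <- stats::qnorm(1 - alpha)
    return(c(d - q * se_d, d + q * se_d))
  }
  c(lo, hi) / mult
}
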