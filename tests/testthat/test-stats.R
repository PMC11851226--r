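# recursive partial-correlation identity, first- and second-order
partial_r_order1 <- function(rxy, rxc, ryc) {
  (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2))
}
partial_r_order2 <- function(x, y, c1, c2) {
  r <- function(a, b) cor(a, b)
  rxy_1 <- partial_r_order1(r(x, y), r(x, c1), r(y, c1))
  rxc2_1 <- partial_r_order1(r(x, c2), r(x, c1), r(c2, c1))
  ryc2_1 <- partial_r_order1(r(y, c2), r(y, c1), r(c2, c1))
  partial_r_order1(rxy_1, rxc2_1, ryc2_1)
}

test_that("winsorization reproduces the worked example and respects bounds", {
  x <- c(0, 1, 2, 3, 10)
  w <- winsorize_group(x)
  # mean 3.2, sample SD 3.962..., upper bound 9.1434
  expect_equal(as.numeric(w), c(0, 1, 2, 3, 3.2 + 1.5 * sd(x)))
  expect_equal(as.numeric(w)[5], 9.143, tolerance = 5e-4)
  expect_identical(attr(w, "n_replaced"), 1L)

  # data with no value beyond its own bounds is untouched
  w2 <- winsorize_group(c(1, 2, 3, 4, 5))
  expect_equal(as.numeric(w2), c(1, 2, 3, 4, 5))
  expect_identical(attr(w2, "n_replaced"), 0L)

  # symmetric data within 1.5 SD is unchanged
  a <- c(-1, 0, 1)
  expect_equal(as.numeric(winsorize_group(a)), a)

  expect_warning(wz <- winsorize_group(c(2, 2, 2)), "zero standard deviation")
  expect_equal(as.numeric(wz), c(2, 2, 2))
  expect_error(winsorize_group(c(1, 2)), "n >= 3")
})

test_that("winsorized output never leaves the computed bounds", {
  set.seed(41)
  for (rep in 1:25) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 10))
    w <- as.numeric(winsorize_group(x))
    lo <- mean(x) - 1.5 * sd(x); hi <- mean(x) + 1.5 * sd(x)
    expect_true(all(w >= lo - 1e-12 & w <= hi + 1e-12))
    inb <- x >= lo & x <= hi
    expect_identical(w[inb], x[inb])
  }
})

test_that("partial correlation matches closed-form and regression oracles", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 10L
    x <- rnorm(n); y <- rnorm(n)
    C <- matrix(rnorm(2 * n), n, 2)
    res <- partial_correlation(x, y, C)
    # correlation-matrix recursion oracle
    expect_equal(res$r, partial_r_order2(x, y, C[, 1], C[, 2]), tolerance = 1e-10)
    # residual-regression brute force
    rx <- resid(lm(x ~ C)); ry <- resid(lm(y ~ C))
    expect_equal(res$r, cor(rx, ry), tolerance = 1e-10)
    expect_identical(res$df, n - 2L - 2L)
    t_ref <- res$r * sqrt(res$df / (1 - res$r^2))
    expect_equal(res$p, 2 * pt(-abs(t_ref), res$df), tolerance = 1e-12)
  }
})

test_that("partial correlation degenerates gracefully", {
  set.seed(43)
  n <- 20
  x <- rnorm(n); y <- rnorm(n)
  # k = 0 equals plain Pearson
  expect_equal(partial_correlation(x, y)$r, cor(x, y), tolerance = 1e-12)
  # symmetric in (x, y)
  C <- matrix(rnorm(n), n, 1)
  expect_equal(partial_correlation(x, y, C)$r, partial_correlation(y, x, C)$r,
               tolerance = 1e-12)
  # y equal to a covariate: zero residual variance is an error
  expect_error(partial_correlation(x, C[, 1], C), "zero residual variance")
  # rank-deficient covariates
  expect_error(partial_correlation(x, y, cbind(C, C)), "rank-deficient")
  # |r| = 1 yields an underflow-safe, strictly positive p
  p_perfect <- partial_correlation(x, 2 * x + 1)$p
  expect_gt(p_perfect, 0)
  expect_lt(p_perfect, 1e-250)
})

test_that("null partial-correlation p-values are uniform", {
  ps <- vapply(1:500, function(s) {
    set.seed(5000 + s)
    partial_correlation(rnorm(18), rnorm(18), matrix(rnorm(36), 18, 2))$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni correction divides alpha and inflates p", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 15), 0.05 / 15)
  expect_equal(round(bonferroni_alpha(0.05, 15), 5), 0.00333)
  expect_equal(adjust_p(0.02, m = 10), 0.2)
  expect_equal(adjust_p(c(0.5, 1e-4), m = 4), c(1, 4e-4))
})

# brute-force two-way mixed ANOVA (2 groups x 2 times) from cell sums of squares
mixed_anova_oracle <- function(t1, t2, g) {
  y <- c(t1, t2)
  subj <- rep(seq_along(t1), 2)
  time <- rep(1:2, each = length(t1))
  gg <- rep(g, 2)
  N <- length(t1)
  a <- length(unique(g))
  grand <- mean(y)
  sm <- tapply(y, subj, mean)
  gm <- tapply(y, gg, mean)
  tm <- tapply(y, time, mean)
  ss_group <- 2 * sum(tapply(seq_len(N), g, function(i) length(i) * (mean(sm[i]) - grand)^2))
  ss_subj <- 2 * sum((sm - gm[as.character(g)])^2)
  ss_time <- N * sum((tm - grand)^2)
  ctm <- tapply(y, list(gg, time), mean)
  ss_int <- sum(outer(table(g), c(1, 1)) *
                  (ctm - outer(gm, c(1, 1)) -
                     matrix(tm, a, 2, byrow = TRUE) + grand)^2)
  ss_err_w <- sum((y - sm[subj] - ctm[cbind(as.character(gg), time)] +
                     gm[as.character(gg)])^2)
  list(
    F_group = (ss_group / (a - 1)) / (ss_subj / (N - a)),
    F_time = ss_time / (ss_err_w / (N - a)),
    F_int = (ss_int / (a - 1)) / (ss_err_w / (N - a))
  )
}

test_that("mixed RM-ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(44)
  for (rep in 1:5) {
    n_per <- 9
    g <- rep(c("patient", "control"), each = n_per)
    t1 <- rnorm(2 * n_per) + (g == "patient") * 0.8
    t2 <- t1 + rnorm(2 * n_per, sd = 0.7) + 0.3
    d <- tibble::tibble(group = g, t1 = t1, t2 = t2)
    fit <- rm_ancova(d, "t1", "t2", covariates = character(0))
    oracle <- mixed_anova_oracle(t1, t2, g)
    eff <- fit$effects
    expect_equal(eff$F[eff$effect == "group"], oracle$F_group, tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "time"], oracle$F_time, tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "group:time"], oracle$F_int, tolerance = 1e-8)
  }
})

test_that("RM-ANCOVA detects a planted group offset and nothing else", {
  set.seed(49)
  n_per <- 8
  g <- rep(c("a", "b"), each = n_per)
  base <- rep(seq(-1, 1, length.out = n_per), 2)
  delta <- (g == "b") * 50
  e1 <- rnorm(2 * n_per, sd = 0.05)
  e2 <- rnorm(2 * n_per, sd = 0.05)
  d <- tibble::tibble(group = g, age = rep(seq(30, 58, length.out = n_per), 2),
                      t1 = base + delta + e1, t2 = base + delta + e2)
  fit <- rm_ancova(d, "t1", "t2", covariates = "age")
  eff <- fit$effects
  expect_gt(eff$F[eff$effect == "group"], 1e3)
  expect_lt(eff$p[eff$effect == "group"], 1e-10)
  expect_gt(eff$p[eff$effect == "time"], 0.05)
  expect_gt(eff$p[eff$effect == "group:time"], 0.05)
  # error-df bookkeeping: n - 2 - k
  expect_identical(unique(eff$df_den), nrow(d) - 3L)
})

test_that("RM-ANCOVA F statistics are invariant to affine rescaling", {
  set.seed(45)
  d <- tibble::tibble(group = rep(c("a", "b"), each = 10),
                      age = rnorm(20, 45, 8),
                      t1 = rnorm(20), t2 = rnorm(20))
  f1 <- rm_ancova(d, "t1", "t2")$effects$F
  d2 <- dplyr::mutate(d, t1 = 7.3 * t1 - 11, t2 = 7.3 * t2 - 11)
  f2 <- rm_ancova(d2, "t1", "t2")$effects$F
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("RM-ANCOVA drops incomplete cases and validates the design", {
  d <- tibble::tibble(group = rep(c("a", "b"), each = 6),
                      age = rnorm(12, 45), t1 = rnorm(12), t2 = rnorm(12))
  d$t2[1] <- NA
  fit <- rm_ancova(d, "t1", "t2")
  expect_identical(fit$n, 11L)
  expect_identical(fit$n_dropped, 1L)
  d_small <- d[c(1:2, 7:12), ]
  expect_error(rm_ancova(d_small, "t1", "t2"), "at least 3 complete cases")
  d_one <- dplyr::mutate(d, group = "a")
  expect_error(rm_ancova(d_one, "t1", "t2"), "exactly 2 levels")
})

test_that("multivariate group test matches Wilks lambda from stats::manova", {
  set.seed(46)
  n <- 24
  Y <- matrix(rnorm(n * 5), n, 5)
  Y[1:12, 1] <- Y[1:12, 1] + 1.2
  g <- rep(c("patient", "control"), each = 12)
  covar <- rnorm(n, 45, 6)
  fit <- multivariate_group_test(Y, g, covar)
  ref <- summary(stats::manova(Y ~ covar + factor(g)), test = "Wilks")
  ref_row <- ref$stats["factor(g)", ]
  expect_equal(fit$lambda, unname(ref_row["Wilks"]), tolerance = 1e-8)
  expect_equal(fit$F, unname(ref_row["approx F"]), tolerance = 1e-8)
  expect_equal(fit$p, unname(ref_row["Pr(>F)"]), tolerance = 1e-8)
  # df bookkeeping: n = 24, 5 measures, 1 covariate -> F(5, 17)
  expect_identical(fit$df_num, 5L)
  expect_identical(fit$df_den, 17L)
})

test_that("multivariate test responds to separation as expected", {
  set.seed(47)
  n <- 30
  g <- rep(c("a", "b"), each = 15)
  # exactly identical group means: lambda ~ 1, F ~ 0
  Y0 <- matrix(rnorm(n * 3), n, 3)
  for (j in 1:3) Y0[, j] <- Y0[, j] - ave(Y0[, j], g)
  f0 <- multivariate_group_test(Y0, g)
  expect_equal(f0$lambda, 1, tolerance = 1e-10)
  expect_equal(f0$F, 0, tolerance = 1e-8)
  # one measure with huge separation: lambda near 0, large F
  Y1 <- Y0; Y1[, 2] <- Y1[, 2] + (g == "b") * 50
  f1 <- multivariate_group_test(Y1, g)
  expect_lt(f1$lambda, 0.01)
  expect_gt(f1$F, 100)
  expect_error(multivariate_group_test(Y1[c(1:2, 16:17), ], g[c(1:2, 16:17)]),
               "need n >")
})

test_that("tidiers return well-formed tibbles", {
  set.seed(48)
  pc <- partial_correlation(rnorm(15), rnorm(15), matrix(rnorm(15), 15, 1))
  td <- tidy(pc)
  expect_named(td, c("estimate", "statistic", "df", "p.value", "n", "covariates"))
  d <- tibble::tibble(group = rep(c("a", "b"), each = 8), age = rnorm(16, 45),
                      t1 = rnorm(16), t2 = rnorm(16))
  fit <- rm_ancova(d, "t1", "t2")
  expect_named(tidy(fit), c("term", "statistic", "df_num", "df_den", "p.value"))
  expect_identical(glance(fit)$n, 16L)
})
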