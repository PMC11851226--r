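#' Group-bound winsorization
#'
#' Values deviating more than 1.5 standard deviations from the group mean are
#' replaced by the boundary `mean +/- 1.5 * SD`. Bounds are computed ONCE from
#' the input (sample SD, n-1 denominator) and not iterated; order and length
#' are preserved. Apply per group, per variable, per timepoint.
#'
#' @param values numeric vector, n >= 3, finite.
#' @param n_sd boundary multiplier, default 1.5.
#' @return The winsorized vector, with attribute `n_replaced` giving the
#'   number of replaced values.
#' @export
winsorize_group <- function(values, n_sd = 1.5) {
  x <- as.numeric(values)
  if (length(x) < 3L) stop("winsorize_group needs n >= 3", call. = FALSE)
  if (any(!is.finite(x))) stop("winsorize_group requires finite values", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    warning("zero standard deviation; values returned unchanged", call. = FALSE)
    attr(x, "n_replaced") <- 0L
    return(x)
  }
  m <- mean(x)
  lo <- m - n_sd * s
  hi <- m + n_sd * s
  out <- pmin(pmax(x, lo), hi)
  attr(out, "n_replaced") <- sum(out != x)
  out
}

#' Pearson partial correlation with covariates
#'
#' Correlation between `x` and `y` after removing, by least squares, the
#' linear effect of the covariates (plus intercept) from each. With no
#' covariates this reduces to the plain Pearson correlation. The test is
#' two-sided: `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k`.
#'
#' @param x,y numeric vectors of equal length n.
#' @param covariates optional numeric matrix/data frame with n rows and k
#'   full-rank columns (e.g. age, tumor volume).
#' @return An object of class `lc_partial_cor`: list with `r`, `df`,
#'   `t_stat`, `p`, `n`, `covariate_names`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (is.null(covariates)) {
    cmat <- matrix(numeric(0), nrow = n, ncol = 0)
    cnames <- character(0)
  } else {
    cmat <- as.matrix(covariates)
    cnames <- colnames(cmat) %||% paste0("c", seq_len(ncol(cmat)))
    if (nrow(cmat) != n) stop("covariates must have n rows", call. = FALSE)
  }
  k <- ncol(cmat)
  if (any(!is.finite(c(x, y, cmat)))) stop("non-finite input to partial_correlation", call. = FALSE)
  if (n < k + 3L) stop("need n >= k + 3 observations", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, cmat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("covariate matrix is rank-deficient", call. = FALSE)
  rx <- qr.resid(qrX, x)
  ry <- qr.resid(qrX, y)
  if (stats::var(rx) <= 1e-12 * stats::var(x) || stats::var(ry) <= 1e-12 * stats::var(y)) {
    stop("a variable is fully explained by the covariates (zero residual variance)",
         call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  if (df < 1L) stop("df < 1 after covariate adjustment", call. = FALSE)
  if (abs(r) >= 1) {
    r <- sign(r) * 1
    t_stat <- sign(r) * Inf
    p <- .Machine$double.xmin
  } else {
    t_stat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df)
    p <- max(p, .Machine$double.xmin)
  }
  structure(
    list(r = r, df = df, t_stat = t_stat, p = p, n = n, covariate_names = cnames),
    class = "lc_partial_cor"
  )
}

#' @export
print.lc_partial_cor <- function(x, ...) {
  cat(sprintf("Partial correlation r = %.4f, t(%d) = %.3f, p = %.4g", x$r, x$df,
              x$t_stat, x$p))
  if (length(x$covariate_names)) {
    cat(" | controlling:", paste(x$covariate_names, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Bonferroni-adjust p-values
#'
#' `p_i -> min(1, p_i * m)`. The family size `m` defaults to the number of
#' p-values but may be set explicitly when the family is larger than the
#' vector at hand.
#'
#' @param p numeric vector of p-values.
#' @param m family size.
#' @return Adjusted p-values, same length as `p`.
#' @export
adjust_p <- function(p, m = length(p)) {
  stopifnot(m >= length(p))
  stats::p.adjust(p, method = "bonferroni", n = m)
}

rm_effect <- function(name, ss_effect, df_num, ss_err, df_den) {
  ms_e <- ss_effect / df_num
  ms_err <- ss_err / df_den
  F_val <- if (ms_err > 0) ms_e / ms_err else Inf
  p <- if (is.finite(F_val)) stats::pf(F_val, df_num, df_den, lower.tail = FALSE) else .Machine$double.xmin
  tibble::tibble(effect = name, F = F_val, df_num = df_num, df_den = df_den,
                 p = max(p, .Machine$double.xmin))
}

drop_ss <- function(qr_full, y, X_full, drop_cols) {
  rss_full <- sum(qr.resid(qr_full, y)^2)
  X_red <- X_full[, -drop_cols, drop = FALSE]
  rss_red <- if (ncol(X_red)) sum(qr.resid(qr(X_red), y)^2) else sum(y^2)
  rss_red - rss_full
}

#' Mixed repeated-measures ANCOVA (2 groups x 2 timepoints)
#'
#' Mixed between (group) x within (timepoint) design with optional
#' between-subject covariates, in the classical split: the between-subject
#' (group) effect is tested on subject means, the within-subject effects
#' (time, group x time) on the timepoint difference, both in least-squares
#' models with the centered covariates and an effect-coded group term.
#' Sums of squares are full-vs-reduced model comparisons (Type III-like),
#' so the tests match the standard mixed RM-ANCOVA layout: with k covariates
#' both error terms carry `n - 2 - k` degrees of freedom. Complete cases
#' only; incomplete subjects are dropped and counted.
#'
#' @param data data frame, one row per subject.
#' @param value_initial,value_followup names of the two timepoint columns.
#' @param group name of the two-level group column.
#' @param covariates character vector of covariate column names (may be
#'   empty for a plain mixed ANOVA).
#' @return An object of class `lc_rm_ancova`: list with `effects` (tibble
#'   with effect, F, df_num, df_den, p), `n`, `n_dropped`, `groups`.
#' @export
rm_ancova <- function(data, value_initial, value_followup, group = "group",
                      covariates = "age") {
  df <- tibble::as_tibble(data)
  need <- c(value_initial, value_followup, group, covariates)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  used <- stats::complete.cases(df[need])
  n_dropped <- sum(!used)
  df <- df[used, , drop = FALSE]
  g <- factor(df[[group]])
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  if (any(table(g) < 3L)) stop("each group needs at least 3 complete cases", call. = FALSE)
  n <- nrow(df)
  k <- length(covariates)
  t1 <- as.numeric(df[[value_initial]])
  t2 <- as.numeric(df[[value_followup]])
  subj_mean <- (t1 + t2) / 2
  d <- t2 - t1
  g_eff <- ifelse(g == levels(g)[1L], -1, 1)
  C <- if (k) scale(as.matrix(df[covariates]), center = TRUE, scale = FALSE) else
    matrix(numeric(0), n, 0)

  # between-subject part: subject means ~ 1 + covariates + group
  Xb <- cbind(Intercept = 1, C, group = g_eff)
  qb <- qr(Xb)
  if (qb$rank < ncol(Xb)) stop("between-subject design is rank-deficient", call. = FALSE)
  df_err <- n - 2L - k
  ss_err_b <- sum(qr.resid(qb, subj_mean)^2)
  eff_group <- rm_effect("group", drop_ss(qb, subj_mean, Xb, ncol(Xb)), 1L,
                         ss_err_b, df_err)

  # within-subject part: difference scores ~ 1 + covariates + group
  Xw <- cbind(Intercept = 1, C, group = g_eff)
  qw <- qr(Xw)
  ss_err_w <- sum(qr.resid(qw, d)^2)
  eff_time <- rm_effect("time", drop_ss(qw, d, Xw, 1L), 1L, ss_err_w, df_err)
  eff_int <- rm_effect("group:time", drop_ss(qw, d, Xw, ncol(Xw)), 1L,
                       ss_err_w, df_err)

  structure(
    list(effects = dplyr::bind_rows(eff_group, eff_time, eff_int),
         n = n, n_dropped = n_dropped, groups = levels(g),
         covariates = covariates),
    class = "lc_rm_ancova"
  )
}

#' @export
print.lc_rm_ancova <- function(x, ...) {
  cat("Mixed RM-ANCOVA (n = ", x$n, ", groups: ",
      paste(x$groups, collapse = " vs "), ")\n", sep = "")
  print(x$effects)
  invisible(x)
}

#' Multivariate group test (Wilks' lambda) with covariate adjustment
#'
#' Tests the group effect jointly across several outcome measures while
#' adjusting for covariates: Wilks' lambda from the full-vs-reduced residual
#' cross-product matrices, converted to the exact F available in the
#' two-group case, with `df_num = p` (number of measures) and
#' `df_den = n - k - p - 1`.
#'
#' @param measures n x p numeric matrix of outcomes.
#' @param group two-level factor of length n.
#' @param covariates optional n x k matrix.
#' @return An object of class `lc_manova`: list with `lambda`, `F`,
#'   `df_num`, `df_den`, `p`, `n`.
#' @export
multivariate_group_test <- function(measures, group, covariates = NULL) {
  Y <- as.matrix(measures)
  n <- nrow(Y)
  p <- ncol(Y)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly 2 groups required for the exact-F form", call. = FALSE)
  C <- if (is.null(covariates)) matrix(numeric(0), n, 0) else as.matrix(covariates)
  k <- ncol(C)
  if (n <= p + k + 1L) stop("need n > measures + covariates + 1 subjects", call. = FALSE)
  if (any(!is.finite(Y)) || any(!is.finite(C))) stop("non-finite input", call. = FALSE)
  g_eff <- ifelse(g == levels(g)[1L], -1, 1)
  X_full <- cbind(1, C, g_eff)
  X_red <- cbind(1, C)
  E <- crossprod(qr.resid(qr(X_full), Y))
  ER <- crossprod(qr.resid(qr(X_red), Y))
  H <- ER - E
  detE <- det(E)
  if (!is.finite(detE) || detE <= 0) {
    stop("singular within-group covariance; reduce the number of measures", call. = FALSE)
  }
  lambda <- detE / det(E + H)
  df_num <- p
  df_den <- n - k - p - 1L
  F_val <- ((1 - lambda) / lambda) * (df_den / df_num)
  p_val <- stats::pf(F_val, df_num, df_den, lower.tail = FALSE)
  structure(
    list(lambda = lambda, F = F_val, df_num = df_num, df_den = df_den,
         p = max(p_val, .Machine$double.xmin), n = n),
    class = "lc_manova"
  )
}

#' @export
print.lc_manova <- function(x, ...) {
  cat(sprintf("Wilks' lambda = %.4f, F(%d,%d) = %.3f, p = %.4g\n",
              x$lambda, x$df_num, x$df_den, x$F, x$p))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
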