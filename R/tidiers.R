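#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a partial-correlation result
#'
#' @param x an `lc_partial_cor`.
#' @param ... unused.
#' @return One-row tibble: estimate, statistic, df, p.value, n, covariates.
#' @export
tidy.lc_partial_cor <- function(x, ...) {
  tibble::tibble(
    estimate = x$r, statistic = x$t_stat, df = x$df, p.value = x$p, n = x$n,
    covariates = paste(x$covariate_names, collapse = "+")
  )
}

#' Tidy a mixed RM-ANCOVA
#'
#' @param x an `lc_rm_ancova`.
#' @param ... unused.
#' @return Tibble with one row per effect: term, statistic, df_num, df_den,
#'   p.value.
#' @export
tidy.lc_rm_ancova <- function(x, ...) {
  dplyr::rename(x$effects, term = "effect", statistic = "F", p.value = "p")
}

#' @rdname tidy.lc_rm_ancova
#' @export
glance.lc_rm_ancova <- function(x, ...) {
  tibble::tibble(n = x$n, n_dropped = x$n_dropped,
                 groups = paste(x$groups, collapse = "/"),
                 covariates = paste(x$covariates, collapse = "+"))
}

#' Tidy a multivariate group test
#'
#' @param x an `lc_manova`.
#' @param ... unused.
#' @return One-row tibble: term, wilks, statistic, df_num, df_den, p.value, n.
#' @export
tidy.lc_manova <- function(x, ...) {
  tibble::tibble(term = "group", wilks = x$lambda, statistic = x$F,
                 df_num = x$df_num, df_den = x$df_den, p.value = x$p, n = x$n)
}

#' Tidy a connectivity matrix into a long edge table
#'
#' @param x an `lc_fc`.
#' @param ... unused.
#' @return Tibble with one row per unordered node pair: node_a, node_b, z.
#' @export
tidy.lc_fc <- function(x, ...) {
  ut <- upper.tri(x$z)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    node_a = x$node_ids[idx[, 1L]],
    node_b = x$node_ids[idx[, 2L]],
    z = x$z[ut]
  )
}
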