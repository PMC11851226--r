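#' Fisher-z functional connectivity matrix
#'
#' Cross-correlates all node time series pairwise (Pearson, over frames),
#' clips r to `[-clip, clip]` to keep the transform finite for degenerate
#' pairs, and applies the Fisher z-transform `z = atanh(r)` elementwise.
#' The diagonal is set to `NA` — self-connectivity is undefined and never
#' enters any summary.
#'
#' @param ts an `lc_timeseries` with T >= 3 frames.
#' @param clip magnitude at which r is clipped, default `1 - 1e-7`
#'   (z at the clip is about 8.38).
#' @return An object of class `lc_fc`: list with `z` (symmetric N x N
#'   matrix), `node_ids`, `has_tumor_node`.
#' @export
fc_matrix <- function(ts, clip = 1 - 1e-7) {
  stopifnot(inherits(ts, "lc_timeseries"))
  x <- ts$series
  if (nrow(x) < 3L) stop("need at least 3 frames to correlate", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in time series", call. = FALSE)
  v <- apply(x, 2L, stats::var)
  if (any(v <= 0)) {
    bad <- ts$node_ids[v <= 0]
    stop("zero-variance node(s): ", paste(bad, collapse = ", "),
         " (pre-filter with extract_roi_timeseries)", call. = FALSE)
  }
  r <- stats::cor(x)
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- NA_real_
  dimnames(z) <- list(as.character(ts$node_ids), as.character(ts$node_ids))
  structure(
    list(z = z, node_ids = ts$node_ids,
         has_tumor_node = any(ts$node_ids == TUMOR_NODE)),
    class = "lc_fc"
  )
}

#' @export
print.lc_fc <- function(x, ...) {
  cat("<lc_fc> ", nrow(x$z), " x ", ncol(x$z), " Fisher-z matrix",
      if (x$has_tumor_node) " (tumor node present)", "\n", sep = "")
  invisible(x)
}

atlas_index <- function(m) which(m$node_ids != TUMOR_NODE)

#' Tumor-to-extralesional connectivity (Tu-EL)
#'
#' Mean Fisher-z value between the tumor node and every retained atlas node.
#' Signed values enter as-is: anticorrelation lowers the summary.
#'
#' @param m an `lc_fc` with a tumor node.
#' @return Scalar Tu-EL value.
#' @export
summary_tu_el <- function(m) {
  stopifnot(inherits(m, "lc_fc"))
  if (!m$has_tumor_node) stop("matrix has no tumor node; Tu-EL is undefined", call. = FALSE)
  ti <- which(m$node_ids == TUMOR_NODE)
  mean(m$z[ti, atlas_index(m)])
}

#' Extralesional connectivity (EL)
#'
#' Mean Fisher-z value over all unordered pairs of retained atlas nodes
#' (upper triangle; the tumor row/column, if present, is excluded).
#'
#' @param m an `lc_fc` with at least 2 atlas nodes.
#' @return Scalar EL value.
#' @export
summary_el <- function(m) {
  stopifnot(inherits(m, "lc_fc"))
  ai <- atlas_index(m)
  if (length(ai) < 2L) stop("need at least 2 atlas nodes for EL", call. = FALSE)
  sub <- m$z[ai, ai, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Contralesional-hemisphere connectivity (conEL)
#'
#' Mean Fisher-z value over unordered node pairs lying entirely within the
#' hemisphere opposite the lesion. Cross-hemispheric pairs and the tumor node
#' are excluded, mirroring the within-hemisphere construction used for the
#' controls' baseline.
#'
#' @param m an `lc_fc`.
#' @param roi_table ROI lookup (columns `roi_id`, `hemisphere`).
#' @param lesion_side `"left"` or `"right"`.
#' @return Scalar conEL value.
#' @export
summary_conel <- function(m, roi_table, lesion_side = c("left", "right")) {
  lesion_side <- match.arg(lesion_side)
  contra <- if (lesion_side == "left") "right" else "left"
  hemi_pair_mean(m, roi_table, contra)
}

hemi_pair_mean <- function(m, roi_table, hemisphere) {
  stopifnot(inherits(m, "lc_fc"))
  roi_table <- validate_roi_table(roi_table)
  ids <- roi_table$roi_id[roi_table$hemisphere == hemisphere]
  idx <- which(m$node_ids %in% ids)
  if (length(idx) < 2L) {
    stop("fewer than 2 retained nodes in the ", hemisphere, " hemisphere", call. = FALSE)
  }
  sub <- m$z[idx, idx, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Controls' hemispheric connectivity baseline
#'
#' Controls have no lesion side, so their "contralesional" value is the mean
#' of the within-left and within-right pairwise connectivity means.
#'
#' @param m a control `lc_fc` (no tumor node).
#' @param roi_table ROI lookup (columns `roi_id`, `hemisphere`).
#' @return Scalar baseline value.
#' @export
control_hemispheric_baseline <- function(m, roi_table) {
  stopifnot(inherits(m, "lc_fc"))
  if (m$has_tumor_node) stop("hemispheric baseline is defined for control matrices only", call. = FALSE)
  (hemi_pair_mean(m, roi_table, "left") + hemi_pair_mean(m, roi_table, "right")) / 2
}

#' Scalar connectivity summaries for one subject/timepoint
#'
#' Convenience wrapper returning a one-row tibble with `tu_el` (patients with
#' a tumor node only), `el`, and `con_el` (within-contralesional mean for
#' patients, hemispheric baseline for controls).
#'
#' @param m an `lc_fc`.
#' @param roi_table ROI lookup table.
#' @param lesion_side `"left"`, `"right"` or `"none"` (control).
#' @param subject_id,timepoint identifiers carried through to the output.
#' @return One-row tibble: subject_id, timepoint, tu_el, el, con_el.
#' @export
fc_summaries <- function(m, roi_table, lesion_side, subject_id = NA_character_,
                         timepoint = NA_character_) {
  tu <- if (m$has_tumor_node) summary_tu_el(m) else NA_real_
  el <- summary_el(m)
  ce <- if (identical(lesion_side, "none")) {
    control_hemispheric_baseline(m, roi_table)
  } else {
    summary_conel(m, roi_table, lesion_side)
  }
  tibble::tibble(subject_id = subject_id, timepoint = timepoint,
                 tu_el = tu, el = el, con_el = ce)
}
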