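#' Lesion mask
#'
#' Binary volume marking tumor tissue (preoperative), the resection cavity
#' (postoperative) or their voxelwise union (`combined`). Lesion masks drive
#' both voxel masking of the BOLD series and atlas-ROI exclusion.
#'
#' @param mask an `lc_volume` of kind `"binary"` (3D).
#' @param kind `"tumor"`, `"resection"` or `"combined"`.
#' @param side hemisphere carrying the lesion, `"left"` or `"right"`.
#' @return An object of class `lc_lesion`.
#' @export
new_lesion_mask <- function(mask, kind = c("tumor", "resection", "combined"),
                            side = c("left", "right")) {
  kind <- match.arg(kind)
  side <- match.arg(side)
  stopifnot(inherits(mask, "lc_volume"))
  if (mask$kind != "binary") stop("lesion mask must be a binary volume", call. = FALSE)
  if (length(dim(mask$data)) != 3L) stop("lesion mask must be 3D", call. = FALSE)
  if (kind == "tumor" && sum(mask$data) == 0) {
    stop("tumor mask has no nonzero voxel", call. = FALSE)
  }
  structure(list(mask = mask, kind = kind, side = side), class = "lc_lesion")
}

#' @export
print.lc_lesion <- function(x, ...) {
  cat("<lc_lesion> ", x$kind, " (", x$side, "), ",
      sum(x$mask$data), " voxels\n", sep = "")
  invisible(x)
}

#' Number of voxels in a lesion mask
#' @param lesion an `lc_lesion`.
#' @return Integer voxel count.
#' @export
lesion_size <- function(lesion) {
  stopifnot(inherits(lesion, "lc_lesion"))
  as.integer(sum(lesion$mask$data))
}

#' Combine tumor and resection masks
#'
#' Voxelwise logical OR of the pre- and postoperative lesions. The combined
#' mask is what keeps extralesional brain volume constant within a subject
#' across timepoints: it is applied to the BOLD data and drives ROI exclusion
#' at both assessments.
#'
#' @param tumor,resection `lc_lesion` objects on the same grid and side.
#' @return An `lc_lesion` of kind `"combined"`.
#' @export
combine_lesion_masks <- function(tumor, resection) {
  stopifnot(inherits(tumor, "lc_lesion"), inherits(resection, "lc_lesion"))
  if (tumor$side != resection$side) {
    stop("tumor and resection masks are on different sides (",
         tumor$side, " vs ", resection$side, ")", call. = FALSE)
  }
  check_grid_compatibility(list(tumor$mask, resection$mask))
  u <- (tumor$mask$data + resection$mask$data) > 0
  vol <- new_volume(array(as.numeric(u), dim = dim(tumor$mask$data)),
                    voxel_size = tumor$mask$voxel_size,
                    affine = tumor$mask$affine, kind = "binary")
  new_lesion_mask(vol, kind = "combined", side = tumor$side)
}

#' Atlas ROIs overlapped by a lesion
#'
#' Returns every `roi_id` whose intersection with the lesion holds at least
#' `min_overlap_voxels` voxels. With the default of 1 a single shared voxel
#' excludes the parcel — the strictest reading of "covers tumor tissue".
#'
#' @param atlas an `lc_atlas`.
#' @param lesion an `lc_lesion` on the same grid.
#' @param min_overlap_voxels exclusion threshold, default 1.
#' @return Sorted integer vector of excluded roi_ids (possibly empty).
#' @export
lesioned_roi_ids <- function(atlas, lesion, min_overlap_voxels = 1L) {
  stopifnot(inherits(atlas, "lc_atlas"), inherits(lesion, "lc_lesion"))
  check_grid_compatibility(list(atlas$labels, lesion$mask))
  stopifnot(min_overlap_voxels >= 1L)
  lab <- as.integer(atlas$labels$data)
  inside <- lab[lesion$mask$data > 0]
  inside <- inside[inside != 0L]
  if (!length(inside)) return(integer(0))
  counts <- table(inside)
  ids <- as.integer(names(counts)[counts >= min_overlap_voxels])
  sort(ids)
}

#' Mask lesioned voxels out of a BOLD series
#'
#' Sets every voxel inside the lesion to `NA` (the excluded sentinel) at every
#' frame; all other voxels are untouched. Downstream ROI means skip sentinel
#' voxels.
#'
#' @param bold a 4D `lc_volume`.
#' @param lesion an `lc_lesion` on the same grid.
#' @return A 4D `lc_volume` with lesioned voxels set to `NA`.
#' @export
apply_lesion_mask <- function(bold, lesion) {
  stopifnot(inherits(bold, "lc_volume"), inherits(lesion, "lc_lesion"))
  if (length(dim(bold$data)) != 4L) stop("bold must be 4D", call. = FALSE)
  check_grid_compatibility(list(bold, lesion$mask))
  out <- bold$data
  idx <- which(lesion$mask$data > 0)
  if (length(idx)) {
    nvox <- prod(dim(out)[1:3])
    frames <- seq_len(dim(out)[4L]) - 1L
    out[as.vector(outer(idx, frames * nvox, `+`))] <- NA_real_
  }
  new_volume(out, voxel_size = bold$voxel_size, affine = bold$affine, kind = "float")
}

#' Tumor volume in cubic centimetres
#'
#' @param tumor an `lc_lesion`.
#' @return Voxel count times voxel volume, converted from mm^3 to cm^3.
#' @export
tumor_volume_cm3 <- function(tumor) {
  stopifnot(inherits(tumor, "lc_lesion"))
  lesion_size(tumor) * prod(tumor$mask$voxel_size) / 1000
}

#' Sentinel node id for the tumor column
#' @export
TUMOR_NODE <- -1L

#' Extract mean ROI time series
#'
#' For every retained atlas ROI the column is the arithmetic mean over its
#' non-sentinel voxels per frame. When a tumor mask is supplied, one extra
#' column holding the mean over tumor voxels of the *unmasked* BOLD is
#' appended last (masking first would delete the tumor's own signal). Node
#' order is ascending `roi_id`, then the tumor sentinel [TUMOR_NODE].
#' Retained ROIs left with zero usable voxels, or with essentially zero
#' temporal variance, are dropped with a warning and moved to `excluded_ids`.
#'
#' @param bold a 4D `lc_volume`, typically already lesion-masked via
#'   [apply_lesion_mask()].
#' @param atlas an `lc_atlas` on the same grid.
#' @param excluded integer roi_ids to exclude (from [lesioned_roi_ids()]).
#' @param tumor optional `lc_lesion` whose mean series becomes the tumor node;
#'   if given, `tumor_bold` supplies the unmasked data (defaults to `bold`).
#' @param tumor_bold 4D `lc_volume` to read the tumor signal from.
#' @param var_tol variance threshold below which a node is considered
#'   degenerate (default 1e-12).
#' @return An object of class `lc_timeseries`: list with `series` (T x N
#'   matrix), `node_ids`, `excluded_ids`, `tr_s` attribute slot.
#' @export
extract_roi_timeseries <- function(bold, atlas, excluded = integer(0),
                                   tumor = NULL, tumor_bold = bold,
                                   var_tol = 1e-12) {
  stopifnot(inherits(bold, "lc_volume"), inherits(atlas, "lc_atlas"))
  if (length(dim(bold$data)) != 4L) stop("bold must be 4D", call. = FALSE)
  check_grid_compatibility(list(bold, atlas$labels))
  excluded <- sort(unique(as.integer(excluded)))
  unknown <- setdiff(excluded, atlas$roi_table$roi_id)
  if (length(unknown)) {
    stop("excluded ids not in atlas: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  d <- dim(bold$data)
  T_len <- d[4L]
  nvox <- prod(d[1:3])
  flat <- matrix(bold$data, nrow = nvox, ncol = T_len)
  lab <- as.integer(atlas$labels$data)

  retained <- sort(setdiff(atlas$roi_table$roi_id, excluded))
  cols <- list()
  keep_ids <- integer(0)
  dropped <- integer(0)
  for (id in retained) {
    vox <- which(lab == id)
    sub <- flat[vox, , drop = FALSE]
    usable <- stats::complete.cases(sub)
    if (!any(usable)) {
      dropped <- c(dropped, id)
      next
    }
    m <- colMeans(sub[usable, , drop = FALSE])
    if (stats::var(m) < var_tol) {
      dropped <- c(dropped, id)
      next
    }
    keep_ids <- c(keep_ids, id)
    cols[[length(cols) + 1L]] <- m
  }
  if (length(dropped)) {
    warning("dropped ", length(dropped), " ROI(s) with no usable voxels or ",
            "zero variance: ", paste(utils::head(dropped, 8L), collapse = ", "),
            call. = FALSE)
  }
  node_ids <- keep_ids
  if (!is.null(tumor)) {
    stopifnot(inherits(tumor, "lc_lesion"))
    check_grid_compatibility(list(tumor_bold, tumor$mask))
    vox <- which(tumor$mask$data > 0)
    if (!length(vox)) stop("tumor mask has zero voxels", call. = FALSE)
    tflat <- matrix(tumor_bold$data, nrow = nvox, ncol = T_len)
    m <- colMeans(tflat[vox, , drop = FALSE])
    if (stats::var(m) < var_tol) stop("tumor time series has zero variance", call. = FALSE)
    cols[[length(cols) + 1L]] <- m
    node_ids <- c(node_ids, TUMOR_NODE)
  }
  series <- do.call(cbind, cols)
  colnames(series) <- as.character(node_ids)
  structure(
    list(series = series, node_ids = node_ids,
         excluded_ids = sort(c(excluded, dropped))),
    class = "lc_timeseries"
  )
}

#' @export
print.lc_timeseries <- function(x, ...) {
  cat("<lc_timeseries> ", nrow(x$series), " frames x ", ncol(x$series),
      " nodes (", sum(x$node_ids == TUMOR_NODE), " tumor node, ",
      length(x$excluded_ids), " excluded)\n", sep = "")
  invisible(x)
}

#' Build an lc_timeseries directly from a matrix
#'
#' Convenience constructor for simulated or precomputed data.
#'
#' @param series T x N numeric matrix.
#' @param node_ids integer node ids, [TUMOR_NODE] allowed once, last.
#' @param excluded_ids roi_ids removed upstream.
#' @return An `lc_timeseries`.
#' @export
as_timeseries <- function(series, node_ids, excluded_ids = integer(0)) {
  series <- as.matrix(series)
  node_ids <- as.integer(node_ids)
  if (ncol(series) != length(node_ids)) stop("node_ids length must match columns", call. = FALSE)
  if (anyDuplicated(node_ids)) stop("duplicate node ids", call. = FALSE)
  if (any(node_ids %in% excluded_ids)) stop("excluded id present among nodes", call. = FALSE)
  colnames(series) <- as.character(node_ids)
  structure(list(series = series, node_ids = node_ids,
                 excluded_ids = sort(as.integer(excluded_ids))),
            class = "lc_timeseries")
}

#' High-pass filter ROI time series
#'
#' Removes the column means and applies a zero-phase (forward-backward)
#' Butterworth high-pass at `cutoff_hz`: slow scanner drifts below the
#' cutoff are strongly attenuated while resting-state fluctuations above it
#' pass essentially unchanged. Output length equals input length.
#'
#' @param ts an `lc_timeseries`.
#' @param cutoff_hz high-pass cutoff in Hz, default 0.01.
#' @param tr_s repetition time in seconds (frame spacing), e.g. 2.2.
#' @param order Butterworth order of each pass (default 2; the
#'   forward-backward application doubles the effective roll-off).
#' @return A filtered `lc_timeseries`.
#' @export
highpass_filter <- function(ts, cutoff_hz = 0.01, tr_s, order = 2L) {
  stopifnot(inherits(ts, "lc_timeseries"), tr_s > 0)
  nyquist <- 1 / (2 * tr_s)
  if (cutoff_hz >= nyquist) {
    stop("cutoff ", cutoff_hz, " Hz is at/above Nyquist (", signif(nyquist, 4), " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "high")
  filt <- apply(ts$series, 2L, function(col) {
    signal::filtfilt(bf, col - mean(col))
  })
  as_timeseries(filt, ts$node_ids, ts$excluded_ids)
}
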