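#' Volumetric image container
#'
#' A `lc_volume` is a thin S3 wrapper around a 3D or 4D numeric array with the
#' grid metadata the pipeline needs: per-axis voxel size in mm, the
#' voxel-to-world affine, and a `kind` tag describing the payload
#' (`"float"` for BOLD, `"label"` for an atlas, `"binary"` for a mask).
#' Voxel indexing is 0-based in all user-facing coordinates; no resampling is
#' ever performed — every volume belonging to one subject must share a grid.
#'
#' @param data numeric array, 3D (x, y, z) or 4D (x, y, z, t with t >= 2).
#' @param voxel_size numeric length-3, mm per spatial axis.
#' @param affine 4x4 voxel-to-world matrix; defaults to a scaling affine built
#'   from `voxel_size`.
#' @param kind one of `"float"`, `"label"`, `"binary"`.
#'
#' @return An object of class `lc_volume`.
#' @export
new_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                       kind = c("float", "label", "binary")) {
  kind <- match.arg(kind)
  data <- unclass(data)
  nd <- length(dim(data))
  if (is.null(dim(data)) || !nd %in% c(3L, 4L)) {
    stop("volume data must be a 3D or 4D array, got ",
         if (is.null(dim(data))) "a vector" else paste0(nd, "D"),
         call. = FALSE)
  }
  if (any(dim(data)[1:3] < 1L)) stop("all spatial axes must have length >= 1", call. = FALSE)
  if (nd == 4L && dim(data)[4L] < 2L) stop("4D volumes need T >= 2 frames", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be 3 positive mm values", call. = FALSE)
  }
  if (kind == "binary") {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1))) stop("binary volume contains values outside {0, 1}", call. = FALSE)
  }
  if (kind == "label") {
    v <- as.vector(data)
    if (any(v < 0) || any(v != round(v))) {
      stop("label volume must contain non-negative integers", call. = FALSE)
    }
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  structure(
    list(data = data, voxel_size = voxel_size, affine = affine, kind = kind),
    class = "lc_volume"
  )
}

#' @export
print.lc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<lc_volume> ", x$kind, " ", paste(d, collapse = " x "),
      " @ ", paste(signif(x$voxel_size, 4), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.lc_volume <- function(x) dim(x$data)

#' Number of time frames of a volume
#'
#' @param vol a [new_volume()] object.
#' @return Integer count of frames (1 for 3D volumes).
#' @export
n_frames <- function(vol) {
  stopifnot(inherits(vol, "lc_volume"))
  d <- dim(vol$data)
  if (length(d) == 4L) d[4L] else 1L
}

#' Read a NIfTI volume from disk
#'
#' Wraps [RNifti::readNifti()] and attaches the grid metadata used throughout
#' the pipeline. Values are passed through untouched.
#'
#' @param path path to a NIfTI-1/NIfTI-2 file (`.nii` or `.nii.gz`).
#' @param kind payload tag; `"binary"` and `"label"` trigger value validation.
#' @return An `lc_volume`.
#' @export
load_volume <- function(path, kind = c("float", "label", "binary")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read volume '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  nd <- length(dim(img))
  if (!nd %in% c(3L, 4L)) {
    stop("'", path, "' is ", nd, "D; only 3D/4D images are supported", call. = FALSE)
  }
  vs <- RNifti::pixdim(img)[1:3]
  aff <- structure(RNifti::xform(img), class = NULL)
  new_volume(array(as.numeric(img), dim = dim(img)),
             voxel_size = vs, affine = aff, kind = kind)
}

#' Write a volume to a NIfTI file
#'
#' @param vol an `lc_volume`.
#' @param path destination (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "lc_volume"))
  datatype <- if (vol$kind == "float") "double" else "int32"
  arr <- vol$data
  attr(arr, "pixdim") <- c(vol$voxel_size, rep(1, length(dim(arr)) - 3L))
  attr(arr, "pixunits") <- c("mm", "s")
  img <- RNifti::asNifti(arr, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that volumes share one voxel grid
#'
#' All inputs of one subject (BOLD, atlas, masks) must live on the same grid:
#' equal spatial dimensions and voxel sizes within `tol_mm`. Returns silently
#' on success and raises a descriptive error otherwise.
#'
#' @param volumes list of `lc_volume` objects.
#' @param tol_mm voxel-size tolerance in mm (default 1e-3).
#' @return Invisibly `TRUE`.
#' @export
check_grid_compatibility <- function(volumes, tol_mm = 1e-3) {
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  ref <- volumes[[1L]]
  ref_shape <- dim(ref$data)[1:3]
  for (i in seq_along(volumes)) {
    v <- volumes[[i]]
    if (!inherits(v, "lc_volume")) stop("element ", i, " is not an lc_volume", call. = FALSE)
    shape <- dim(v$data)[1:3]
    if (!identical(as.integer(shape), as.integer(ref_shape))) {
      stop("grid mismatch: volume 1 is ", paste(ref_shape, collapse = "x"),
           " but volume ", i, " is ", paste(shape, collapse = "x"), call. = FALSE)
    }
    if (any(abs(v$voxel_size - ref$voxel_size) > tol_mm)) {
      stop("voxel-size mismatch beyond ", tol_mm, " mm: ",
           paste(signif(ref$voxel_size, 7), collapse = "x"), " vs ",
           paste(signif(v$voxel_size, 7), collapse = "x"), call. = FALSE)
    }
  }
  invisible(TRUE)
}
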