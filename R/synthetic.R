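#' Configuration for the synthetic-cohort generator
#'
#' The generator emulates the measured structure of a lesion-aware
#' resting-state study: equicorrelated extralesional parcel signals (one
#' common latent factor), a contiguous tumor region whose BOLD signal shares
#' a tunable fraction of the latent factor, and behavioral scores with a
#' planted linear dependence on the true tumor coupling. Everything is
#' deterministic given `seed`.
#'
#' @param n_rois number of atlas parcels (even; canonical 246).
#' @param grid_shape 3D voxel grid; left hemisphere is `x <= nx/2`.
#' @param n_frames BOLD frames per run (default 300).
#' @param tr_s repetition time in seconds (default 2.2).
#' @param voxel_size_mm voxel edge lengths in mm; the default coarse 8 mm
#'   grid keeps synthetic tumor volumes in the tens-of-cm^3 range typical of
#'   gliomas.
#' @param base_within_corr expected pairwise Pearson r among parcel signals.
#' @param rho_tumor_range per-patient tumor coupling rho drawn uniformly from
#'   this interval (set both ends equal for a fixed rho).
#' @param voxel_noise_sd i.i.d. noise added to each voxel on top of its
#'   parcel signal.
#' @param lesion_side hemisphere carrying every synthetic tumor.
#' @param n_lesioned_rois number k of parcels the tumor mask overlaps.
#' @param resection_dilation_vox voxels of 6-neighborhood dilation applied to
#'   the tumor mask to form the resection mask.
#' @param alertness_intercept,behavior_slope,behavior_noise_sd,age_coef
#'   alertness quotient model: `intercept + slope * z_true + age_coef * age
#'   + N(0, noise_sd)`; higher is worse.
#' @param age_range subject ages drawn uniformly from this interval (years).
#' @param n_patients,n_controls group sizes (default 18 + 18).
#' @param seed mandatory integer seed; there is no implicit randomness.
#' @return A validated list of class `lc_sim_config`.
#' @export
synthetic_config <- function(n_rois = 246L,
                             grid_shape = c(14L, 12L, 6L),
                             n_frames = 300L,
                             tr_s = 2.2,
                             voxel_size_mm = c(8, 8, 8),
                             base_within_corr = 0.3,
                             rho_tumor_range = c(0.2, 0.8),
                             voxel_noise_sd = 0.5,
                             lesion_side = "left",
                             n_lesioned_rois = 12L,
                             resection_dilation_vox = 1L,
                             alertness_intercept = 400,
                             behavior_slope = 300,
                             behavior_noise_sd = 20,
                             age_coef = 1,
                             age_range = c(30, 60),
                             n_patients = 18L,
                             n_controls = 18L,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  cfg <- list(
    n_rois = as.integer(n_rois), grid_shape = as.integer(grid_shape),
    n_frames = as.integer(n_frames), tr_s = tr_s,
    voxel_size_mm = as.numeric(voxel_size_mm),
    base_within_corr = base_within_corr,
    rho_tumor_range = sort(as.numeric(rho_tumor_range)),
    voxel_noise_sd = voxel_noise_sd,
    lesion_side = match.arg(lesion_side, c("left", "right")),
    n_lesioned_rois = as.integer(n_lesioned_rois),
    resection_dilation_vox = as.integer(resection_dilation_vox),
    alertness_intercept = alertness_intercept,
    behavior_slope = behavior_slope,
    behavior_noise_sd = behavior_noise_sd,
    age_coef = age_coef, age_range = as.numeric(age_range),
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    seed = as.integer(seed)
  )
  stopifnot(cfg$n_rois >= 2L, cfg$n_rois %% 2L == 0L,
            length(cfg$grid_shape) == 3L, all(cfg$grid_shape >= 1L),
            cfg$n_frames >= 4L, cfg$tr_s > 0,
            cfg$base_within_corr > 0, cfg$base_within_corr < 1,
            all(cfg$rho_tumor_range >= 0), all(cfg$rho_tumor_range < 1),
            cfg$voxel_noise_sd > 0, cfg$behavior_noise_sd > 0,
            cfg$n_lesioned_rois >= 1L,
            cfg$n_lesioned_rois < cfg$n_rois / 2,
            cfg$n_patients >= 0L, cfg$n_controls >= 0L)
  half_vox <- floor(cfg$grid_shape[1L] / 2) * cfg$grid_shape[2L] * cfg$grid_shape[3L]
  if (half_vox < cfg$n_rois / 2) {
    stop("grid too small for ", cfg$n_rois, " parcels", call. = FALSE)
  }
  structure(cfg, class = "lc_sim_config")
}

#' Expected tumor-to-parcel correlation and Fisher z under the generator
#'
#' Under the single-latent-factor model the tumor signal correlates with each
#' parcel signal at `rho * sqrt(base_within_corr)`; the expected Tu-EL value
#' is its Fisher z.
#'
#' @param rho tumor coupling weight in `[0, 1)`.
#' @param base_within_corr parcel equicorrelation.
#' @return Named list with `r` and `z`.
#' @export
expected_tu_el <- function(rho, base_within_corr) {
  r <- rho * sqrt(base_within_corr)
  list(r = r, z = atanh(r))
}

#' Simulate parcel + tumor mean time series
#'
#' Draws one latent factor per frame; parcel i is
#' `sqrt(b) * latent + sqrt(1-b) * noise_i` and the final (tumor) column is
#' `rho * latent + sqrt(1-rho^2) * noise_T`, so all columns have unit
#' variance in expectation and expected pairwise parcel correlation `b`.
#'
#' @param cfg an [synthetic_config()] object.
#' @param subject_seed optional integer; when given, seeds the RNG so the
#'   draw is reproducible in isolation.
#' @param rho_tumor coupling for the tumor column; default midpoint of
#'   `cfg$rho_tumor_range`.
#' @return `n_frames x (n_rois + 1)` matrix; tumor column last, named
#'   `"tumor"`.
#' @export
simulate_parcel_timeseries <- function(cfg, subject_seed = NULL, rho_tumor = NULL) {
  stopifnot(inherits(cfg, "lc_sim_config"))
  if (!is.null(subject_seed)) set.seed(as.integer(subject_seed))
  if (is.null(rho_tumor)) rho_tumor <- mean(cfg$rho_tumor_range)
  stopifnot(rho_tumor >= 0, rho_tumor < 1)
  T_len <- cfg$n_frames
  R <- cfg$n_rois
  b <- cfg$base_within_corr
  latent <- stats::rnorm(T_len)
  parcels <- sqrt(b) * latent +
    sqrt(1 - b) * matrix(stats::rnorm(T_len * R), T_len, R)
  tumor <- rho_tumor * latent + sqrt(1 - rho_tumor^2) * stats::rnorm(T_len)
  out <- cbind(parcels, tumor)
  colnames(out) <- c(paste0("roi", seq_len(R)), "tumor")
  out
}

#' ROI lookup table of the synthetic atlas
#'
#' Parcels `1..n_rois/2` are left-hemispheric, the rest right-hemispheric.
#'
#' @param cfg an [synthetic_config()].
#' @return Tibble with `roi_id`, `name`, `hemisphere`.
#' @export
synthetic_roi_table <- function(cfg) {
  R <- cfg$n_rois
  half <- R %/% 2L
  tibble::tibble(
    roi_id = seq_len(R),
    name = sprintf("parcel_%03d", seq_len(R)),
    hemisphere = rep(c("left", "right"), each = half)
  )
}

# parcel id per voxel: hemispheres split along x, each hemisphere's voxels
# split into contiguous equal-ish runs in linear order
synthetic_label_array <- function(cfg) {
  d <- cfg$grid_shape
  half_x <- floor(d[1L] / 2)
  lab <- array(0L, dim = d)
  ids_left <- seq_len(cfg$n_rois %/% 2L)
  ids_right <- ids_left + cfg$n_rois %/% 2L
  assign_hemi <- function(xs, ids) {
    vox <- which(slice.index(lab, 1L) %in% xs)
    runs <- split(vox, cut(seq_along(vox), breaks = length(ids), labels = FALSE))
    for (j in seq_along(ids)) lab[runs[[j]]] <<- ids[j]
  }
  assign_hemi(seq_len(half_x), ids_left)
  assign_hemi((half_x + 1L):d[1L], ids_right)
  lab
}

#' Synthetic atlas parcellation
#'
#' Partitions the configured grid into `n_rois` contiguous parcels with a
#' left/right split along the x axis.
#'
#' @param cfg an [synthetic_config()].
#' @return An `lc_atlas`.
#' @export
synthetic_atlas <- function(cfg) {
  lab <- synthetic_label_array(cfg)
  vol <- new_volume(lab, voxel_size = cfg$voxel_size_mm, kind = "label")
  new_atlas(vol, synthetic_roi_table(cfg))
}

# choose k contiguous parcel ids on the lesion side, starting position random
sample_lesioned_ids <- function(cfg) {
  half <- cfg$n_rois %/% 2L
  offset <- if (cfg$lesion_side == "left") 0L else half
  start <- sample.int(half - cfg$n_lesioned_rois + 1L, 1L)
  offset + start + seq_len(cfg$n_lesioned_rois) - 1L
}

#' Binary 6-neighborhood dilation of a mask volume
#'
#' @param mask a binary `lc_volume`.
#' @param iterations number of dilation passes.
#' @return A dilated binary `lc_volume`.
#' @export
dilate_mask <- function(mask, iterations = 1L) {
  stopifnot(inherits(mask, "lc_volume"), mask$kind == "binary")
  m <- mask$data > 0
  d <- dim(m)
  for (i in seq_len(iterations)) {
    grown <- m
    grown[-1, , ] <- grown[-1, , ] | m[-d[1L], , ]
    grown[-d[1L], , ] <- grown[-d[1L], , ] | m[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | m[, -d[2L], ]
    grown[, -d[2L], ] <- grown[, -d[2L], ] | m[, -1, ]
    grown[, , -1] <- grown[, , -1] | m[, , -d[3L]]
    grown[, , -d[3L]] <- grown[, , -d[3L]] | m[, , -1]
    m <- grown
  }
  new_volume(array(as.numeric(m), d), voxel_size = mask$voxel_size,
             affine = mask$affine, kind = "binary")
}

# voxel BOLD from parcel series: every voxel gets its parcel's series plus
# i.i.d. noise; tumor voxels get the tumor series instead (initial timepoint)
render_bold_array <- function(cfg, lab, parcel_ts, tumor_series = NULL,
                              tumor_vox = integer(0)) {
  d <- cfg$grid_shape
  T_len <- cfg$n_frames
  nvox <- prod(d)
  flat <- matrix(0, nvox, T_len)
  labv <- as.integer(lab)
  for (id in seq_len(cfg$n_rois)) {
    vox <- which(labv == id)
    if (!length(vox)) next
    flat[vox, ] <- matrix(parcel_ts[, id], length(vox), T_len, byrow = TRUE)
  }
  if (length(tumor_vox) && !is.null(tumor_series)) {
    flat[tumor_vox, ] <- matrix(tumor_series, length(tumor_vox), T_len, byrow = TRUE)
  }
  flat <- flat + matrix(stats::rnorm(nvox * T_len, sd = cfg$voxel_noise_sd), nvox, T_len)
  array(flat, dim = c(d, T_len))
}

simulate_scores <- function(cfg, group, z_true, age) {
  # five measures; patients are offset toward worse performance on all of
  # them; the alertness quotient additionally carries the planted coupling
  # slope (higher = worse)
  worse <- if (group == "patient") 1 else 0
  rn <- function(m, s) stats::rnorm(1L, m, s)
  alert <- function() cfg$alertness_intercept +
    cfg$behavior_slope * z_true + cfg$age_coef * age +
    stats::rnorm(1L, 0, cfg$behavior_noise_sd)
  tibble::tibble(
    learning_initial = rn(60 - 8 * worse, 6),
    learning_followup = rn(60 - 8 * worse, 6),
    consolidation_initial = rn(2 + 2 * worse, 1.5),
    consolidation_followup = rn(2 + 2 * worse, 1.5),
    recognition_initial = rn(28 - 4 * worse, 3),
    recognition_followup = rn(28 - 4 * worse, 3),
    alertness_initial = alert(),
    alertness_followup = alert(),
    flexibility_initial = rn(40 + 25 * worse, 12),
    flexibility_followup = rn(40 + 25 * worse, 12)
  )
}

#' Simulate a cohort at the time-series level
#'
#' Runs the generator and the connectivity stage in memory (no files): for
#' every subject, parcel/tumor series are drawn, patients lose the
#' `n_lesioned_rois` planted parcels, Fisher-z matrices and the Tu-EL / EL /
#' conEL summaries are computed for both timepoints, and behavioral scores
#' with the planted coupling dependence are attached. This is the fast path
#' used for statistical calibration; [render_cohort()] exercises the same
#' model through NIfTI files.
#'
#' @param cfg an [synthetic_config()].
#' @return Tibble, one row per subject: group, age, rho_true, z_true,
#'   tumor_volume, per-timepoint summaries and scores.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "lc_sim_config"))
  set.seed(cfg$seed)
  lut <- synthetic_roi_table(cfg)
  half <- cfg$n_rois %/% 2L
  n_all <- cfg$n_patients + cfg$n_controls
  rows <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    is_pat <- i <= cfg$n_patients
    age <- stats::runif(1L, cfg$age_range[1L], cfg$age_range[2L])
    rho <- if (is_pat) stats::runif(1L, cfg$rho_tumor_range[1L], cfg$rho_tumor_range[2L]) else NA_real_
    z_true <- if (is_pat) expected_tu_el(rho, cfg$base_within_corr)$z else 0
    excl <- if (is_pat) sample_lesioned_ids(cfg) else integer(0)
    summar <- list()
    for (tp in c("initial", "followup")) {
      ts_mat <- simulate_parcel_timeseries(cfg, rho_tumor = if (is_pat) rho else 0)
      keep <- setdiff(seq_len(cfg$n_rois), excl)
      with_tumor <- is_pat && tp == "initial"
      cols <- if (with_tumor) c(keep, cfg$n_rois + 1L) else keep
      ids <- if (with_tumor) c(keep, TUMOR_NODE) else keep
      ts <- as_timeseries(ts_mat[, cols, drop = FALSE], ids, excluded_ids = excl)
      m <- fc_matrix(ts)
      summar[[tp]] <- fc_summaries(m, lut,
                                   lesion_side = if (is_pat) cfg$lesion_side else "none")
    }
    scores <- simulate_scores(cfg, if (is_pat) "patient" else "control", z_true, age)
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("S%03d", i),
        group = if (is_pat) "patient" else "control",
        age = age,
        lesion_side = if (is_pat) cfg$lesion_side else "none",
        rho_true = rho, z_true = if (is_pat) z_true else NA_real_,
        tumor_volume = if (is_pat) stats::runif(1L, 20, 120) else NA_real_,
        tu_el_initial = summar$initial$tu_el,
        el_initial = summar$initial$el,
        con_el_initial = summar$initial$con_el,
        tu_el_followup = summar$followup$tu_el,
        el_followup = summar$followup$el,
        con_el_followup = summar$followup$con_el
      ),
      scores
    )
  }
  dplyr::bind_rows(rows)
}

#' Render a synthetic cohort to disk as NIfTI + CSV files
#'
#' Writes, under `out_dir`: the atlas label image and ROI lookup table, one
#' 4D BOLD NIfTI per subject and timepoint, binary tumor and resection masks
#' for patients, a cohort CSV, a per-file manifest CSV consumed by
#' [run_pipeline()], and a `ground_truth.json` recording every planted
#' quantity. Followup BOLD has the same extralesional structure but no tumor
#' signal; the resection mask is the tumor mask dilated by
#' `resection_dilation_vox`.
#'
#' @param cfg an [synthetic_config()].
#' @param out_dir writable output directory (created if needed).
#' @return Invisibly, the manifest tibble.
#' @export
render_cohort <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "lc_sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  atlas <- synthetic_atlas(cfg)
  lab <- atlas$labels$data
  labv <- as.integer(lab)
  save_volume(atlas$labels, file.path(out_dir, "atlas.nii.gz"))
  readr::write_csv(atlas$roi_table, file.path(out_dir, "roi_lut.csv"))

  n_all <- cfg$n_patients + cfg$n_controls
  manifest <- list()
  cohort <- list()
  truth <- list(config = unclass(cfg), subjects = list())
  for (i in seq_len(n_all)) {
    sid <- sprintf("S%03d", i)
    is_pat <- i <= cfg$n_patients
    age <- stats::runif(1L, cfg$age_range[1L], cfg$age_range[2L])
    rho <- if (is_pat) stats::runif(1L, cfg$rho_tumor_range[1L], cfg$rho_tumor_range[2L]) else NA_real_
    z_true <- if (is_pat) expected_tu_el(rho, cfg$base_within_corr)$z else 0

    tumor_path <- resection_path <- NA_character_
    tumor_vox <- integer(0)
    excl <- integer(0)
    tumor_vol <- NA_real_
    if (is_pat) {
      excl <- sample_lesioned_ids(cfg)
      tumor_vox <- which(labv %in% excl)
      tmask <- new_volume(array(as.numeric(seq_along(labv) %in% tumor_vox),
                                dim = cfg$grid_shape),
                          voxel_size = cfg$voxel_size_mm, kind = "binary")
      rmask <- dilate_mask(tmask, cfg$resection_dilation_vox)
      tumor_path <- file.path(out_dir, paste0(sid, "_tumor.nii.gz"))
      resection_path <- file.path(out_dir, paste0(sid, "_resection.nii.gz"))
      save_volume(tmask, tumor_path)
      save_volume(rmask, resection_path)
      tumor_vol <- tumor_volume_cm3(new_lesion_mask(tmask, "tumor", cfg$lesion_side))
    }

    bold_paths <- c(initial = NA_character_, followup = NA_character_)
    for (tp in c("initial", "followup")) {
      ts_mat <- simulate_parcel_timeseries(cfg, rho_tumor = if (is_pat) rho else 0)
      tumor_series <- if (is_pat && tp == "initial") ts_mat[, cfg$n_rois + 1L] else NULL
      arr <- render_bold_array(cfg, lab, ts_mat,
                               tumor_series = tumor_series,
                               tumor_vox = if (is_pat) tumor_vox else integer(0))
      vol <- new_volume(arr, voxel_size = cfg$voxel_size_mm, kind = "float")
      p <- file.path(out_dir, paste0(sid, "_bold_", tp, ".nii.gz"))
      save_volume(vol, p)
      bold_paths[tp] <- p
    }

    scores <- simulate_scores(cfg, if (is_pat) "patient" else "control", z_true, age)
    cohort[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject_id = sid,
                     group = if (is_pat) "patient" else "control",
                     age = age,
                     lesion_side = if (is_pat) cfg$lesion_side else "none",
                     tumor_volume = tumor_vol),
      scores
    )
    manifest[[i]] <- tibble::tibble(
      subject_id = sid,
      bold_initial = bold_paths["initial"],
      bold_followup = bold_paths["followup"],
      tumor_mask = tumor_path,
      resection_mask = resection_path
    )
    truth$subjects[[sid]] <- list(
      group = if (is_pat) "patient" else "control",
      rho_true = rho, z_true = if (is_pat) z_true else NA_real_,
      excluded_roi_ids = excl, tumor_volume_cm3 = tumor_vol,
      age = age
    )
  }
  cohort_tbl <- dplyr::bind_rows(cohort)
  manifest_tbl <- dplyr::bind_rows(manifest)
  readr::write_csv(cohort_tbl, file.path(out_dir, "cohort.csv"))
  readr::write_csv(manifest_tbl, file.path(out_dir, "manifest.csv"))
  truth$behavior_slope <- cfg$behavior_slope
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest_tbl)
}

#' Regenerate follow-up data for an existing cohort directory
#'
#' Overwrites each subject's follow-up BOLD with a fresh draw sharing the
#' extralesional structure (no tumor signal) and writes the resection mask as
#' the stored tumor mask dilated by `iterations`. Intended for exercising the
#' longitudinal combined-mask path with alternative follow-up realizations.
#'
#' @param cfg the [synthetic_config()] used to render the cohort.
#' @param cohort_dir directory produced by [render_cohort()].
#' @param iterations dilation passes for the resection mask.
#' @param seed RNG seed for the new follow-up draws.
#' @return Invisibly, the updated manifest tibble.
#' @export
make_followup <- function(cfg, cohort_dir, iterations = cfg$resection_dilation_vox,
                          seed = cfg$seed + 1L) {
  manifest <- readr::read_csv(file.path(cohort_dir, "manifest.csv"),
                              show_col_types = FALSE, progress = FALSE)
  truth <- jsonlite::read_json(file.path(cohort_dir, "ground_truth.json"))
  atlas <- load_volume(file.path(cohort_dir, "atlas.nii.gz"), kind = "label")
  lab <- atlas$data
  set.seed(as.integer(seed))
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    ts_mat <- simulate_parcel_timeseries(cfg, rho_tumor = 0)
    arr <- render_bold_array(cfg, lab, ts_mat)
    save_volume(new_volume(arr, voxel_size = cfg$voxel_size_mm, kind = "float"),
                manifest$bold_followup[i])
    if (!is.na(manifest$tumor_mask[i])) {
      tmask <- load_volume(manifest$tumor_mask[i], kind = "binary")
      save_volume(dilate_mask(tmask, iterations), manifest$resection_mask[i])
    }
  }
  invisible(manifest)
}
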