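#' Pipeline configuration
#'
#' Bundles the file paths and tunable parameters of a full cohort run.
#' All referenced paths must exist at validation time.
#'
#' @param cohort_csv cohort table, see [load_cohort_table()].
#' @param manifest_csv per-subject image manifest with columns `subject_id`,
#'   `bold_initial`, `bold_followup`, `tumor_mask`, `resection_mask` (mask
#'   cells empty for controls).
#' @param atlas_nii atlas label image.
#' @param lut_csv ROI lookup table.
#' @param out_dir output directory for result tables and the run log.
#' @param min_overlap_voxels ROI-exclusion threshold, see [lesioned_roi_ids()].
#' @param clip correlation clip of [fc_matrix()].
#' @param alpha family-wise significance level.
#' @param m_patients,m_controls Bonferroni family sizes for the two
#'   correlation families; `NULL` means "number of tests actually run".
#' @param winsorize apply [winsorize_group()] to every score, per group and
#'   timepoint, before the statistics.
#' @param highpass apply [highpass_filter()] to extracted series.
#' @param tr_s,cutoff_hz filter parameters (used when `highpass = TRUE`).
#' @param seed recorded in the run log; the pipeline itself is deterministic.
#' @return A validated list of class `lc_pipeline_config`.
#' @export
pipeline_config <- function(cohort_csv, manifest_csv, atlas_nii, lut_csv,
                            out_dir, min_overlap_voxels = 1L, clip = 1 - 1e-7,
                            alpha = 0.05, m_patients = NULL, m_controls = NULL,
                            winsorize = TRUE, highpass = FALSE, tr_s = 2.2,
                            cutoff_hz = 0.01, seed = 1L) {
  for (p in c(cohort_csv, manifest_csv, atlas_nii, lut_csv)) {
    if (!file.exists(p)) stop("config path does not exist: ", p, call. = FALSE)
  }
  stopifnot(alpha > 0, alpha < 1, min_overlap_voxels >= 1L, clip > 0, clip < 1)
  structure(list(cohort_csv = cohort_csv, manifest_csv = manifest_csv,
                 atlas_nii = atlas_nii, lut_csv = lut_csv, out_dir = out_dir,
                 min_overlap_voxels = as.integer(min_overlap_voxels),
                 clip = clip, alpha = alpha, m_patients = m_patients,
                 m_controls = m_controls, winsorize = winsorize,
                 highpass = highpass, tr_s = tr_s, cutoff_hz = cutoff_hz,
                 seed = as.integer(seed)),
            class = "lc_pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @return An `lc_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("cohort_csv", "manifest_csv", "atlas_nii", "lut_csv", "out_dir")) {
    if (!is.null(raw[[key]]) && !grepl("^(/|[A-Za-z]:)", raw[[key]])) {
      raw[[key]] <- file.path(base, raw[[key]])
    }
  }
  do.call(pipeline_config, raw)
}

extract_subject_summaries <- function(cfg, atlas, lut, row, manifest_row) {
  is_pat <- row$group == "patient"
  stage <- "load"
  withCallingHandlers(
    tryCatch({
      out <- list()
      tumor <- resection <- combined <- NULL
      excluded <- integer(0)
      if (is_pat) {
        stage <- "masks"
        tumor <- new_lesion_mask(load_volume(manifest_row$tumor_mask, kind = "binary"),
                                 "tumor", row$lesion_side)
        resection <- new_lesion_mask(load_volume(manifest_row$resection_mask, kind = "binary"),
                                     "resection", row$lesion_side)
        combined <- combine_lesion_masks(tumor, resection)
        excluded <- lesioned_roi_ids(atlas, combined, cfg$min_overlap_voxels)
      }
      node_sets <- list()
      for (tp in c("initial", "followup")) {
        stage <- paste0("extract:", tp)
        bold <- load_volume(manifest_row[[paste0("bold_", tp)]])
        check_grid_compatibility(c(list(bold, atlas$labels),
                                   if (is_pat) list(combined$mask)))
        masked <- if (is_pat) apply_lesion_mask(bold, combined) else bold
        ts <- extract_roi_timeseries(
          masked, atlas, excluded,
          tumor = if (is_pat && tp == "initial") tumor else NULL,
          tumor_bold = bold
        )
        if (cfg$highpass) ts <- highpass_filter(ts, cfg$cutoff_hz, cfg$tr_s)
        stage <- paste0("fc:", tp)
        m <- fc_matrix(ts, clip = cfg$clip)
        node_sets[[tp]] <- setdiff(ts$node_ids, TUMOR_NODE)
        out[[tp]] <- dplyr::mutate(
          fc_summaries(m, lut, row$lesion_side, row$subject_id, tp),
          n_nodes = length(ts$node_ids),
          n_excluded = length(ts$excluded_ids)
        )
      }
      if (!identical(node_sets$initial, node_sets$followup)) {
        stop("retained node sets differ between timepoints")
      }
      dplyr::bind_rows(out)
    },
    error = function(e) {
      stop("pipeline failed for subject ", row$subject_id, " at stage '",
           stage, "': ", conditionMessage(e), call. = FALSE)
    }),
    warning = function(w) invokeRestart("muffleWarning")
  )
}

winsorize_scores <- function(cohort) {
  for (col in score_columns()) {
    for (grp in unique(cohort$group)) {
      idx <- which(cohort$group == grp & !is.na(cohort[[col]]))
      if (length(idx) >= 3L) {
        w <- suppressWarnings(winsorize_group(cohort[[col]][idx]))
        cohort[[col]][idx] <- as.numeric(w)
      }
    }
  }
  cohort
}

run_correlation_family <- function(data, fc_cols, score_cols, covariates, family, m) {
  rows <- list()
  for (fc in fc_cols) {
    for (sc in score_cols) {
      need <- c(fc, sc, covariates)
      ok <- stats::complete.cases(data[need])
      n_ok <- sum(ok)
      if (n_ok < length(covariates) + 3L) next
      pc <- partial_correlation(data[[fc]][ok], data[[sc]][ok],
                                covariates = as.matrix(data[covariates])[ok, , drop = FALSE])
      rows[[length(rows) + 1L]] <- dplyr::mutate(tidy(pc),
                                                 family = family, fc_measure = fc,
                                                 score = sc, .before = 1L)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    m_eff <- if (is.null(m)) nrow(out) else m
    out$m <- m_eff
    out$p.adjusted <- adjust_p(out$p.value, m = max(m_eff, nrow(out)))
  }
  out
}

#' Run the full lesion-aware connectivity pipeline
#'
#' Orchestrates extraction, connectivity and statistics over a cohort:
#' per-subject Fisher-z matrices and Tu-EL / EL / conEL summaries at both
#' timepoints (the combined tumor+resection mask drives voxel masking and
#' ROI exclusion at both, so the node set is longitudinally constant);
#' group-bound winsorization of scores; mixed RM-ANCOVA per cognitive
#' measure and per FC summary; a multivariate (Wilks) group test across the
#' five measures; and covariate-adjusted partial-correlation families for
#' patients (age + tumor volume) and controls (age), Bonferroni-adjusted.
#' Result tables are returned and written as CSVs plus a JSON run log.
#'
#' @param cfg an [pipeline_config()].
#' @return An object of class `lc_results`: list of tibbles `summaries`,
#'   `cohort`, `ancova`, `multivariate`, `correlations`, plus `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "lc_pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- load_cohort_table(cfg$cohort_csv)
  manifest <- readr::read_csv(cfg$manifest_csv, show_col_types = FALSE, progress = FALSE)
  if (!all(cohort$subject_id %in% manifest$subject_id)) {
    stop("manifest lacks entries for some subjects", call. = FALSE)
  }
  atlas <- new_atlas(load_volume(cfg$atlas_nii, kind = "label"),
                     load_roi_table(cfg$lut_csv))
  lut <- atlas$roi_table

  summaries <- dplyr::bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    extract_subject_summaries(cfg, atlas, lut, row,
                              manifest[manifest$subject_id == row$subject_id, ])
  }))

  scored <- if (cfg$winsorize) winsorize_scores(cohort) else cohort

  wide_fc <- tidyr::pivot_wider(summaries,
                                id_cols = "subject_id",
                                names_from = "timepoint",
                                values_from = c("tu_el", "el", "con_el"))
  analysis_tbl <- dplyr::left_join(scored, wide_fc, by = "subject_id")

  # mixed RM-ANCOVA per cognitive measure and per FC summary, age-adjusted
  ancova_rows <- list()
  targets <- c(stats::setNames(cognitive_measures()$measure, cognitive_measures()$measure),
               el = "el", con_el = "con_el")
  for (nm in names(targets)) {
    v <- targets[[nm]]
    ci <- paste0(v, "_initial"); cf <- paste0(v, "_followup")
    fit <- tryCatch(rm_ancova(analysis_tbl, ci, cf, group = "group", covariates = "age"),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ancova_rows[[nm]] <- dplyr::mutate(tidy(fit), analysis = nm, n = fit$n, .before = 1L)
  }
  ancova <- dplyr::bind_rows(ancova_rows)

  # multivariate group effect over the five measures (subject means), age-adjusted
  meas <- cognitive_measures()$measure
  mm <- sapply(meas, function(m) {
    rowMeans(cbind(analysis_tbl[[paste0(m, "_initial")]],
                   analysis_tbl[[paste0(m, "_followup")]]))
  })
  cc <- stats::complete.cases(mm, analysis_tbl$age)
  multivariate <- if (sum(cc) >= length(meas) + 4L &&
                      length(unique(analysis_tbl$group[cc])) == 2L) {
    fit <- multivariate_group_test(mm[cc, , drop = FALSE],
                                   analysis_tbl$group[cc],
                                   covariates = analysis_tbl$age[cc])
    tidy(fit)
  } else {
    tibble::tibble()
  }

  score_cols <- score_columns()
  pats <- dplyr::filter(analysis_tbl, .data$group == "patient")
  ctrls <- dplyr::filter(analysis_tbl, .data$group == "control")
  fc_cols_pat <- c("tu_el_initial", "el_initial", "el_followup",
                   "con_el_initial", "con_el_followup")
  fc_cols_ctrl <- c("el_initial", "el_followup", "con_el_initial", "con_el_followup")
  correlations <- dplyr::bind_rows(
    if (nrow(pats) >= 5L)
      run_correlation_family(pats, fc_cols_pat, score_cols,
                             c("age", "tumor_volume"), "patients", cfg$m_patients),
    if (nrow(ctrls) >= 4L)
      run_correlation_family(ctrls, fc_cols_ctrl, score_cols,
                             "age", "controls", cfg$m_controls)
  )

  results <- structure(
    list(summaries = summaries, cohort = scored, ancova = ancova,
         multivariate = multivariate, correlations = correlations,
         config = cfg),
    class = "lc_results"
  )
  write_results(results)
  results
}

write_results <- function(results) {
  cfg <- results$config
  readr::write_csv(results$summaries, file.path(cfg$out_dir, "summaries.csv"))
  readr::write_csv(results$ancova, file.path(cfg$out_dir, "ancova.csv"))
  readr::write_csv(results$correlations, file.path(cfg$out_dir, "correlations.csv"))
  if (nrow(results$multivariate)) {
    readr::write_csv(results$multivariate, file.path(cfg$out_dir, "multivariate.csv"))
  }
  log <- list(
    package = "lesionconn",
    version = as.character(utils::packageVersion("lesionconn")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = cfg[c("min_overlap_voxels", "clip", "alpha", "winsorize",
                       "highpass", "tr_s", "cutoff_hz")],
    n_subjects = length(unique(results$summaries$subject_id))
  )
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' @export
print.lc_results <- function(x, ...) {
  cat("<lc_results> ", length(unique(x$summaries$subject_id)), " subjects, ",
      nrow(x$ancova), " ANCOVA effect rows, ", nrow(x$correlations),
      " partial correlations\n", sep = "")
  invisible(x)
}
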