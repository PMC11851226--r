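#' Cognitive measures handled by the pipeline
#'
#' Five domains, each scored at two timepoints. The polarity flag records
#' whether a higher score means worse performance (alertness quotient,
#' consolidation = forgotten words, flexibility = reaction-time difference) or
#' better performance (learning, recognition = correct words).
#'
#' @return A tibble with columns `measure` and `higher_is_worse`.
#' @export
cognitive_measures <- function() {
  tibble::tibble(
    measure = c("learning", "consolidation", "recognition", "alertness", "flexibility"),
    higher_is_worse = c(FALSE, TRUE, FALSE, TRUE, TRUE)
  )
}

score_columns <- function() {
  paste(rep(cognitive_measures()$measure, each = 2),
        rep(c("initial", "followup"), 5L), sep = "_")
}

#' Read and validate a cohort table
#'
#' One row per subject. Required columns: `subject_id`, `group`
#' (`patient`/`control`), `age`, `lesion_side` (`left`/`right`/`none`),
#' `tumor_volume` (cm^3, patients only) and the ten score columns
#' `<measure>_<timepoint>` for the five measures of [cognitive_measures()]
#' at timepoints `initial` and `followup`. Empty score cells become `NA`
#' (never 0); structural invariant breaches raise validation errors.
#'
#' @param path CSV file with a header row.
#' @return A tibble of typed cohort records.
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort table: no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(raw)
}

#' Validate an in-memory cohort table
#'
#' @param df data frame shaped as described in [load_cohort_table()].
#' @return The validated tibble (scores coerced to numeric, groups/sides to
#'   lower case).
#' @export
validate_cohort <- function(df) {
  df <- tibble::as_tibble(df)
  needed <- c("subject_id", "group", "age", "lesion_side", "tumor_volume", score_columns())
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$group <- tolower(as.character(df$group))
  df$lesion_side <- tolower(as.character(df$lesion_side))
  bad_grp <- setdiff(unique(df$group), c("patient", "control"))
  if (length(bad_grp)) stop("unknown group label(s): ", paste(bad_grp, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$subject_id)) {
    dup <- df$subject_id[duplicated(df$subject_id)][1L]
    stop("duplicate subject_id: ", dup, call. = FALSE)
  }
  bad_side <- setdiff(unique(df$lesion_side), c("left", "right", "none"))
  if (length(bad_side)) stop("unknown lesion_side: ", paste(bad_side, collapse = ", "), call. = FALSE)

  ctrl <- df$group == "control"
  if (any(ctrl & df$lesion_side != "none")) {
    stop("control subjects must have lesion_side = none", call. = FALSE)
  }
  tv <- suppressWarnings(as.numeric(df$tumor_volume))
  if (any(ctrl & !is.na(tv))) {
    stop("control subjects must not carry a tumor_volume", call. = FALSE)
  }
  if (any(!ctrl & df$lesion_side == "none")) {
    stop("patients must have lesion_side left or right", call. = FALSE)
  }
  df$tumor_volume <- tv
  df$age <- as.numeric(df$age)
  if (any(!is.finite(df$age))) stop("non-finite age", call. = FALSE)

  for (sc in score_columns()) {
    v <- suppressWarnings(as.numeric(df[[sc]]))
    if (any(is.infinite(v))) stop("non-finite score in ", sc, call. = FALSE)
    df[[sc]] <- v
  }
  n_na <- sum(is.na(as.matrix(df[score_columns()])))
  if (n_na > 0L) {
    rlang::inform(paste0("cohort table: ", n_na,
                         " missing score cell(s) kept as NA (listwise deletion downstream)"))
  }
  df
}

#' Read a ROI lookup table
#'
#' Columns `roi_id` (unique positive integers), `name`, `hemisphere`
#' (`left`/`right`). Together with the label volume this defines the atlas
#' node set (canonically 246 regions, but any R >= 2 is accepted).
#'
#' @param path CSV file.
#' @return Tibble with columns `roi_id`, `name`, `hemisphere`.
#' @export
load_roi_table <- function(path) {
  if (!file.exists(path)) stop("cannot read ROI table: no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_roi_table(df)
}

validate_roi_table <- function(df) {
  df <- tibble::as_tibble(df)
  miss <- setdiff(c("roi_id", "name", "hemisphere"), names(df))
  if (length(miss)) stop("ROI table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df$roi_id <- as.integer(df$roi_id)
  if (any(is.na(df$roi_id)) || any(df$roi_id <= 0L)) stop("roi_id must be positive integers", call. = FALSE)
  if (anyDuplicated(df$roi_id)) stop("duplicate roi_id in ROI table", call. = FALSE)
  df$hemisphere <- tolower(as.character(df$hemisphere))
  bad <- setdiff(unique(df$hemisphere), c("left", "right"))
  if (length(bad)) stop("hemisphere must be left/right, got: ", paste(bad, collapse = ", "), call. = FALSE)
  df[c("roi_id", "name", "hemisphere")]
}

#' Assemble an atlas parcellation
#'
#' Pairs an integer label volume with its ROI lookup table and checks that
#' every nonzero label in the volume is described by the table (background 0).
#'
#' @param labels an `lc_volume` of kind `"label"`.
#' @param roi_table tibble as returned by [load_roi_table()].
#' @return An object of class `lc_atlas`.
#' @export
new_atlas <- function(labels, roi_table) {
  stopifnot(inherits(labels, "lc_volume"))
  if (labels$kind != "label") stop("atlas labels must be a label volume", call. = FALSE)
  roi_table <- validate_roi_table(roi_table)
  present <- setdiff(unique(as.integer(labels$data)), 0L)
  orphan <- setdiff(present, roi_table$roi_id)
  if (length(orphan)) {
    stop("label(s) in volume missing from ROI table: ",
         paste(utils::head(orphan, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(labels = labels, roi_table = roi_table), class = "lc_atlas")
}

#' @export
print.lc_atlas <- function(x, ...) {
  cat("<lc_atlas> ", nrow(x$roi_table), " ROIs on a ",
      paste(dim(x$labels$data)[1:3], collapse = "x"), " grid\n", sep = "")
  invisible(x)
}
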