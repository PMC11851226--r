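#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a Fisher-z connectivity matrix
#'
#' @param object an `lc_fc`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.lc_fc <- function(object, ...) {
  edges <- tidy(object)
  edges2 <- dplyr::bind_rows(edges,
                             dplyr::rename(edges, node_a = "node_b", node_b = "node_a"))
  ggplot2::ggplot(edges2, ggplot2::aes(x = factor(.data$node_a),
                                       y = factor(.data$node_b),
                                       fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Fisher z",
                  title = "Functional connectivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

results_behavior_long <- function(results) {
  tidyr::pivot_longer(results$cohort,
                      cols = dplyr::all_of(score_columns()),
                      names_to = c("measure", "timepoint"),
                      names_pattern = "(.*)_(initial|followup)",
                      values_to = "score")
}

#' Behavioral scores by group and timepoint
#'
#' Box-and-strip plot of each cognitive measure, split by group, with
#' initial and follow-up assessments side by side.
#'
#' @param results an `lc_results` bundle from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_behavior <- function(results) {
  long <- results_behavior_long(results)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$score,
                                     fill = .data$timepoint)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.8), size = 0.7, alpha = 0.6) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Cognitive performance by group and timepoint") +
    ggplot2::theme_bw()
}

#' Connectivity summaries by group and timepoint
#'
#' @param results an `lc_results` bundle.
#' @return A ggplot object.
#' @export
plot_fc_summaries <- function(results) {
  long <- tidyr::pivot_longer(
    dplyr::left_join(results$summaries,
                     results$cohort[c("subject_id", "group")], by = "subject_id"),
    cols = c("el", "con_el"), names_to = "summary", values_to = "z"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$z,
                                     fill = .data$timepoint)) +
    ggplot2::geom_boxplot(alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::facet_wrap(~summary) +
    ggplot2::labs(x = NULL, y = "mean Fisher z",
                  title = "Extralesional and contralesional connectivity") +
    ggplot2::theme_bw()
}

#' Tumor coupling versus attention performance
#'
#' Scatter of patients' preoperative Tu-EL values against the alertness
#' quotient (higher = worse), annotated with the covariate-adjusted partial
#' correlation from the results bundle when available.
#'
#' @param results an `lc_results` bundle.
#' @param score score column, default `"alertness_initial"`.
#' @return A ggplot object, or `NULL` when no patient has a Tu-EL value.
#' @export
plot_tuel_scatter <- function(results, score = "alertness_initial") {
  df <- dplyr::left_join(
    dplyr::filter(results$summaries, .data$timepoint == "initial", !is.na(.data$tu_el)),
    results$cohort, by = "subject_id"
  )
  if (!nrow(df)) return(NULL)
  ann <- dplyr::filter(results$correlations,
                       .data$family == "patients",
                       .data$fc_measure == "tu_el_initial",
                       .data$score == !!score)
  lab <- if (nrow(ann)) sprintf("partial r = %.3f, p = %.3g", ann$estimate[1L], ann$p.value[1L]) else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$tu_el, y = .data[[score]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "#b2182b") +
    ggplot2::labs(x = "Tu-EL (mean Fisher z)", y = score,
                  title = "Tumor coupling vs attention",
                  subtitle = lab) +
    ggplot2::theme_bw()
  p
}

#' Tumor coupling by tumor grade
#'
#' Descriptive plot of mean Tu-EL per ordinal grade (no test is attached).
#' Requires a `grade` column in the cohort table.
#'
#' @param results an `lc_results` bundle.
#' @return A ggplot object, or `NULL` when no grade column is present.
#' @export
plot_tuel_by_grade <- function(results) {
  if (!"grade" %in% names(results$cohort)) return(NULL)
  df <- dplyr::left_join(
    dplyr::filter(results$summaries, .data$timepoint == "initial", !is.na(.data$tu_el)),
    results$cohort, by = "subject_id"
  )
  if (!nrow(df)) return(NULL)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$grade), y = .data$tu_el)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "#4393c3", alpha = 0.7) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "tumor grade", y = "Tu-EL (mean Fisher z)",
                  title = "Tumor coupling by grade") +
    ggplot2::theme_bw()
}

#' Write descriptive figures and their underlying data
#'
#' Saves the figure source data as CSVs (always) and the rendered figures as
#' PNGs (best effort: device failures are caught and never abort a run).
#'
#' @param results an `lc_results` bundle.
#' @param out_dir output directory, default `<config out_dir>/figures`.
#' @return Invisibly, the character vector of files written.
#' @export
render_report <- function(results, out_dir = file.path(results$config$out_dir, "figures")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  save_data <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, p)
    written <<- c(written, p)
  }
  save_plot <- function(plot, name) {
    if (is.null(plot)) return(invisible(NULL))
    p <- file.path(out_dir, paste0(name, ".png"))
    ok <- tryCatch({
      suppressMessages(ggplot2::ggsave(p, plot, width = 8, height = 6, dpi = 120))
      TRUE
    }, error = function(e) FALSE)
    if (ok) written <<- c(written, p)
  }
  save_data(results_behavior_long(results), "behavior_by_group")
  save_plot(plot_behavior(results), "behavior_by_group")
  save_data(results$summaries, "fc_summaries")
  save_plot(plot_fc_summaries(results), "fc_summaries")
  has_tuel <- any(!is.na(results$summaries$tu_el))
  if (has_tuel) {
    save_plot(plot_tuel_scatter(results), "tuel_vs_alertness")
    save_plot(plot_tuel_by_grade(results), "tuel_by_grade")
  }
  invisible(written)
}
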