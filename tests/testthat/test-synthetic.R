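small_cfg <- function(seed = 99, ...) {
  synthetic_config(n_rois = 20L, grid_shape = c(6L, 4L, 3L), n_frames = 60L,
                   n_patients = 4L, n_controls = 4L, n_lesioned_rois = 3L,
                   seed = seed, ...)
}

test_that("the generator is fully deterministic given config + seed", {
  cfg <- small_cfg()
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  render_cohort(cfg, d1)
  render_cohort(cfg, d2)
  for (f in c("cohort.csv", "roi_lut.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  b1 <- load_volume(file.path(d1, "S001_bold_initial.nii.gz"))
  b2 <- load_volume(file.path(d2, "S001_bold_initial.nii.gz"))
  expect_identical(b1$data, b2$data)

  s3 <- simulate_study(small_cfg(seed = 100))
  expect_false(identical(s1$el_initial, s3$el_initial))
})

test_that("seed is mandatory and invariants are enforced", {
  expect_error(synthetic_config(), "seed is mandatory")
  expect_error(synthetic_config(n_lesioned_rois = 12, n_rois = 20, seed = 1))
  expect_error(synthetic_config(base_within_corr = 0, seed = 1))
  expect_error(synthetic_config(n_rois = 246, grid_shape = c(4, 4, 4), seed = 1),
               "grid too small")
})

test_that("parcel series recover the configured equicorrelation", {
  cfg <- synthetic_config(n_rois = 10L, grid_shape = c(6L, 4L, 3L),
                          n_frames = 300L, base_within_corr = 0.3,
                          n_patients = 1L, n_controls = 0L, n_lesioned_rois = 2L,
                          seed = 1)
  rs <- vapply(1:120, function(s) {
    ts <- simulate_parcel_timeseries(cfg, subject_seed = 2000 + s)
    cm <- cor(ts[, 1:10])
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  # mean pairwise r within 3 standard errors of the target
  expect_lt(abs(mean(rs) - 0.3), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("tumor coupling is null at rho = 0 and monotone in rho", {
  cfg <- synthetic_config(n_rois = 10L, grid_shape = c(6L, 4L, 3L),
                          n_frames = 300L, n_patients = 1L, n_controls = 0L,
                          n_lesioned_rois = 2L, seed = 1)
  mean_tuel <- function(rho, n_seeds = 80) {
    zs <- vapply(seq_len(n_seeds), function(s) {
      ts <- simulate_parcel_timeseries(cfg, subject_seed = 3000 + 7 * s + round(1e3 * rho),
                                       rho_tumor = rho)
      m <- fc_matrix(as_timeseries(ts, c(1:10, TUMOR_NODE)))
      summary_tu_el(m)
    }, numeric(1))
    c(mean = mean(zs), se = sd(zs) / sqrt(n_seeds))
  }
  null <- mean_tuel(0)
  expect_lt(abs(null["mean"]), 3 * null["se"])
  lo <- mean_tuel(0.3); hi <- mean_tuel(0.8)
  expect_gt(hi["mean"], lo["mean"])
  # and the recovered means track the analytic mixing prediction
  expect_lt(abs(lo["mean"] - expected_tu_el(0.3, 0.3)$z), 4 * lo["se"] + 0.02)
  expect_lt(abs(hi["mean"] - expected_tu_el(0.8, 0.3)$z), 4 * hi["se"] + 0.02)
})

test_that("rendered cohorts carry recoverable planted truth", {
  cfg <- small_cfg(seed = 123)
  dir <- withr::local_tempdir()
  render_cohort(cfg, dir)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  atlas <- new_atlas(load_volume(file.path(dir, "atlas.nii.gz"), kind = "label"),
                     load_roi_table(file.path(dir, "roi_lut.csv")))
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"), show_col_types = FALSE)
  cohort <- load_cohort_table(file.path(dir, "cohort.csv"))

  for (sid in cohort$subject_id[cohort$group == "patient"]) {
    planted <- truth$subjects[[sid]]
    row <- manifest[manifest$subject_id == sid, ]
    tumor <- new_lesion_mask(load_volume(row$tumor_mask, kind = "binary"),
                             "tumor", cfg$lesion_side)
    # tumor mask overlaps exactly the planted parcels
    expect_identical(lesioned_roi_ids(atlas, tumor),
                     sort(as.integer(planted$excluded_roi_ids)))
    # planted parcels sit on the configured lesion side
    expect_true(all(atlas$roi_table$hemisphere[
      match(planted$excluded_roi_ids, atlas$roi_table$roi_id)] == cfg$lesion_side))
    # pipeline tumor volume equals the recorded ground truth
    expect_equal(tumor_volume_cm3(tumor), planted$tumor_volume_cm3)
    expect_equal(cohort$tumor_volume[cohort$subject_id == sid],
                 planted$tumor_volume_cm3)
  }
  # controls carry no masks
  ctrl <- manifest[manifest$subject_id %in% cohort$subject_id[cohort$group == "control"], ]
  expect_true(all(is.na(ctrl$tumor_mask)))
})

test_that("followup regeneration keeps the resection superset contract", {
  cfg <- small_cfg(seed = 321)
  dir <- withr::local_tempdir()
  render_cohort(cfg, dir)
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"), show_col_types = FALSE)
  row <- manifest[1, ]
  tumor <- load_volume(row$tumor_mask, kind = "binary")

  # dilation 0: resection equals tumor, combined equals tumor
  make_followup(cfg, dir, iterations = 0L, seed = 555)
  res0 <- load_volume(row$resection_mask, kind = "binary")
  expect_identical(res0$data, tumor$data)
  comb0 <- combine_lesion_masks(
    new_lesion_mask(tumor, "tumor", cfg$lesion_side),
    new_lesion_mask(res0, "resection", cfg$lesion_side))
  expect_identical(comb0$mask$data, tumor$data)

  # dilation 1: resection strictly contains the tumor
  make_followup(cfg, dir, iterations = 1L, seed = 556)
  res1 <- load_volume(row$resection_mask, kind = "binary")
  expect_true(all(res1$data >= tumor$data))
  expect_gt(sum(res1$data), sum(tumor$data))
})

test_that("dilation grows masks by the 6-neighborhood", {
  m <- mask_from_indices(which(array(seq_len(64), c(4, 4, 4)) == 22),
                         dim3 = c(4, 4, 4))
  d1 <- dilate_mask(m, 1L)
  expect_identical(sum(d1$data), 7)  # center + 6 face neighbors
  expect_true(all(d1$data >= m$data))
})

test_that("planted behavioral slope propagates with the documented polarity", {
  cfg <- synthetic_config(n_rois = 20L, grid_shape = c(6L, 4L, 3L),
                          n_frames = 120L, n_patients = 14L, n_controls = 4L,
                          n_lesioned_rois = 3L, seed = 77)
  st <- simulate_study(cfg)
  pats <- st[st$group == "patient", ]
  # higher true coupling -> higher (worse) alertness score
  expect_gt(cor(pats$z_true, pats$alertness_initial), 0.5)
})
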