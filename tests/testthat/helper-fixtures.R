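# Small in-code fixtures shared across test files.

# a 4x4x4 grid split into 4 ROIs (2 left, 2 right along x)
tiny_atlas <- function(voxel_size = c(2, 2, 2)) {
  lab <- array(0L, dim = c(4, 4, 4))
  lab[1:2, 1:2, ] <- 1L
  lab[1:2, 3:4, ] <- 2L
  lab[3:4, 1:2, ] <- 3L
  lab[3:4, 3:4, ] <- 4L
  lut <- tibble::tibble(
    roi_id = 1:4,
    name = paste0("r", 1:4),
    hemisphere = c("left", "left", "right", "right")
  )
  new_atlas(new_volume(lab, voxel_size = voxel_size, kind = "label"), lut)
}

# binary mask volume from voxel index set on a given grid
mask_from_indices <- function(idx, dim3 = c(4, 4, 4), voxel_size = c(2, 2, 2)) {
  m <- array(0, dim = dim3)
  m[idx] <- 1
  new_volume(m, voxel_size = voxel_size, kind = "binary")
}

# deterministic 4D BOLD on the tiny grid
tiny_bold <- function(n_frames = 20, seed = 1, dim3 = c(4, 4, 4),
                      voxel_size = c(2, 2, 2)) {
  set.seed(seed)
  new_volume(array(rnorm(prod(dim3) * n_frames), dim = c(dim3, n_frames)),
             voxel_size = voxel_size, kind = "float")
}

# valid minimal cohort table (2 patients + 2 controls)
tiny_cohort_df <- function() {
  base <- tibble::tibble(
    subject_id = c("P1", "P2", "C1", "C2"),
    group = c("patient", "patient", "control", "control"),
    age = c(40, 52, 44, 49),
    lesion_side = c("left", "right", "none", "none"),
    tumor_volume = c(35, 80, NA, NA)
  )
  for (col in paste(rep(cognitive_measures()$measure, each = 2),
                    c("initial", "followup"), sep = "_")) {
    base[[col]] <- rnorm(4, 50, 5)
  }
  base
}

# Fisher-z matrix wrapper from an explicit symmetric matrix
fc_from_matrix <- function(z, node_ids) {
  diag(z) <- NA_real_
  structure(list(z = z, node_ids = as.integer(node_ids),
                 has_tumor_node = any(node_ids == TUMOR_NODE)),
            class = "lc_fc")
}

# enumeration oracle: mean z over unordered pairs within a node subset
pair_mean_oracle <- function(z, idx) {
  vals <- c()
  for (i in idx) for (j in idx) if (i < j) vals <- c(vals, z[i, j])
  mean(vals)
}

# columns with an exact given sample correlation
columns_with_exact_r <- function(r, n = 50, seed = 3) {
  set.seed(seed)
  x <- scale(rnorm(n))[, 1]
  e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
  cbind(x, r * x + sqrt(1 - r^2) * e)
}
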