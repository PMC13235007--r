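# Small in-code fixtures shared across test files.

# volume with given 3D mask and intensities (defaults to standard normal)
toy_volume <- function(dims = c(12L, 12L, 3L), mask = NULL, intensities = NULL,
                       spacing = c(1, 1, 1), seed = 42) {
  set.seed(seed)
  if (is.null(mask)) {
    mask <- array(FALSE, dims)
    mask[3:10, 3:10, 2] <- TRUE
  }
  if (is.null(intensities)) intensities <- array(rnorm(prod(dims)), dims)
  tumor_volume(intensities, spacing, mask, patient_id = "toy")
}

# an analysis_slice built directly from a 2D matrix + mask
toy_slice <- function(values, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  structure(list(intensities = values, mask = mask,
                 slice_index = 1L, patient_id = "toy"),
            class = "analysis_slice")
}

# write a NIfTI image/mask pair for CLI tests; returns the two paths
write_nifti_case <- function(dir, id, intensities, mask, spacing = c(1, 1, 1)) {
  vol <- tumor_volume(intensities, spacing, mask, patient_id = id)
  img <- file.path(dir, paste0(id, "_img.nii.gz"))
  msk <- file.path(dir, paste0(id, "_mask.nii.gz"))
  write_case(vol, img, msk)
  c(image = img, mask = msk)
}
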