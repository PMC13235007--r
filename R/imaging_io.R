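#' Construct a tumor volume
#'
#' Container for one case: a 3D intensity grid, its voxel spacing in mm,
#' a binary tumor mask on the same grid, and provenance identifiers.
#'
#' @param intensities Numeric 3D array (arbitrary MR units).
#' @param spacing Numeric length-3 vector, mm per voxel along each axis.
#' @param mask Logical 3D array, same dimensions as `intensities`.
#' @param patient_id,site Character identifiers.
#' @return An object of class `tumor_volume`.
#' @export
tumor_volume <- function(intensities, spacing, mask,
                         patient_id = "unknown", site = "unknown") {
  intensities <- as_array3d(intensities)
  mask <- as_array3d(mask)
  if (!identical(dim(intensities), dim(mask)))
    ith_format_error(sprintf(
      "image shape (%s) and mask shape (%s) differ",
      paste(dim(intensities), collapse = "x"),
      paste(dim(mask), collapse = "x")))
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    ith_parameter_error("spacing must be 3 positive finite values (mm)")
  storage.mode(mask) <- "logical"
  structure(
    list(intensities = intensities, spacing = as.numeric(spacing),
         mask = mask, patient_id = as.character(patient_id),
         site = as.character(site)),
    class = "tumor_volume")
}

#' @exportS3Method base::print
print.tumor_volume <- function(x, ...) {
  cat(sprintf("tumor_volume '%s' (site %s): %s grid, spacing %s mm, %d ROI voxels\n",
              x$patient_id, x$site, paste(dim(x$intensities), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), sum(x$mask)))
  invisible(x)
}

as_array3d <- function(a) {
  a <- unclass(a)
  d <- dim(a)
  if (is.null(d)) ith_format_error("expected an array, got a vector")
  if (length(d) == 2) dim(a) <- c(d, 1L)
  if (length(dim(a)) != 3) ith_format_error("expected a 2D or 3D array")
  a
}

#' Read one case from a NIfTI image/mask pair
#'
#' Voxel spacing is taken from the image header; the mask is binarized at
#' `> 0`. Image and mask must share the same grid.
#'
#' @param image_path,mask_path Paths to NIfTI (.nii/.nii.gz) files.
#' @param patient_id,site Provenance identifiers stored on the volume.
#' @return A [tumor_volume()].
#' @export
read_case <- function(image_path, mask_path,
                      patient_id = "unknown", site = "unknown") {
  img <- tryCatch(RNifti::readNifti(image_path),
                  error = function(e) ith_io_error(
                    sprintf("cannot read image '%s': %s", image_path,
                            conditionMessage(e))))
  msk <- tryCatch(RNifti::readNifti(mask_path),
                  error = function(e) ith_io_error(
                    sprintf("cannot read mask '%s': %s", mask_path,
                            conditionMessage(e))))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  ia <- as_array3d(as.array(img))
  ma <- as_array3d(as.array(msk))
  if (!identical(dim(ia), dim(ma)))
    ith_format_error(sprintf(
      "image shape (%s) and mask shape (%s) differ",
      paste(dim(ia), collapse = "x"), paste(dim(ma), collapse = "x")))
  if (length(sp) < 3 || any(is.na(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  tumor_volume(ia, sp, ma > 0, patient_id = patient_id, site = site)
}

#' Write a case to NIfTI files
#'
#' @param vol A [tumor_volume()].
#' @param image_path,mask_path Output paths (.nii.gz recommended).
#' @return Invisibly, the two paths.
#' @export
write_case <- function(vol, image_path, mask_path) {
  stopifnot(inherits(vol, "tumor_volume"))
  img <- RNifti::asNifti(vol$intensities)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, image_path)
  msk <- RNifti::asNifti(array(as.integer(vol$mask), dim(vol$mask)))
  RNifti::pixdim(msk) <- vol$spacing
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image = image_path, mask = mask_path))
}

resample_axis_linear <- function(arr, axis, src_sp, target) {
  d <- dim(arr)
  n <- d[axis]
  new_n <- max(1L, as.integer(round(n * src_sp / target)))
  src_pos <- (seq_len(n) - 1) * src_sp
  out_pos <- (seq_len(new_n) - 1) * target
  others <- setdiff(1:3, axis)
  if (n == 1L) {
    # constant along a degenerate axis
    idx <- rep(1L, new_n)
    return(index_axis(arr, axis, idx))
  }
  res <- apply(arr, others, function(v)
    approx(src_pos, v, xout = out_pos, rule = 2)$y)
  dim(res) <- c(new_n, d[others])
  aperm(res, order(c(axis, others)))
}

index_axis <- function(arr, axis, idx) {
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

#' Resample a volume to an isotropic grid
#'
#' Intensities are interpolated linearly (separably per axis); the mask is
#' resampled with nearest-neighbor lookup and re-binarized. Output axis
#' lengths are `round(n * spacing / target)` (minimum 1).
#'
#' @param vol A [tumor_volume()].
#' @param target_mm Target isotropic voxel size in mm (default 1).
#' @return A resampled [tumor_volume()] with spacing `rep(target_mm, 3)`.
#' @export
resample_isotropic <- function(vol, target_mm = 1.0) {
  stopifnot(inherits(vol, "tumor_volume"))
  if (!is.numeric(target_mm) || length(target_mm) != 1 ||
      !is.finite(target_mm) || target_mm <= 0)
    ith_parameter_error("target_mm must be a positive number")
  if (all(abs(vol$spacing - target_mm) < 1e-12)) return(vol)
  ints <- vol$intensities
  for (ax in 1:3) ints <- resample_axis_linear(ints, ax, vol$spacing[ax], target_mm)
  nn_idx <- lapply(1:3, function(ax) {
    n <- dim(vol$mask)[ax]
    new_n <- max(1L, as.integer(round(n * vol$spacing[ax] / target_mm)))
    pos <- (seq_len(new_n) - 1) * target_mm
    pmin(n, pmax(1L, as.integer(round(pos / vol$spacing[ax])) + 1L))
  })
  msk <- vol$mask[nn_idx[[1]], nn_idx[[2]], nn_idx[[3]], drop = FALSE]
  tumor_volume(ints, rep(target_mm, 3), msk,
               patient_id = vol$patient_id, site = vol$site)
}

#' Keep only the index lesion (largest connected component)
#'
#' Replaces the mask by its largest 26-connected 3D component. Equal-sized
#' components are resolved toward the one first encountered in linear scan
#' order, which is deterministic.
#'
#' @param vol A [tumor_volume()].
#' @param connectivity 3D connectivity code: 8 (26-neighborhood, default)
#'   or 4 (6-neighborhood).
#' @return The volume with a single-component mask.
#' @export
select_index_lesion <- function(vol, connectivity = 8) {
  stopifnot(inherits(vol, "tumor_volume"))
  if (!any(vol$mask)) ith_empty_roi_error("mask has no foreground voxels")
  comp <- .cc_label_cpp(array(as.integer(vol$mask), dim(vol$mask)),
                        dim(vol$mask), as.integer(connectivity))
  sizes <- tabulate(comp[comp > 0L])
  # which.max takes the first maximum: lowest region id = earliest in scan
  keep <- which.max(sizes)
  vol$mask <- array(comp == keep, dim(vol$mask))
  vol
}

#' Z-score intensities over the ROI
#'
#' Voxels inside the mask are centered and scaled to unit population
#' standard deviation (computed over ROI voxels); voxels outside the mask
#' are set to 0.
#'
#' @param vol A [tumor_volume()].
#' @return The normalized volume.
#' @export
normalize_roi <- function(vol) {
  stopifnot(inherits(vol, "tumor_volume"))
  if (!any(vol$mask)) ith_empty_roi_error("mask has no foreground voxels")
  v <- vol$intensities[vol$mask]
  if (length(v) < 2)
    ith_degenerate_roi_error("ROI has fewer than 2 voxels")
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))   # population sd
  if (!is.finite(s) || s <= 0)
    ith_degenerate_roi_error("ROI intensity variance is zero")
  out <- array(0, dim(vol$intensities))
  out[vol$mask] <- (v - m) / s
  vol$intensities <- out
  vol
}
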