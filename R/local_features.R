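#' Pick the analysis slice
#'
#' Returns the axial slice (third axis) with the largest ROI pixel count;
#' ties go to the lowest slice index.
#'
#' @param vol A [tumor_volume()].
#' @return An object of class `analysis_slice` with fields `intensities`
#'   (2D), `mask` (2D), `slice_index`, `patient_id`.
#' @export
pick_analysis_slice <- function(vol) {
  stopifnot(inherits(vol, "tumor_volume"))
  counts <- apply(vol$mask, 3, sum)
  if (sum(counts) == 0) ith_empty_roi_error("mask has no foreground voxels")
  z <- which.max(counts)   # first maximum = lowest index on ties
  structure(
    list(intensities = vol$intensities[, , z],
         mask = vol$mask[, , z],
         slice_index = as.integer(z),
         patient_id = vol$patient_id),
    class = "analysis_slice")
}

#' @exportS3Method base::print
print.analysis_slice <- function(x, ...) {
  cat(sprintf("analysis_slice '%s': slice %d, %s grid, %d ROI pixels\n",
              x$patient_id, x$slice_index,
              paste(dim(x$intensities), collapse = "x"), sum(x$mask)))
  invisible(x)
}

# Equal-width quantization of ROI intensities into 1..nlevels over the
# slice's ROI range; the top edge maps to nlevels. Shift-invariant by
# construction. Zero range puts everything in level 1.
quantize_slice <- function(intensities, mask, nlevels = 8L) {
  q <- array(1L, dim(intensities))
  v <- intensities[mask]
  rng <- range(v)
  if (diff(rng) > 0) {
    lev <- floor((v - rng[1]) / diff(rng) * nlevels) + 1L
    q[mask] <- pmin(as.integer(lev), as.integer(nlevels))
  }
  q
}

#' Extract local features with a sliding window
#'
#' For every ROI pixel a `window` x `window` neighborhood is intersected
#' with the ROI and summarized by six first-order statistics (mean,
#' standard deviation, skewness, kurtosis, energy, entropy) and four
#' gray-level co-occurrence features (contrast, homogeneity, angular
#' second moment, correlation). Co-occurrence uses `nlevels` equal-width
#' gray levels over the slice's ROI range, symmetric pairs at distance 1
#' pooled over the four 2D directions. Windows covering fewer than 3 ROI
#' pixels inherit the feature vector of the nearest (Euclidean) valid ROI
#' pixel so the map keeps one row per ROI pixel.
#'
#' @param slice An [pick_analysis_slice()] result (expected normalized:
#'   ROI standard deviation near 1; deviations > 0.1 trigger a warning).
#' @param window Odd window edge length in pixels (>= 3); on a 1 mm grid
#'   the default 3 corresponds to a 3 x 3 mm window.
#' @param nlevels Number of gray levels for quantization (default 8).
#' @return An object of class `local_feature_map`: `coords` (ROI pixel
#'   positions, row-major order), `features` (one row per ROI pixel),
#'   `feature_names`.
#' @export
extract_local_features <- function(slice, window = 3L, nlevels = 8L) {
  stopifnot(inherits(slice, "analysis_slice"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    ith_parameter_error("window must be an odd integer >= 3")
  if (!any(slice$mask)) ith_empty_roi_error("slice mask is empty")
  v <- slice$intensities[slice$mask]
  sd_roi <- sqrt(mean((v - mean(v))^2))
  if (abs(sd_roi - 1) > 0.1)
    warning(sprintf("slice '%s' does not look ROI-normalized (sd = %.3f)",
                    slice$patient_id, sd_roi))

  idx <- which(slice$mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])   # canonical row-major scan order
  coords <- idx[ord, , drop = FALSE]
  dimnames(coords) <- list(NULL, c("row", "col"))
  q <- quantize_slice(slice$intensities, slice$mask, nlevels)
  feats <- .window_features_cpp(slice$intensities, slice$mask, q,
                                coords, window, as.integer(nlevels))
  bad <- is.na(feats[, 1])
  if (any(bad)) {
    good <- which(!bad)
    if (length(good) == 0)
      ith_degenerate_roi_error(
        "no window covers 3 or more ROI pixels; ROI too small")
    for (i in which(bad)) {
      d2 <- (coords[good, 1] - coords[i, 1])^2 +
            (coords[good, 2] - coords[i, 2])^2
      feats[i, ] <- feats[good[which.min(d2)], ]
    }
  }
  colnames(feats) <- ith_feature_names()
  structure(
    list(coords = coords, features = feats,
         feature_names = ith_feature_names(),
         patient_id = slice$patient_id, window = window,
         nlevels = as.integer(nlevels)),
    class = "local_feature_map")
}

#' Names of the extracted local features
#' @return Character vector of length 10.
#' @export
ith_feature_names <- function() {
  c("fo_mean", "fo_sd", "fo_skewness", "fo_kurtosis", "fo_energy",
    "fo_entropy", "glcm_contrast", "glcm_homogeneity", "glcm_asm",
    "glcm_correlation")
}

#' Write a feature map to CSV
#'
#' @param fmap A `local_feature_map`.
#' @param path Output CSV path (row, col, then one column per feature).
#' @return Invisibly, `path`.
#' @export
write_feature_map <- function(fmap, path) {
  stopifnot(inherits(fmap, "local_feature_map"))
  df <- data.frame(fmap$coords, fmap$features, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
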