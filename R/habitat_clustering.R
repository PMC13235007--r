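#' Cluster ROI pixels into habitats
#'
#' Column-standardizes the local feature matrix (zero-variance columns
#' dropped), runs k-means with a fixed seed and 10 restarts, and relabels
#' clusters in decreasing size order (label 1 = largest; equal sizes are
#' ordered by first pixel in canonical scan order). Rows are processed in
#' canonical row-major coordinate order so results are independent of the
#' input row ordering. If fewer ROI pixels (or fewer distinct feature
#' vectors) than `k` are available, `k` is reduced with a warning; if all
#' feature columns are constant, every pixel joins a single habitat.
#'
#' @param fmap A `local_feature_map` from [extract_local_features()].
#' @param slice The matching `analysis_slice` (supplies the mask geometry).
#' @param k Number of clusters requested (default 6, sensible range 2-10).
#' @param seed Integer seed controlling the k-means restarts.
#' @return An object of class `habitat_label_map`: `labels` (2D integer
#'   grid, 0 = background, 1..V = habitats), `V`, `patient_id`, `seed`,
#'   `k` (the k actually used).
#' @export
cluster_pixels <- function(fmap, slice, k = 6L, seed = 1L) {
  stopifnot(inherits(fmap, "local_feature_map"),
            inherits(slice, "analysis_slice"))
  npix <- nrow(fmap$features)
  if (npix == 0) ith_empty_roi_error("feature map has no rows")
  if (!all(is.finite(fmap$features)))
    ith_integrity_error("feature matrix contains non-finite entries")
  k <- as.integer(k)
  if (k < 1) ith_parameter_error("k must be >= 1")

  ord <- order(fmap$coords[, 1], fmap$coords[, 2])
  coords <- fmap$coords[ord, , drop = FALSE]
  X <- fmap$features[ord, , drop = FALSE]

  sds <- apply(X, 2, function(col) sqrt(mean((col - mean(col))^2)))
  keep <- sds > 1e-12
  labels_vec <- rep(1L, npix)
  k_used <- 1L
  if (any(keep)) {
    X <- scale(X[, keep, drop = FALSE])
    n_distinct <- nrow(unique(X))
    k_used <- min(k, npix, n_distinct)
    if (k_used < k)
      warning(sprintf("k reduced from %d to %d (pixels or distinct feature vectors)",
                      k, k_used))
    if (k_used > 1L) {
      set.seed(seed)
      km <- tryCatch(
        kmeans(X, centers = k_used, nstart = 10, iter.max = 100),
        error = function(e) {
          # duplicate-heavy data can start Hartigan-Wong on tied centers;
          # MacQueen tolerates empty clusters
          set.seed(seed)
          suppressWarnings(kmeans(X, centers = k_used, nstart = 10,
                                  iter.max = 100, algorithm = "MacQueen"))
        })
      labels_vec <- km$cluster
    }
  }

  sizes <- tabulate(labels_vec, nbins = max(labels_vec))
  first_pix <- vapply(seq_along(sizes), function(l) {
    w <- which(labels_vec == l)
    if (length(w)) w[1] else .Machine$integer.max
  }, integer(1))
  present <- which(sizes > 0)
  ranking <- present[order(-sizes[present], first_pix[present])]
  remap <- integer(length(sizes))
  remap[ranking] <- seq_along(ranking)
  labels_vec <- remap[labels_vec]

  grid <- array(0L, dim(slice$mask))
  grid[cbind(coords[, 1], coords[, 2])] <- labels_vec
  structure(
    list(labels = grid, V = length(ranking),
         patient_id = fmap$patient_id, seed = as.integer(seed),
         k = as.integer(k_used)),
    class = "habitat_label_map")
}

#' @exportS3Method base::print
print.habitat_label_map <- function(x, ...) {
  cat(sprintf("habitat_label_map '%s': %s grid, V = %d habitats (k = %d, seed %d)\n",
              x$patient_id, paste(dim(x$labels), collapse = "x"),
              x$V, x$k, x$seed))
  invisible(x)
}

#' Export a habitat label map
#'
#' Writes the integer label grid as NIfTI and/or a color-mapped PNG for
#' visual inspection of the global habitat distribution pattern.
#'
#' @param labmap A `habitat_label_map`.
#' @param nifti_path,png_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the written paths.
#' @export
write_label_map <- function(labmap, nifti_path = NULL, png_path = NULL) {
  stopifnot(inherits(labmap, "habitat_label_map"))
  written <- character(0)
  if (!is.null(nifti_path)) {
    arr <- array(labmap$labels, c(dim(labmap$labels), 1L))
    img <- RNifti::asNifti(arr)
    RNifti::writeNifti(img, nifti_path)
    written <- c(written, nifti_path)
  }
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 480, height = 480)
    cols <- c("black", grDevices::hcl.colors(max(labmap$V, 2), "Spectral"))
    graphics::image(labmap$labels, col = cols, axes = FALSE, useRaster = TRUE,
                    main = sprintf("%s (V = %d)", labmap$patient_id, labmap$V))
    grDevices::dev.off()
    written <- c(written, png_path)
  }
  invisible(written)
}
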