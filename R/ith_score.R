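#' Connected-region statistics of a habitat label map
#'
#' For each habitat label i in 1..V, computes the number of connected
#' regions `n_i`, the pixel area of the largest region `S_i,max`, and the
#' total pixel area `S_i`, under the chosen pixel connectivity.
#'
#' @param labmap A `habitat_label_map`, or a plain integer label array
#'   (0 = background) for direct use.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal, default).
#' @return An object of class `cluster_region_stats`: a data frame with
#'   columns `cluster`, `n_regions`, `s_max`, `s_i`, plus attributes
#'   `s_total` and `connectivity`.
#' @export
connected_regions <- function(labmap, connectivity = 8) {
  labels <- if (inherits(labmap, "habitat_label_map")) labmap$labels else labmap
  if (is.null(dim(labels))) ith_integrity_error("labels must be an array")
  storage.mode(labels) <- "integer"
  if (any(is.na(labels)) || any(labels < 0L))
    ith_integrity_error("labels must be non-negative integers")
  if (!connectivity %in% c(4, 8))
    ith_parameter_error("connectivity must be 4 or 8")
  V <- max(labels)
  if (inherits(labmap, "habitat_label_map") && V > labmap$V)
    ith_integrity_error(sprintf("labels contain ids above V = %d", labmap$V))
  present <- sort(unique(labels[labels > 0L]))
  if (inherits(labmap, "habitat_label_map") &&
      !identical(present, seq_len(labmap$V)))
    ith_integrity_error("label ids are not exactly 1..V")

  regions <- .cc_label_cpp(labels, dim(labels), as.integer(connectivity))
  reg_ids <- regions[regions > 0L]
  reg_sizes <- tabulate(reg_ids)
  # cluster owning each region: label at the first pixel of the region
  reg_cluster <- integer(length(reg_sizes))
  reg_cluster[reg_ids] <- labels[labels > 0L]

  stats <- data.frame(
    cluster = present,
    n_regions = vapply(present, function(i) sum(reg_cluster == i), integer(1)),
    s_max = vapply(present, function(i) max(reg_sizes[reg_cluster == i]), integer(1)),
    s_i = vapply(present, function(i) sum(reg_sizes[reg_cluster == i]), integer(1)))
  attr(stats, "s_total") <- sum(stats$s_i)
  attr(stats, "connectivity") <- connectivity
  class(stats) <- c("cluster_region_stats", "data.frame")
  stats
}

#' ITH score from connected-region statistics
#'
#' The heterogeneity of a habitat label map is scored as
#' \deqn{ITH = 1 - \frac{1}{S_{total}} \sum_{i=1}^{V} \frac{S_{i,max}}{n_i}}
#' where, for habitat i, \eqn{n_i} is its number of connected regions and
#' \eqn{S_{i,max}} the area of its largest region. A map in which every
#' habitat forms a single connected region scores 0; increasing
#' fragmentation (more, smaller regions) pushes the score toward 1.
#'
#' @param stats A `cluster_region_stats` from [connected_regions()].
#' @param s_total Total ROI pixel area; defaults to the sum recorded in
#'   `stats`. Habitats with zero area are excluded from the sum and from V.
#' @param patient_id Optional provenance id.
#' @return An object of class `ith_result`: `score`, `s_total`, `V`,
#'   `stats`, `patient_id`, `connectivity`.
#' @export
compute_ith <- function(stats, s_total = NULL, patient_id = "unknown") {
  stopifnot(inherits(stats, "cluster_region_stats"))
  conn <- attr(stats, "connectivity")
  stats <- stats[stats$s_i > 0, , drop = FALSE]
  if (is.null(s_total)) s_total <- sum(stats$s_i)
  if (s_total <= 0) ith_empty_roi_error("S_total must be positive")
  if (any(stats$n_regions < 1))
    ith_integrity_error("every habitat must have at least one region")
  if (sum(stats$s_i) != s_total)
    ith_integrity_error("cluster areas do not sum to S_total")
  score <- 1 - sum(stats$s_max / stats$n_regions) / s_total
  structure(
    list(score = score, s_total = as.integer(s_total),
         V = nrow(stats), stats = stats, patient_id = patient_id,
         connectivity = conn),
    class = "ith_result")
}

#' @exportS3Method base::print
print.ith_result <- function(x, ...) {
  conn <- if (is.null(x$connectivity)) NA_integer_ else as.integer(x$connectivity)
  cat(sprintf("ith_result '%s': ITH = %.4f (V = %d habitats, S_total = %d px, %d-connectivity)\n",
              x$patient_id, x$score, x$V, x$s_total, conn))
  invisible(x)
}

#' ITH score of a label map (convenience wrapper)
#'
#' @inheritParams connected_regions
#' @param patient_id Optional provenance id.
#' @return An `ith_result`.
#' @export
ith_score <- function(labmap, connectivity = 8, patient_id = "unknown") {
  if (inherits(labmap, "habitat_label_map") && missing(patient_id))
    patient_id <- labmap$patient_id
  compute_ith(connected_regions(labmap, connectivity),
              patient_id = patient_id)
}

#' Pipeline configuration
#'
#' @param target_mm Isotropic resampling target (mm).
#' @param window Sliding-window edge length in pixels (odd, >= 3).
#' @param nlevels Gray levels for co-occurrence quantization.
#' @param k Requested habitat count for per-tumor k-means.
#' @param seed Clustering seed.
#' @param connectivity Connected-region connectivity (4 or 8).
#' @return A list of class `ith_config`.
#' @export
ith_config <- function(target_mm = 1.0, window = 3L, nlevels = 8L,
                       k = 6L, seed = 1L, connectivity = 8) {
  structure(list(target_mm = target_mm, window = as.integer(window),
                 nlevels = as.integer(nlevels), k = as.integer(k),
                 seed = as.integer(seed), connectivity = connectivity),
            class = "ith_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    if (is.null(e$ith_stage)) {
      e$ith_stage <- stage
      e$message <- sprintf("[%s] %s", stage, conditionMessage(e))
      class(e) <- unique(c("ith_stage_error", class(e)))
    }
    stop(e)
  })
}

#' Run the full ITH pipeline on one case
#'
#' Composes index-lesion selection, isotropic resampling, ROI
#' normalization, analysis-slice selection, local feature extraction,
#' habitat clustering, and connected-region ITH scoring. Errors carry the
#' failing stage name in their message and `ith_stage` field.
#'
#' @param vol A [tumor_volume()].
#' @param config An [ith_config()].
#' @param keep_intermediates If `TRUE`, attach the label map and feature
#'   map to the result (for inspection/plots).
#' @return An `ith_result`, with fields `k`, `seed` and optionally
#'   `label_map`/`feature_map` appended.
#' @export
ith_pipeline <- function(vol, config = ith_config(), keep_intermediates = FALSE) {
  stopifnot(inherits(vol, "tumor_volume"))
  vol  <- run_stage("select_index_lesion", select_index_lesion(vol))
  vol  <- run_stage("resample_isotropic",
                    resample_isotropic(vol, config$target_mm))
  vol  <- run_stage("normalize_roi", normalize_roi(vol))
  sl   <- run_stage("pick_analysis_slice", pick_analysis_slice(vol))
  fmap <- run_stage("extract_local_features",
                    extract_local_features(sl, config$window, config$nlevels))
  lmap <- run_stage("cluster_pixels",
                    cluster_pixels(fmap, sl, config$k, config$seed))
  res  <- run_stage("ith_score", ith_score(lmap, config$connectivity))
  res$k <- lmap$k
  res$seed <- config$seed
  res$slice_index <- sl$slice_index
  if (keep_intermediates) {
    res$label_map <- lmap
    res$feature_map <- fmap
  }
  res
}
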