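# --- Spot-intensity histograms and multimeric RNA cluster calling ---

#' Spot-intensity frequency histogram
#'
#' Counts per half-open bin `[edge, edge + width)`, first edge at 0.
#'
#' @param spots Data frame with an `intensity` column (>= 1 row).
#' @param bin_width Bin width, a.u. (> 0).
#' @return Data frame `bin_start`, `bin_end`, `count`; counts sum to the
#'   number of spots.
#' @export
intensity_histogram <- function(spots, bin_width) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (nrow(spots) == 0) stop("need at least one spot")
  bin <- floor(spots$intensity / bin_width)
  tab <- table(bin)
  b <- as.numeric(names(tab))
  all_b <- 0:max(b)
  counts <- integer(length(all_b))
  counts[match(b, all_b)] <- as.integer(tab)
  data.frame(
    bin_start = all_b * bin_width,
    bin_end = (all_b + 1) * bin_width,
    count = counts
  )
}

#' Call multimeric clusters by intensity threshold
#'
#' A spot is a cluster when its intensity strictly exceeds `threshold`.
#' Multiplicity is estimated against the single-molecule reference
#' intensity: `max(1, round(intensity / reference_intensity))`.
#'
#' @param spots Spot data frame with `intensity`.
#' @param threshold Intensity cut, a.u. (> 0).
#' @param reference_intensity Mean single-molecule intensity, a.u.
#' @return `spots` with `is_cluster` and `estimated_multiplicity` columns.
#' @export
call_clusters <- function(spots, threshold, reference_intensity) {
  if (threshold <= 0) stop("threshold must be > 0")
  spots$is_cluster <- spots$intensity > threshold
  spots$estimated_multiplicity <-
    pmax(1L, as.integer(round(spots$intensity / reference_intensity)))
  spots
}

#' Calibrate a cluster-calling threshold from single-molecule intensities
#'
#' Locates the single-molecule intensity peak as the argmax of a Gaussian
#' kernel density estimate and places the threshold at `k` times the peak
#' position (default `k = 3`), between the single-molecule peak and the
#' multimer tail. With a multimodal density, the lowest mode is used with a
#' warning.
#'
#' @param intensities Sample of spot intensities (length >= 20).
#' @param k Multiplier applied to the single-molecule mode.
#' @return Threshold, a.u. Attribute `mode` carries the peak position.
#' @export
calibrate_threshold <- function(intensities, k = 3) {
  if (length(intensities) < 20) stop("need at least 20 intensities")
  if (k <= 0) stop("k must be > 0")
  d <- stats::density(intensities)
  # interior local maxima of the density curve
  y <- d$y
  is_mode <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_mode) == 0) is_mode <- which.max(y)
  if (length(is_mode) > 1) {
    warning("multimodal intensity density; using the lowest mode")
    is_mode <- is_mode[1L]
  }
  mode_x <- d$x[is_mode]
  structure(k * mode_x, mode = mode_x)
}

#' Per-cell cluster frequency
#'
#' @param calls Output of [call_clusters()] with a `cell_id` column.
#' @return A list with `per_cell` (data frame `cell_id`, `n_spots`,
#'   `n_clusters`, `n_singles`) and `cohort` (mean clusters per cell with
#'   standard error).
#' @export
cluster_frequency <- function(calls) {
  if (!"cell_id" %in% names(calls)) stop("calls need a cell_id column")
  per <- split(calls, calls$cell_id)
  per_cell <- do.call(rbind, lapply(per, function(d) {
    data.frame(
      cell_id = d$cell_id[1],
      n_spots = nrow(d),
      n_clusters = sum(d$is_cluster),
      n_singles = sum(!d$is_cluster)
    )
  }))
  rownames(per_cell) <- NULL
  x <- per_cell$n_clusters
  cohort <- data.frame(
    mean_clusters_per_cell = mean(x),
    se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
    n_cells = length(x)
  )
  list(per_cell = per_cell, cohort = cohort)
}
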