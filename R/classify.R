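# --- Duration filtering and long/directed vs short/diffuse classification ---

#' Filter tracks by duration
#'
#' Retains tracks whose duration (time from first to last spot) strictly
#' exceeds `min_duration`.
#'
#' @param tracks Long-format track data frame.
#' @param min_duration Duration threshold, s.
#' @param frame_interval Frame interval, s.
#' @return The filtered track data frame.
#' @export
filter_by_duration <- function(tracks, min_duration, frame_interval) {
  per <- split_tracks(tracks)
  keep <- vapply(per, function(tr) {
    track_duration(tr, frame_interval) > min_duration
  }, logical(1))
  ids <- as.numeric(names(keep))[keep]
  tracks[tracks$track_id %in% ids, , drop = FALSE]
}

#' Minimum frame count implied by a duration filter
#'
#' The smallest integer number of consecutive frames consistent with a track
#' lasting more than `min_duration` at the given frame rate:
#' `ceiling(min_duration * frame_rate)`, plus one when the product is an
#' integer (strict inequality). At 2.5 s and 6.66 fps this gives 17 frames.
#'
#' @param min_duration Duration threshold, s.
#' @param frame_rate Acquisition rate, frames/s.
#' @return Integer frame count.
#' @export
min_frames <- function(min_duration, frame_rate) {
  if (min_duration <= 0 || frame_rate <= 0) {
    stop("min_duration and frame_rate must be > 0")
  }
  prod <- min_duration * frame_rate
  n <- ceiling(prod)
  if (abs(prod - round(prod)) < 1e-9) n <- n + 1
  as.integer(n)
}

#' Classify tracks as long/directed or short/diffuse
#'
#' A track is long/directed when its net displacement and its linearity of
#' forward progression both strictly exceed their thresholds (defaults:
#' displacement > 4 µm and linearity > 0.7); otherwise short/diffuse.
#' Boundary ties resolve to short/diffuse.
#'
#' @param metrics Per-track metrics from [track_metrics()].
#' @param thresholds A [classifier_thresholds()] object.
#' @return `metrics` with a `motion_class` column
#'   (`"long_directed"`/`"short_diffuse"`).
#' @export
classify_tracks <- function(metrics, thresholds = classifier_thresholds()) {
  stopifnot(inherits(thresholds, "classifier_thresholds"))
  directed <- metrics$displacement_um > thresholds$min_displacement &
    metrics$linearity > thresholds$min_linearity
  metrics$motion_class <- ifelse(directed, "long_directed", "short_diffuse")
  metrics
}

#' Percentage of long/directed tracks
#'
#' @param classified Output of [classify_tracks()] (non-empty).
#' @return Percent of tracks classified long/directed.
#' @export
directed_fraction <- function(classified) {
  if (nrow(classified) == 0) stop("no tracks: directed fraction undefined")
  100 * mean(classified$motion_class == "long_directed")
}

#' Per-cell summary of directed-track frequency
#'
#' @param classified Output of [classify_tracks()] with a `cell_id` column.
#' @return Data frame `cell_id`, `n_tracks`, `n_directed`, `pct_directed`.
#' @export
directed_fraction_per_cell <- function(classified) {
  if (!"cell_id" %in% names(classified)) stop("classified needs a cell_id column")
  per <- split(classified, classified$cell_id)
  res <- do.call(rbind, lapply(per, function(d) {
    data.frame(
      cell_id = d$cell_id[1],
      n_tracks = nrow(d),
      n_directed = sum(d$motion_class == "long_directed"),
      pct_directed = 100 * mean(d$motion_class == "long_directed")
    )
  }))
  rownames(res) <- NULL
  res
}

#' Derive classification thresholds from a control population
#'
#' Sets the displacement and linearity thresholds from the track metrics of
#' a microtubule-depolymerized (nocodazole-like) control so that at most a
#' `target_fpr` fraction of control tracks would classify as directed.
#' Thresholds are marginal: for each metric the threshold is the smallest
#' control value `t` such that at most `floor(target_fpr * n)` control
#' tracks strictly exceed `t` (with `target_fpr = 0` this is the control
#' maximum). Since a directed call requires exceeding both thresholds, the
#' joint control false-positive rate is also at most `target_fpr`.
#'
#' @param control_metrics Metrics of duration-filtered control tracks.
#' @param target_fpr Tolerated control false-positive proportion, in
#'   `[0, 1)`.
#' @param min_duration Duration threshold carried into the result, s.
#' @return A [classifier_thresholds()] object.
#' @export
derive_thresholds <- function(control_metrics, target_fpr = 0,
                              min_duration = 2.5) {
  if (nrow(control_metrics) == 0) stop("control set is empty")
  if (target_fpr < 0 || target_fpr >= 1) stop("target_fpr must be in [0, 1)")
  n <- nrow(control_metrics)
  allow <- floor(target_fpr * n)
  upper_q <- function(x) {
    s <- sort(x, decreasing = TRUE)
    s[allow + 1L] # at most `allow` values strictly exceed this
  }
  disp <- upper_q(control_metrics$displacement_um)
  lin <- upper_q(control_metrics$linearity)
  if (stats::sd(control_metrics$displacement_um) == 0 ||
      stats::sd(control_metrics$linearity) == 0) {
    warning("degenerate control distribution; using default thresholds")
    return(classifier_thresholds(min_duration = min_duration))
  }
  classifier_thresholds(
    min_duration = min_duration,
    min_displacement = disp,
    min_linearity = min(lin, 1)
  )
}
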