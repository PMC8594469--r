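# --- Spot linking and per-track motion metrics ---

# Split a track data frame into per-track data frames ordered by frame.
split_tracks <- function(tracks) {
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  split(tracks, tracks$track_id)
}

#' Link spots across frames into tracks
#'
#' Greedy global-nearest-neighbour linking: for every frame, candidate links
#' between open track heads and new spots are sorted by ascending distance
#' (ties by track id) and accepted one by one, each spot and each track used
#' at most once. Links beyond `max_link_dist` are forbidden. A track stays
#' open for up to `max_gap` missed frames; closed gaps are filled with
#' linearly interpolated virtual spots flagged `interpolated = TRUE`.
#' Spots never linked to anything do not form tracks.
#'
#' @param spots Data frame with `frame` (0-based), `x_um`, `y_um` and
#'   optionally `intensity`, `channel`.
#' @param max_link_dist Maximum per-link distance, µm (> 0).
#' @param max_gap Maximum number of missed frames bridged (>= 0).
#' @return A track data frame (`track_id`, `frame`, `t_s` absent — add via
#'   `frame * frame_interval` — `x_um`, `y_um`, `intensity`, `interpolated`).
#' @export
link_spots <- function(spots, max_link_dist, max_gap = 0L) {
  if (max_link_dist <= 0) stop("max_link_dist must be > 0")
  max_gap <- as.integer(max_gap)
  if (max_gap < 0L) stop("max_gap must be >= 0")
  if (!all(c("frame", "x_um", "y_um") %in% names(spots))) {
    stop("spots must have columns frame, x_um, y_um")
  }
  has_int <- "intensity" %in% names(spots)
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  # open tracks: list of lists with fields id, rows (indices into spots),
  # last_frame, last_x, last_y
  open <- list()
  done <- list()
  next_id <- 1L
  for (f in frames) {
    idx <- which(spots$frame == f)
    # retire tracks whose gap budget is exhausted
    if (length(open)) {
      last <- vapply(open, function(tr) tr$last_frame, numeric(1))
      expired <- which(f - last > max_gap + 1L)
      if (length(expired)) {
        done <- c(done, open[expired])
        open <- open[-expired]
      }
    }
    assigned_spot <- rep(FALSE, length(idx))
    assigned_track <- rep(FALSE, length(open))
    if (length(open) && length(idx)) {
      dx <- outer(vapply(open, `[[`, numeric(1), "last_x"), spots$x_um[idx], "-")
      dy <- outer(vapply(open, `[[`, numeric(1), "last_y"), spots$y_um[idx], "-")
      dmat <- sqrt(dx * dx + dy * dy)
      cand <- which(dmat <= max_link_dist, arr.ind = TRUE)
      if (nrow(cand)) {
        ids <- vapply(open, `[[`, integer(1), "id")
        ord <- order(dmat[cand], ids[cand[, 1]], cand[, 2])
        for (k in ord) {
          ti <- cand[k, 1]
          si <- cand[k, 2]
          if (assigned_track[ti] || assigned_spot[si]) next
          assigned_track[ti] <- TRUE
          assigned_spot[si] <- TRUE
          open[[ti]]$rows <- c(open[[ti]]$rows, idx[si])
          open[[ti]]$last_frame <- f
          open[[ti]]$last_x <- spots$x_um[idx[si]]
          open[[ti]]$last_y <- spots$y_um[idx[si]]
        }
      }
    }
    # unassigned spots open new tracks
    for (si in which(!assigned_spot)) {
      open[[length(open) + 1L]] <- list(
        id = next_id, rows = idx[si], last_frame = f,
        last_x = spots$x_um[idx[si]], last_y = spots$y_um[idx[si]]
      )
      next_id <- next_id + 1L
    }
  }
  done <- c(done, open)
  done <- done[vapply(done, function(tr) length(tr$rows) >= 2L, logical(1))]
  if (!length(done)) {
    return(data.frame(track_id = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      intensity = numeric(0), interpolated = logical(0)))
  }
  done <- done[order(vapply(done, `[[`, integer(1), "id"))]
  out <- vector("list", length(done))
  for (i in seq_along(done)) {
    tr <- done[[i]]
    df <- data.frame(
      track_id = i,
      frame = as.integer(spots$frame[tr$rows]),
      x_um = spots$x_um[tr$rows],
      y_um = spots$y_um[tr$rows],
      intensity = if (has_int) spots$intensity[tr$rows] else NA_real_,
      interpolated = FALSE
    )
    # close gaps with linearly interpolated virtual spots
    gaps <- which(diff(df$frame) > 1L)
    if (length(gaps)) {
      fill <- lapply(gaps, function(g) {
        f0 <- df$frame[g]
        f1 <- df$frame[g + 1L]
        ff <- (f0 + 1L):(f1 - 1L)
        a <- (ff - f0) / (f1 - f0)
        data.frame(
          track_id = i, frame = ff,
          x_um = df$x_um[g] + a * (df$x_um[g + 1L] - df$x_um[g]),
          y_um = df$y_um[g] + a * (df$y_um[g + 1L] - df$y_um[g]),
          intensity = NA_real_, interpolated = TRUE
        )
      })
      df <- rbind(df, do.call(rbind, fill))
      df <- df[order(df$frame), , drop = FALSE]
    }
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Net displacement of a track
#'
#' Euclidean distance from the first to the last spot, µm.
#'
#' @param track Data frame for one track (`frame`, `x_um`, `y_um`).
#' @return Displacement, µm.
#' @export
track_displacement <- function(track) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  sqrt((track$x_um[n] - track$x_um[1])^2 + (track$y_um[n] - track$y_um[1])^2)
}

#' Total path length of a track
#'
#' Sum of inter-spot step lengths, µm.
#'
#' @param track Data frame for one track.
#' @return Path length, µm.
#' @export
track_path_length <- function(track) {
  track <- track[order(track$frame), ]
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Linearity of forward progression
#'
#' Mean straight-line speed (net displacement / track time) divided by mean
#' speed (path length / track time); algebraically equal to
#' displacement / path length. A stationary particle (zero path length) is
#' assigned linearity 0.
#'
#' @param track Data frame for one track.
#' @return Linearity in `[0, 1]`.
#' @export
track_linearity <- function(track) {
  p <- track_path_length(track)
  if (p == 0) {
    message("zero path length: linearity defined as 0")
    return(0)
  }
  track_displacement(track) / p
}

#' Mean speed of a track
#'
#' Path length divided by track duration.
#'
#' @param track Data frame for one track.
#' @param frame_interval Frame interval, s.
#' @return Mean speed, µm/s.
#' @export
mean_speed <- function(track, frame_interval) {
  d <- track_duration(track, frame_interval)
  if (d <= 0) stop("track duration must be > 0")
  track_path_length(track) / d
}

#' Duration of a track
#'
#' Time from the first to the last spot, s.
#'
#' @param track Data frame for one track.
#' @param frame_interval Frame interval, s.
#' @return Duration, s.
#' @export
track_duration <- function(track, frame_interval) {
  (max(track$frame) - min(track$frame)) * frame_interval
}

#' Time-averaged mean square displacement
#'
#' Overlapping-window estimator: `MSD(tau) = mean_i |r(i+tau) - r(i)|^2`.
#' At the maximal admissible lag (track length - 1) there is a single window
#' and the MSD equals the squared net displacement.
#'
#' @param track Data frame for one track.
#' @param max_lag Largest lag in frames; default: track length - 1.
#' @param frame_interval Frame interval, s, for the `lag_s` column.
#' @return Data frame `lag` (frames), `lag_s`, `msd` (µm²), including lag 0.
#' @export
compute_msd <- function(track, max_lag = NULL, frame_interval = 1) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (is.null(max_lag)) max_lag <- n - 1L
  max_lag <- as.integer(max_lag)
  if (max_lag >= n) stop("max_lag must be < track length")
  msd <- numeric(max_lag + 1L)
  for (tau in seq_len(max_lag)) {
    i <- seq_len(n - tau)
    msd[tau + 1L] <- mean((track$x_um[i + tau] - track$x_um[i])^2 +
                            (track$y_um[i + tau] - track$y_um[i])^2)
  }
  data.frame(lag = 0:max_lag, lag_s = (0:max_lag) * frame_interval, msd = msd)
}

#' Velocity autocorrelation of a track
#'
#' Frame-to-frame velocities `v_i = (r_{i+1} - r_i) / dt`;
#' `VAC(tau) = mean_i(v_i . v_{i+tau}) / mean_i(|v_i|^2)`, so `VAC(0) = 1`.
#' Near zero at all positive lags for Brownian motion, positive for
#' persistent directed motion. An all-zero-velocity track returns zeros with
#' `VAC(0)` defined as 1.
#'
#' @param track Data frame for one track.
#' @param max_lag Largest lag in frames (track must have
#'   >= `max_lag + 2` spots).
#' @param frame_interval Frame interval, s.
#' @param normalize If `FALSE`, return the unnormalized covariance
#'   `mean_i(v_i . v_{i+tau})` (µm²/s²).
#' @return Data frame `lag`, `lag_s`, `vac`.
#' @export
velocity_autocorrelation <- function(track, max_lag, frame_interval = 1,
                                     normalize = TRUE) {
  track <- track[order(track$frame), ]
  n <- nrow(track)
  max_lag <- as.integer(max_lag)
  if (n < max_lag + 2L) stop("track length must be >= max_lag + 2")
  vx <- diff(track$x_um) / frame_interval
  vy <- diff(track$y_um) / frame_interval
  m <- length(vx)
  v2 <- mean(vx^2 + vy^2)
  vac <- numeric(max_lag + 1L)
  for (tau in 0:max_lag) {
    i <- seq_len(m - tau)
    vac[tau + 1L] <- mean(vx[i] * vx[i + tau] + vy[i] * vy[i + tau])
  }
  if (normalize) {
    if (v2 == 0) {
      message("all-zero velocities: VAC set to 0 with VAC(0) = 1")
      vac <- rep(0, max_lag + 1L)
      vac[1L] <- 1
    } else {
      vac <- vac / v2
    }
  }
  data.frame(lag = 0:max_lag, lag_s = (0:max_lag) * frame_interval, vac = vac)
}

#' Per-track motion metrics
#'
#' Computes, for every track in a long-format track table, the metric set
#' used for motion classification: net displacement, path length, linearity
#' of forward progression, mean speed, duration, and the full-lifetime MSD
#' (squared net displacement).
#'
#' @param tracks Long-format track data frame.
#' @param frame_interval Frame interval, s.
#' @return Data frame with one row per track: `track_id`, `n_frames`,
#'   `duration_s`, `displacement_um`, `path_um`, `linearity`,
#'   `mean_speed_um_s`, `msd_max_um2`.
#' @export
track_metrics <- function(tracks, frame_interval) {
  per <- split_tracks(tracks)
  rows <- lapply(per, function(tr) {
    disp <- track_displacement(tr)
    path <- track_path_length(tr)
    dur <- track_duration(tr, frame_interval)
    data.frame(
      track_id = tr$track_id[1],
      n_frames = nrow(tr),
      duration_s = dur,
      displacement_um = disp,
      path_um = path,
      linearity = if (path > 0) disp / path else 0,
      mean_speed_um_s = if (dur > 0) path / dur else 0,
      msd_max_um2 = disp^2
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Ensemble-averaged MSD or VAC curve
#'
#' Averages per-track curves with equal weight per track at each common lag.
#'
#' @param tracks Long-format track data frame.
#' @param max_lag Largest lag in frames.
#' @param frame_interval Frame interval, s.
#' @param what `"msd"` or `"vac"`.
#' @return Data frame `lag`, `lag_s`, `value`, `n_tracks`.
#' @export
ensemble_curve <- function(tracks, max_lag, frame_interval,
                           what = c("msd", "vac")) {
  what <- match.arg(what)
  per <- split_tracks(tracks)
  curves <- lapply(per, function(tr) {
    n <- nrow(tr)
    if (what == "msd") {
      if (n - 1L < max_lag) return(NULL)
      compute_msd(tr, max_lag, frame_interval)$msd
    } else {
      if (n < max_lag + 2L) return(NULL)
      velocity_autocorrelation(tr, max_lag, frame_interval)$vac
    }
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  if (!length(curves)) stop("no track long enough for max_lag = ", max_lag)
  m <- do.call(rbind, curves)
  data.frame(
    lag = 0:max_lag,
    lag_s = (0:max_lag) * frame_interval,
    value = colMeans(m),
    n_tracks = length(curves)
  )
}
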