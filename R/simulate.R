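#' Simulate a single Brownian track
#'
#' Positions follow a 2D random walk: each per-axis step is drawn from
#' `N(0, 2 * D * dt)` so that the ensemble mean square displacement is
#' `4 * D * tau`. Apparent positions carry independent Gaussian localization
#' noise of sd `params$localization_noise`.
#'
#' @param params A [motion_params()] object.
#' @param origin Numeric length-2 start position `(x, y)` in µm.
#' @param seed Integer seed; identical seeds give identical tracks.
#' @param track_id Identifier stored in the output.
#' @return A track data frame with columns `track_id`, `frame` (0-based),
#'   `t_s`, `x_um`, `y_um`.
#' @export
simulate_brownian_track <- function(params, origin = c(0, 0), seed = NULL,
                                    track_id = 1L) {
  stopifnot(inherits(params, "motion_params"))
  n <- params$n_frames
  dt <- params$frame_interval
  with_seed(seed, {
    step_sd <- sqrt(2 * params$diffusion_coefficient * dt)
    x <- origin[1] + cumsum(c(0, stats::rnorm(n - 1L, 0, step_sd)))
    y <- origin[2] + cumsum(c(0, stats::rnorm(n - 1L, 0, step_sd)))
    if (params$localization_noise > 0) {
      x <- x + stats::rnorm(n, 0, params$localization_noise)
      y <- y + stats::rnorm(n, 0, params$localization_noise)
    }
    data.frame(
      track_id = track_id,
      frame = seq_len(n) - 1L,
      t_s = (seq_len(n) - 1L) * dt,
      x_um = x,
      y_um = y
    )
  })
}

#' Simulate a single directed track
#'
#' A constant-speed run: the particle advances `directed_speed * dt` per step
#' along a heading that accumulates Gaussian angular jitter
#' (`direction_jitter` rad/step). No pausing by default; see
#' `pause_prob`/`pause_duration` for an optional two-state run/pause model.
#'
#' @param params A [motion_params()] object with `directed_speed > 0`.
#' @param heading Initial heading, radians (0 = +x).
#' @param origin Numeric length-2 start position in µm.
#' @param seed Integer seed.
#' @param track_id Identifier stored in the output.
#' @param pause_prob Per-step probability of entering a pause (default 0).
#' @param pause_duration Mean pause length in frames (geometric), used only
#'   when `pause_prob > 0`.
#' @return A track data frame (same schema as [simulate_brownian_track()]).
#' @export
simulate_directed_track <- function(params, heading = 0, origin = c(0, 0),
                                    seed = NULL, track_id = 1L,
                                    pause_prob = 0, pause_duration = 3) {
  stopifnot(inherits(params, "motion_params"))
  if (params$directed_speed <= 0) stop("directed_speed must be > 0")
  n <- params$n_frames
  dt <- params$frame_interval
  step_len <- params$directed_speed * dt
  with_seed(seed, {
    theta <- numeric(n - 1L)
    th <- heading
    paused <- logical(n - 1L)
    pause_left <- 0L
    for (k in seq_len(n - 1L)) {
      if (pause_left > 0L) {
        paused[k] <- TRUE
        pause_left <- pause_left - 1L
      } else if (pause_prob > 0 && stats::runif(1) < pause_prob) {
        paused[k] <- TRUE
        pause_left <- stats::rgeom(1, 1 / pause_duration)
      }
      theta[k] <- th
      if (params$direction_jitter > 0) {
        th <- th + stats::rnorm(1, 0, params$direction_jitter)
      }
    }
    dx <- ifelse(paused, 0, step_len * cos(theta))
    dy <- ifelse(paused, 0, step_len * sin(theta))
    x <- origin[1] + cumsum(c(0, dx))
    y <- origin[2] + cumsum(c(0, dy))
    if (params$localization_noise > 0) {
      x <- x + stats::rnorm(n, 0, params$localization_noise)
      y <- y + stats::rnorm(n, 0, params$localization_noise)
    }
    data.frame(
      track_id = track_id,
      frame = seq_len(n) - 1L,
      t_s = (seq_len(n) - 1L) * dt,
      x_um = x,
      y_um = y
    )
  })
}

#' Simulate a mixed particle population
#'
#' Draws `round(directed_fraction * n_tracks)` directed tracks and the rest
#' Brownian, with ground-truth labels. Perturbations follow the drug
#' phenotypes the model emulates: `nocodazole` removes the directed
#' population entirely; `cytochalasinD` and `dmso` change nothing relative to
#' `none` (same RNG stream, so the untreated and actin-disrupted populations
#' are identical at equal seed).
#'
#' Track origins are uniform over a square field of side `field_size_um`.
#' When a `geometry` is supplied, origins are sampled uniformly over its
#' cytoplasm and directed tracks head toward the nearest cell-edge point
#' (anterograde bias); otherwise headings are uniform on the circle.
#'
#' @param params A [motion_params()] object.
#' @param n_tracks Number of tracks (>= 1).
#' @param perturbation A [perturbation()] object (or its kind as a string).
#' @param seed Integer seed.
#' @param field_size_um Side of the square origin field, µm.
#' @param geometry Optional [make_cell_geometry()] object.
#' @return A list with `tracks` (one data frame, `label` column attached) and
#'   `labels` (data frame `track_id`, `label` with levels
#'   `directed`/`diffusive`).
#' @export
simulate_population <- function(params, n_tracks, perturbation = "none",
                                seed = NULL, field_size_um = 30,
                                geometry = NULL) {
  stopifnot(inherits(params, "motion_params"))
  n_tracks <- as.integer(n_tracks)
  if (n_tracks < 1L) stop("n_tracks must be >= 1")
  if (is.character(perturbation)) perturbation <- perturbation(perturbation)
  stopifnot(inherits(perturbation, "perturbation"))
  frac <- params$directed_fraction
  if (perturbation$kind == "nocodazole") frac <- 0
  n_directed <- as.integer(round(frac * n_tracks))

  with_seed(seed, {
    if (is.null(geometry)) {
      ox <- stats::runif(n_tracks, 0, field_size_um)
      oy <- stats::runif(n_tracks, 0, field_size_um)
      headings <- stats::runif(n_tracks, 0, 2 * pi)
    } else {
      pos <- sample_spot_positions(geometry, "uniform", n_tracks, seed = NULL)
      ox <- pos$x_um
      oy <- pos$y_um
      headings <- vapply(seq_len(n_tracks), function(i) {
        edge_heading(geometry, c(ox[i], oy[i]))
      }, numeric(1))
    }
    is_directed <- seq_len(n_tracks) <= n_directed
    tracks <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      tracks[[i]] <- if (is_directed[i]) {
        simulate_directed_track(params, heading = headings[i],
                                origin = c(ox[i], oy[i]), seed = NULL,
                                track_id = i)
      } else {
        simulate_brownian_track(params, origin = c(ox[i], oy[i]), seed = NULL,
                                track_id = i)
      }
    }
    tracks <- do.call(rbind, tracks)
    labels <- data.frame(
      track_id = seq_len(n_tracks),
      label = ifelse(is_directed, "directed", "diffusive")
    )
    tracks$label <- labels$label[match(tracks$track_id, labels$track_id)]
    list(tracks = tracks, labels = labels)
  })
}

# Heading from a point toward the nearest cell-edge pixel of a geometry.
edge_heading <- function(geometry, point) {
  edge <- geometry$edge_um
  d2 <- (edge[, 1] - point[1])^2 + (edge[, 2] - point[2])^2
  k <- which.min(d2)
  atan2(edge[k, 2] - point[2], edge[k, 1] - point[1])
}
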