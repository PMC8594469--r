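#' Construct an image stack
#'
#' A thin container for time-ordered 2D frames with physical calibration.
#'
#' @param frames Numeric array `height x width x n_frames` (a matrix is
#'   treated as a single frame).
#' @param pixel_size Pixel size, µm/px.
#' @param frame_interval Frame interval, s.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, pixel_size > 0, frame_interval > 0)
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("image_stack: %d x %d px, %d frame(s), %.3f um/px, %.4f s/frame\n",
              d[2], d[1], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Maximum-intensity projection of a stack
#'
#' @param stack An [image_stack()].
#' @return A matrix (height x width) of per-pixel maxima across frames.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$frames, c(1, 2), max)
}

# Add one Gaussian emitter (total integrated intensity `total`) to a frame.
# Positions in µm, pixel-center convention; rendered on a +/- 4 sigma window.
add_emitter <- function(frame, x_um, y_um, total, psf_sigma, pixel_size) {
  h <- nrow(frame)
  w <- ncol(frame)
  s <- psf_sigma / pixel_size
  cx <- x_um / pixel_size + 0.5 # pixel-center column coordinate
  cy <- y_um / pixel_size + 0.5
  half <- ceiling(4 * s)
  c0 <- max(1L, floor(cx) - half)
  c1 <- min(w, floor(cx) + half)
  r0 <- max(1L, floor(cy) - half)
  r1 <- min(h, floor(cy) + half)
  if (c0 > c1 || r0 > r1) return(frame)
  cols <- c0:c1
  rows <- r0:r1
  gx <- exp(-((cols - cx)^2) / (2 * s^2))
  gy <- exp(-((rows - cy)^2) / (2 * s^2))
  frame[rows, cols] <- frame[rows, cols] +
    (total / (2 * pi * s^2)) * outer(gy, gx)
  frame
}

#' Render a synthetic image stack
#'
#' Each frame is `background + sum of Gaussian PSFs + Gaussian noise`.
#' Moving emitters come from `tracks` (one PSF per track per frame it
#' occupies); `static_spots` are present in every frame with an integrated
#' intensity of `multiplicity` times a draw from the single-molecule
#' intensity distribution (clipped at 0).
#'
#' @param tracks Track data frame (`track_id`, `frame`, `x_um`, `y_um`) or
#'   `NULL`.
#' @param static_spots Data frame with `x_um`, `y_um` and optionally
#'   `multiplicity` (default 1), or `NULL`.
#' @param geometry A [make_cell_geometry()] giving the raster size and pixel
#'   size.
#' @param render A [render_params()] object.
#' @param n_frames Number of frames; defaults to the track span or 1.
#' @param frame_interval Frame interval, s, stored as calibration.
#' @param seed Integer seed for intensity draws and noise.
#' @return An [image_stack()].
#' @export
render_stack <- function(tracks = NULL, static_spots = NULL, geometry,
                         render = render_params(), n_frames = NULL,
                         frame_interval = 1 / 6.66, seed = NULL) {
  stopifnot(inherits(geometry, "cell_geometry"),
            inherits(render, "render_params"))
  h <- nrow(geometry$cell_mask)
  w <- ncol(geometry$cell_mask)
  if (is.null(n_frames)) {
    n_frames <- if (!is.null(tracks)) max(tracks$frame) + 1L else 1L
  }
  n_frames <- as.integer(n_frames)
  px <- geometry$pixel_size
  xmax <- w * px
  ymax <- h * px
  in_bounds <- function(x, y) all(x >= 0 & x <= xmax & y >= 0 & y <= ymax)
  if (!is.null(tracks) && !in_bounds(tracks$x_um, tracks$y_um)) {
    stop("track positions fall outside the image bounds")
  }
  if (!is.null(static_spots) &&
      !in_bounds(static_spots$x_um, static_spots$y_um)) {
    stop("static spot positions fall outside the image bounds")
  }
  with_seed(seed, {
    draw_intensity <- function(mult) {
      pmax(0, mult * stats::rnorm(length(mult), render$single_molecule_mean,
                                  render$single_molecule_sd))
    }
    static_int <- NULL
    if (!is.null(static_spots)) {
      mult <- if ("multiplicity" %in% names(static_spots)) {
        static_spots$multiplicity
      } else {
        rep(1, nrow(static_spots))
      }
      static_int <- draw_intensity(mult)
    }
    track_int <- NULL
    if (!is.null(tracks)) {
      ids <- sort(unique(tracks$track_id))
      track_int <- stats::setNames(draw_intensity(rep(1, length(ids))),
                                   as.character(ids))
    }
    frames <- array(render$background_level, dim = c(h, w, n_frames))
    for (f in seq_len(n_frames)) {
      fr <- frames[, , f]
      if (!is.null(tracks)) {
        sub <- tracks[tracks$frame == f - 1L, , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
          fr <- add_emitter(fr, sub$x_um[i], sub$y_um[i],
                            track_int[as.character(sub$track_id[i])],
                            render$psf_sigma, px)
        }
      }
      if (!is.null(static_spots)) {
        for (i in seq_len(nrow(static_spots))) {
          fr <- add_emitter(fr, static_spots$x_um[i], static_spots$y_um[i],
                            static_int[i], render$psf_sigma, px)
        }
      }
      if (render$noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(h * w, 0, render$noise_sd), h, w)
        fr[fr < 0] <- 0
      }
      frames[, , f] <- fr
    }
    image_stack(frames, px, frame_interval)
  })
}
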