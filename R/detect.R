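# --- Laplacian-of-Gaussian filtering and local-maximum spot calling ---

# Separable Gaussian smoothing with reflection boundary handling.
gaussian_smooth <- function(image, sigma_px) {
  half <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-half:half)^2) / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(m) {
    # reflect-pad rows, convolve each column with k
    h <- nrow(m)
    idx <- c(rev(seq_len(half) + 1L), seq_len(h), h - seq_len(half))
    pad <- m[idx, , drop = FALSE]
    out <- matrix(0, h, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[(j - 1L) + seq_len(h), , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(image))))
}

# Discrete 5-point Laplacian with reflection at the borders.
laplacian <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  up <- m[c(2L, seq_len(h - 1L)), , drop = FALSE]
  down <- m[c(seq_len(h - 1L) + 1L, h - 1L), , drop = FALSE]
  left <- m[, c(2L, seq_len(w - 1L)), drop = FALSE]
  right <- m[, c(seq_len(w - 1L) + 1L, w - 1L), drop = FALSE]
  up + down + left + right - 4 * m
}

#' Laplacian-of-Gaussian filter for spot enhancement
#'
#' Smooths the image with a Gaussian of scale `sigma` and applies a negated,
#' scale-normalized discrete Laplacian, so that diffraction-limited bright
#' spots become positive peaks. Boundaries are handled by reflection.
#'
#' @param image Numeric matrix (row = y, col = x).
#' @param sigma Filter scale in µm; match to the PSF sigma of the data.
#' @param pixel_size Pixel size, µm/px.
#' @return Filtered matrix of the same dimensions.
#' @export
log_filter <- function(image, sigma, pixel_size) {
  if (!is.matrix(image) || length(image) == 0) stop("image must be a non-empty matrix")
  if (sigma <= 0) stop("sigma must be > 0")
  sigma_px <- sigma / pixel_size
  if (sigma_px > min(dim(image)) / 2) {
    stop("sigma exceeds the image extent")
  }
  -sigma_px^2 * laplacian(gaussian_smooth(image, sigma_px))
}

# Interior local maxima (>= all 8 neighbours) of a matrix, as (row, col).
local_maxima <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  if (h < 3L || w < 3L) return(cbind(row = integer(0), col = integer(0)))
  core <- m[2:(h - 1L), 2:(w - 1L)]
  ok <- matrix(TRUE, h - 2L, w - 2L)
  for (dr in -1:1) {
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      ok <- ok & core >= m[2:(h - 1L) + dr, 2:(w - 1L) + dc]
    }
  }
  idx <- which(ok, arr.ind = TRUE)
  cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
}

# 1D quadratic sub-pixel offset from three samples around a peak; clamped.
quad_offset <- function(fm, f0, fp) {
  den <- fm - 2 * f0 + fp
  if (den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (fm - fp) / den))
}

#' Detect spots in a single frame
#'
#' Calls local maxima of the LoG-filtered image above a threshold, applies
#' non-maximum suppression at `min_separation` (greedy by descending
#' response, ties by lowest row then column), refines positions by 3x3
#' quadratic interpolation, and measures background-subtracted integrated
#' intensities via [measure_spot_intensity()].
#'
#' @param image Numeric matrix.
#' @param params A [detection_params()] object.
#' @param frame_index Frame number stored in the output (0-based).
#' @param pixel_size Pixel size, µm/px.
#' @param channel Channel number stored in the output.
#' @return Data frame with columns `channel`, `frame`, `x_um`, `y_um`,
#'   `x_px`, `y_px`, `intensity`, `response`. Zero rows is a valid result.
#' @export
detect_spots <- function(image, params = detection_params(), frame_index = 0L,
                         pixel_size = 0.16, channel = 1L) {
  stopifnot(inherits(params, "detection_params"))
  filt <- log_filter(image, params$log_sigma, pixel_size)
  thr <- params$threshold
  if (is.null(thr)) {
    # mean + 5 sd of the filtered *background*, estimated robustly so the
    # spots themselves do not inflate the cut
    thr <- stats::median(filt) + 5 * stats::mad(filt)
  }
  empty <- data.frame(channel = integer(0), frame = integer(0),
                      x_um = numeric(0), y_um = numeric(0),
                      x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), response = numeric(0))
  if (!is.finite(thr)) {
    if (thr == -Inf) thr <- -.Machine$double.xmax else return(empty)
  }
  peaks <- local_maxima(filt)
  if (nrow(peaks) == 0) return(empty)
  vals <- filt[peaks]
  keep <- vals > thr
  peaks <- peaks[keep, , drop = FALSE]
  vals <- vals[keep]
  if (nrow(peaks) == 0) return(empty)
  # deterministic order: descending response, then lowest (row, col)
  ord <- order(-vals, peaks[, "row"], peaks[, "col"])
  peaks <- peaks[ord, , drop = FALSE]
  vals <- vals[ord]
  min_sep_px <- params$min_separation / pixel_size
  acc <- matrix(numeric(0), ncol = 2)
  acc_i <- integer(0)
  for (i in seq_len(nrow(peaks))) {
    p <- peaks[i, ]
    if (nrow(acc) == 0 ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= min_sep_px^2) {
      acc <- rbind(acc, p)
      acc_i <- c(acc_i, i)
    }
  }
  n <- length(acc_i)
  x_px <- numeric(n)
  y_px <- numeric(n)
  intensity <- numeric(n)
  h <- nrow(image)
  w <- ncol(image)
  radius_um <- 3 * params$log_sigma
  for (i in seq_len(n)) {
    r <- acc[i, 1]
    cc <- acc[i, 2]
    dy <- quad_offset(filt[r - 1L, cc], filt[r, cc], filt[r + 1L, cc])
    dx <- quad_offset(filt[r, cc - 1L], filt[r, cc], filt[r, cc + 1L])
    x_px[i] <- cc + dx
    y_px[i] <- r + dy
    intensity[i] <- measure_spot_intensity(
      image, c((x_px[i] - 0.5) * pixel_size, (y_px[i] - 0.5) * pixel_size),
      radius = radius_um, pixel_size = pixel_size, clip = TRUE
    )
  }
  out <- data.frame(
    channel = as.integer(channel),
    frame = as.integer(frame_index),
    x_um = (x_px - 0.5) * pixel_size,
    y_um = (y_px - 0.5) * pixel_size,
    x_px = x_px,
    y_px = y_px,
    intensity = intensity,
    response = vals[acc_i]
  )
  out[order(out$y_px, out$x_px), , drop = FALSE]
}

#' Detect spots in every frame of a stack
#'
#' @param stack An [image_stack()].
#' @param params A [detection_params()].
#' @param channel Channel number stored in the output.
#' @return Row-bound [detect_spots()] results over all frames.
#' @export
detect_spots_stack <- function(stack, params = detection_params(),
                               channel = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  res <- lapply(seq_len(dim(stack$frames)[3]), function(f) {
    detect_spots(stack$frames[, , f], params, frame_index = f - 1L,
                 pixel_size = stack$pixel_size, channel = channel)
  })
  do.call(rbind, res)
}

#' Background-subtracted integrated spot intensity
#'
#' Sums pixel intensities in a disc around `position` and subtracts a local
#' background estimated as the median of an annulus from `radius` to
#' `2 * radius`, scaled by the disc area.
#'
#' @param image Numeric matrix.
#' @param position Length-2 `(x, y)` in µm.
#' @param radius Disc radius, µm.
#' @param pixel_size Pixel size, µm/px.
#' @param clip If `TRUE`, clip the disc and annulus at the image border
#'   instead of erroring (used for detections near the edge).
#' @return Integrated intensity, a.u.
#' @export
measure_spot_intensity <- function(image, position, radius,
                                   pixel_size = 0.16, clip = FALSE) {
  h <- nrow(image)
  w <- ncol(image)
  cx <- position[1] / pixel_size + 0.5
  cy <- position[2] / pixel_size + 0.5
  r_px <- radius / pixel_size
  if (!clip && (cx - r_px < 0.5 || cx + r_px > w + 0.5 ||
                cy - r_px < 0.5 || cy + r_px > h + 0.5)) {
    stop("measurement disc extends outside the image")
  }
  half <- ceiling(2 * r_px)
  cols <- max(1L, floor(cx) - half):min(w, floor(cx) + half)
  rows <- max(1L, floor(cy) - half):min(h, floor(cy) + half)
  d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  patch <- image[rows, cols, drop = FALSE]
  disc <- d2 <= r_px^2
  annulus <- d2 > r_px^2 & d2 <= (2 * r_px)^2
  if (!clip && !any(annulus)) stop("annulus is empty")
  bg <- if (any(annulus)) stats::median(patch[annulus]) else 0
  sum(patch[disc]) - bg * sum(disc)
}
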