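# --- Two-channel cotransport detection and kymographs ---

#' Pair motor and mRNA tracks into cotransport events
#'
#' For every pair of tracks (one per channel) sharing at least `min_overlap`
#' common frames with mean per-frame Euclidean distance at most `max_sep`,
#' a candidate event is formed. Candidates are accepted greedily by
#' ascending mean distance; each track joins at most one event.
#'
#' @param tracks_a Track data frame of channel A (motor).
#' @param tracks_b Track data frame of channel B (mRNA).
#' @param max_sep Maximum mean pair distance, µm (default 0.3, about the
#'   diffraction limit).
#' @param min_overlap Minimum number of common frames.
#' @param frame_interval Frame interval, s.
#' @return Data frame of events: `track_a_id`, `track_b_id`,
#'   `overlap_frames`, `overlap_s`, `mean_pair_dist_um`, `distance_um`
#'   (path length of the mRNA track over the overlap), `mean_speed_um_s`.
#' @export
pair_tracks <- function(tracks_a, tracks_b, max_sep = 0.3, min_overlap = 5L,
                        frame_interval = 1 / 7.36) {
  if (max_sep <= 0) stop("max_sep must be > 0")
  min_overlap <- as.integer(min_overlap)
  per_a <- split_tracks(tracks_a)
  per_b <- split_tracks(tracks_b)
  cand <- list()
  for (a in per_a) {
    for (b in per_b) {
      common <- intersect(a$frame, b$frame)
      if (length(common) < min_overlap) next
      ia <- match(common, a$frame)
      ib <- match(common, b$frame)
      d <- sqrt((a$x_um[ia] - b$x_um[ib])^2 + (a$y_um[ia] - b$y_um[ib])^2)
      md <- mean(d)
      if (md > max_sep) next
      ov <- b[ib, , drop = FALSE]
      path <- track_path_length(ov)
      dur <- (max(common) - min(common)) * frame_interval
      cand[[length(cand) + 1L]] <- data.frame(
        track_a_id = a$track_id[1],
        track_b_id = b$track_id[1],
        overlap_frames = length(common),
        overlap_s = dur,
        mean_pair_dist_um = md,
        distance_um = path,
        mean_speed_um_s = if (dur > 0) path / dur else 0
      )
    }
  }
  empty <- data.frame(track_a_id = numeric(0), track_b_id = numeric(0),
                      overlap_frames = integer(0), overlap_s = numeric(0),
                      mean_pair_dist_um = numeric(0), distance_um = numeric(0),
                      mean_speed_um_s = numeric(0))
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$mean_pair_dist_um, cand$track_a_id, cand$track_b_id), ]
  used_a <- used_b <- c()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$track_a_id[i] %in% used_a || cand$track_b_id[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, cand$track_a_id[i])
    used_b <- c(used_b, cand$track_b_id[i])
  }
  res <- cand[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Distance traveled during a cotransport event
#'
#' Path length of the mRNA-channel track over the overlap window.
#'
#' @param event One row of the [pair_tracks()] result.
#' @param tracks_a,tracks_b The channel track tables used for pairing.
#' @return Distance, µm.
#' @export
event_distance <- function(event, tracks_a, tracks_b) {
  a <- tracks_a[tracks_a$track_id == event$track_a_id, , drop = FALSE]
  b <- tracks_b[tracks_b$track_id == event$track_b_id, , drop = FALSE]
  common <- intersect(a$frame, b$frame)
  track_path_length(b[b$frame %in% common, , drop = FALSE])
}

#' Mean speed of a cotransport event
#'
#' Traveled distance divided by the overlap duration.
#'
#' @inheritParams event_distance
#' @param frame_interval Frame interval, s.
#' @return Mean speed, µm/s.
#' @export
event_mean_speed <- function(event, tracks_a, tracks_b,
                             frame_interval = 1 / 7.36) {
  a <- tracks_a[tracks_a$track_id == event$track_a_id, , drop = FALSE]
  b <- tracks_b[tracks_b$track_id == event$track_b_id, , drop = FALSE]
  common <- intersect(a$frame, b$frame)
  dur <- (max(common) - min(common)) * frame_interval
  if (dur <= 0) stop("overlap duration must be > 0")
  event_distance(event, tracks_a, tracks_b) / dur
}

#' Cohort summary of cotransport events
#'
#' Mean and 95% t-interval of traveled distance and mean speed across
#' events.
#'
#' @param events [pair_tracks()] result (>= 1 row).
#' @return Data frame with one row per quantity: `mean`, `ci_lo`, `ci_hi`,
#'   `n`.
#' @export
cotransport_summary <- function(events) {
  if (nrow(events) == 0) stop("no events to summarize")
  one <- function(x, name) {
    tt <- if (length(x) > 1) {
      tryCatch(stats::t.test(x), error = function(e) NULL)
    }
    if (!is.null(tt)) {
      data.frame(quantity = name, mean = mean(x),
                 ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
                 n = length(x))
    } else if (length(x) > 1) {
      data.frame(quantity = name, mean = mean(x), ci_lo = mean(x),
                 ci_hi = mean(x), n = length(x))
    } else {
      data.frame(quantity = name, mean = x, ci_lo = NA_real_,
                 ci_hi = NA_real_, n = 1L)
    }
  }
  rbind(one(events$distance_um, "distance_um"),
        one(events$mean_speed_um_s, "mean_speed_um_s"))
}

# Bilinear interpolation of a frame at (x_um, y_um); 0 outside.
bilinear_at <- function(frame, x_um, y_um, pixel_size) {
  cx <- x_um / pixel_size + 0.5
  cy <- y_um / pixel_size + 0.5
  c0 <- floor(cx)
  r0 <- floor(cy)
  fx <- cx - c0
  fy <- cy - r0
  h <- nrow(frame)
  w <- ncol(frame)
  val <- function(r, cc) {
    ifelse(r >= 1 & r <= h & cc >= 1 & cc <= w,
           frame[cbind(pmin(pmax(r, 1), h), pmin(pmax(cc, 1), w))], 0)
  }
  (1 - fy) * ((1 - fx) * val(r0, c0) + fx * val(r0, c0 + 1)) +
    fy * ((1 - fx) * val(r0 + 1, c0) + fx * val(r0 + 1, c0 + 1))
}

#' Kymograph along a path
#'
#' Samples each frame along a polyline (discretized at one pixel spacing),
#' taking the maximum over `line_width` perpendicular offsets, and stacks
#' the profiles into a position-by-time raster.
#'
#' @param stack An [image_stack()].
#' @param path Two-column matrix or data frame of polyline vertices, µm.
#' @param line_width Width of the sampling line, px (odd values center the
#'   line on the path).
#' @return A list (class `kymograph`) with `image`
#'   (position x time matrix), `positions_um` (distance along the path),
#'   and `path`.
#' @export
kymograph <- function(stack, path, line_width = 3L) {
  stopifnot(inherits(stack, "image_stack"))
  path <- as.matrix(path)
  if (ncol(path) != 2 || nrow(path) < 2) stop("path must be >= 2 points of (x, y)")
  px <- stack$pixel_size
  d <- dim(stack$frames)
  if (any(path[, 1] < 0 | path[, 1] > d[2] * px |
          path[, 2] < 0 | path[, 2] > d[1] * px)) {
    stop("path extends outside the image bounds")
  }
  # discretize the polyline at one-pixel arc-length steps
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  total <- sum(seg_len)
  s <- seq(0, total, by = px)
  cum <- c(0, cumsum(seg_len))
  pts <- matrix(0, length(s), 2)
  tang <- matrix(0, length(s), 2)
  for (i in seq_along(s)) {
    k <- max(which(cum <= s[i] + 1e-12))
    k <- min(k, nrow(seg))
    a <- if (seg_len[k] > 0) (s[i] - cum[k]) / seg_len[k] else 0
    pts[i, ] <- path[k, ] + a * seg[k, ]
    tang[i, ] <- seg[k, ] / max(seg_len[k], 1e-12)
  }
  normal <- cbind(-tang[, 2], tang[, 1])
  offsets <- (seq_len(line_width) - (line_width + 1) / 2) * px
  n_frames <- d[3]
  img <- matrix(0, length(s), n_frames)
  for (f in seq_len(n_frames)) {
    fr <- stack$frames[, , f]
    prof <- rep(-Inf, length(s))
    for (o in offsets) {
      v <- bilinear_at(fr, pts[, 1] + o * normal[, 1],
                       pts[, 2] + o * normal[, 2], px)
      prof <- pmax(prof, v)
    }
    img[, f] <- prof
  }
  structure(list(image = img, positions_um = s, path = path),
            class = "kymograph")
}
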