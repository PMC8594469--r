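#' Generate a synthetic cell/nucleus geometry
#'
#' Builds binary cell and nucleus masks on a pixel raster. The cell boundary
#' is a star-shaped polygon whose radius is modulated by a low-order random
#' Fourier series (`irregularity` scales the modulation; 0 gives concentric
#' discs). The nucleus is a disc (with a milder modulation) strictly inside
#' the cell. Raster convention: pixel centers, origin at the top-left,
#' x rightward, y downward, physical units via `pixel_size` only.
#'
#' @param width_px,height_px Raster size in pixels.
#' @param pixel_size Pixel size, µm/px.
#' @param nucleus_radius_fraction Nucleus radius as a fraction of the mean
#'   cell radius, in (0, 0.9).
#' @param irregularity Boundary modulation amplitude (0 = discs; ~0.2 gives
#'   realistic fibroblast-like outlines).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An object of class `cell_geometry`: list with `cell_mask`,
#'   `nucleus_mask` (logical matrices, row = y), `pixel_size`,
#'   `nucleus_centroid` (µm), and `edge_um` (cell-edge pixel centers, µm).
#' @export
make_cell_geometry <- function(width_px = 160L, height_px = 160L,
                               pixel_size = 0.16,
                               nucleus_radius_fraction = 0.35,
                               irregularity = 0.2, seed = NULL) {
  if (nucleus_radius_fraction <= 0 || nucleus_radius_fraction >= 0.9) {
    stop("nucleus_radius_fraction must be in (0, 0.9)")
  }
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  with_seed(seed, {
    cx <- width_px / 2
    cy <- height_px / 2
    r0 <- 0.42 * min(width_px, height_px)
    # low-order Fourier modulation of the boundary radius
    kmax <- 5L
    a <- stats::rnorm(kmax - 1L, 0, 1) / seq(2L, kmax)
    phi <- stats::runif(kmax - 1L, 0, 2 * pi)
    radius_at <- function(theta, base, amp) {
      mod <- rep(0, length(theta))
      for (j in seq_along(a)) {
        mod <- mod + amp * a[j] * cos((j + 1L) * theta + phi[j])
      }
      # bounded modulation keeps the nucleus inside the cell for any seed
      base * (1 + pmin(pmax(mod, -0.45), 0.45))
    }
    col <- matrix(rep(seq_len(width_px), each = height_px), nrow = height_px)
    row <- matrix(rep(seq_len(height_px), times = width_px), nrow = height_px)
    px <- col - 0.5
    py <- row - 0.5
    theta <- atan2(py - cy, px - cx)
    rr <- sqrt((px - cx)^2 + (py - cy)^2)
    cell_mask <- rr <= radius_at(theta, r0, irregularity)
    r_nuc <- nucleus_radius_fraction * r0
    nucleus_mask <- rr <= radius_at(theta, r_nuc, 0.3 * irregularity)
    # strict containment: nucleus pixels (and their 4-neighbourhood) in cell
    if (!all(cell_mask[nucleus_mask])) {
      stop("nucleus does not fit inside the cell; reduce nucleus_radius_fraction")
    }
    interior <- erode4(cell_mask)
    if (!all(interior[nucleus_mask])) {
      stop("nucleus touches the cell boundary; reduce nucleus_radius_fraction")
    }
    centroid <- c(mean(px[nucleus_mask]), mean(py[nucleus_mask])) * pixel_size
    edge <- cell_mask & !interior
    edge_um <- cbind(px[edge], py[edge]) * pixel_size
    structure(
      list(
        cell_mask = cell_mask,
        nucleus_mask = nucleus_mask,
        pixel_size = pixel_size,
        nucleus_centroid = centroid,
        edge_um = edge_um
      ),
      class = "cell_geometry"
    )
  })
}

# 4-neighbour erosion of a logical mask (border pixels count as outside).
erode4 <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)] &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  core
}

# Pixel-center coordinates (µm) of TRUE pixels of a mask.
mask_coords_um <- function(mask, pixel_size) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x_um = (idx[, "col"] - 0.5) * pixel_size,
        y_um = (idx[, "row"] - 0.5) * pixel_size)
}

# Distance (µm) from each query point to the nearest point of `ref` (n x 2).
# Blocked to keep memory bounded for large queries.
nearest_dist <- function(query, ref) {
  n <- nrow(query)
  out <- numeric(n)
  block <- 2000L
  i <- 1L
  while (i <= n) {
    j <- min(i + block - 1L, n)
    dx <- outer(query[i:j, 1], ref[, 1], "-")
    dy <- outer(query[i:j, 2], ref[, 2], "-")
    out[i:j] <- sqrt(apply(dx * dx + dy * dy, 1, min))
    i <- j + 1L
  }
  out
}

#' Sample spot positions within a cell geometry
#'
#' Draws positions from the cytoplasm (cell minus nucleus) under one of four
#' placement patterns: `uniform` over cytoplasm pixels; `perinuclear` with
#' density decaying exponentially with distance from the nucleus boundary
#' (length scale `decay_um`); `peripheral` with density decaying with
#' distance from the cell edge; `centroid` places every spot at the nucleus
#' centroid. Sampled pixels get uniform sub-pixel jitter.
#'
#' @param geometry A [make_cell_geometry()] object.
#' @param pattern One of `"uniform"`, `"perinuclear"`, `"peripheral"`,
#'   `"centroid"`.
#' @param n Number of positions (>= 1).
#' @param seed Integer seed, or `NULL` for the current RNG stream.
#' @param decay_um Exponential length scale of the non-uniform patterns, µm.
#' @param min_separation Optional minimum pairwise distance, µm; enforced by
#'   rejection (errors after too many failures).
#' @return Data frame with columns `x_um`, `y_um`.
#' @export
sample_spot_positions <- function(geometry,
                                  pattern = c("uniform", "perinuclear",
                                              "peripheral", "centroid"),
                                  n, seed = NULL, decay_um = 1.5,
                                  min_separation = 0) {
  stopifnot(inherits(geometry, "cell_geometry"))
  pattern <- match.arg(pattern)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (pattern == "centroid") {
    return(data.frame(x_um = rep(geometry$nucleus_centroid[1], n),
                      y_um = rep(geometry$nucleus_centroid[2], n)))
  }
  cyto <- geometry$cell_mask & !geometry$nucleus_mask
  if (!any(cyto)) stop("geometry has an empty cytoplasm")
  coords <- mask_coords_um(cyto, geometry$pixel_size)
  w <- switch(pattern,
    uniform = rep(1, nrow(coords)),
    perinuclear = {
      nuc_edge <- mask_coords_um(
        geometry$nucleus_mask & !erode4(geometry$nucleus_mask),
        geometry$pixel_size
      )
      exp(-nearest_dist(coords, nuc_edge) / decay_um)
    },
    peripheral = exp(-nearest_dist(coords, geometry$edge_um) / decay_um)
  )
  with_seed(seed, {
    if (min_separation > 0) {
      chosen <- integer(0)
      pts <- matrix(numeric(0), ncol = 2)
      attempts <- 0L
      max_attempts <- 200L * n
      while (length(chosen) < n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("could not place ", n, " spots at min_separation = ",
               min_separation)
        }
        k <- sample.int(nrow(coords), 1L, prob = w)
        cand <- coords[k, ] + stats::runif(2, -0.5, 0.5) * geometry$pixel_size
        if (nrow(pts) == 0 ||
            min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >=
              min_separation^2) {
          pts <- rbind(pts, cand)
          chosen <- c(chosen, k)
        }
      }
      data.frame(x_um = pts[, 1], y_um = pts[, 2])
    } else {
      k <- sample.int(nrow(coords), n, replace = TRUE, prob = w)
      data.frame(
        x_um = coords[k, 1] + stats::runif(n, -0.5, 0.5) * geometry$pixel_size,
        y_um = coords[k, 2] + stats::runif(n, -0.5, 0.5) * geometry$pixel_size
      )
    }
  })
}
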