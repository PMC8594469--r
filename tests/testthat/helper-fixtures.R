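# Shared fixture builders for the suite; everything is generated in code.

# A perfectly straight constant-speed track.
straight_track <- function(v = 2, dt = 0.5, n = 21, heading = 0,
                           origin = c(0, 0), track_id = 1L) {
  s <- v * dt * (seq_len(n) - 1)
  data.frame(
    track_id = track_id,
    frame = seq_len(n) - 1L,
    t_s = (seq_len(n) - 1L) * dt,
    x_um = origin[1] + s * cos(heading),
    y_um = origin[2] + s * sin(heading)
  )
}

# A track from explicit positions (dt = 1 s unless given).
track_from_xy <- function(x, y, dt = 1) {
  n <- length(x)
  data.frame(track_id = 1L, frame = seq_len(n) - 1L,
             t_s = (seq_len(n) - 1L) * dt, x_um = x, y_um = y)
}

# Pure-diffusion motion parameters used by closed-form checks.
brownian_params <- function(D = 0.1, dt = 0.15, n = 100, noise = 0) {
  motion_params(
    diffusion_coefficient = D, directed_fraction = 0, frame_interval = dt,
    n_frames = n, localization_noise = noise
  )
}

# Default geometry reused across files (deterministic).
test_geometry <- function(seed = 7, ...) {
  make_cell_geometry(seed = seed, ...)
}

# Rebuild a cell_geometry from raw masks (for invariance tests).
geometry_from_masks <- function(cell_mask, nucleus_mask, pixel_size) {
  coords <- rnatraffic:::mask_coords_um(nucleus_mask, pixel_size)
  interior <- rnatraffic:::erode4(cell_mask)
  edge <- cell_mask & !interior
  structure(
    list(
      cell_mask = cell_mask,
      nucleus_mask = nucleus_mask,
      pixel_size = pixel_size,
      nucleus_centroid = c(mean(coords[, 1]), mean(coords[, 2])),
      edge_um = rnatraffic:::mask_coords_um(edge, pixel_size)
    ),
    class = "cell_geometry"
  )
}

# A rendered one-frame field of well-separated single molecules plus
# optional multi-molecule clusters; returns truth and the stack.
rendered_cell_fixture <- function(n_singles = 10, n_clusters = 0,
                                  multiplicity = 6, noise_sd = 10,
                                  intensity_sd = 0, seed = 3) {
  g <- test_geometry()
  pos <- sample_spot_positions(g, "uniform", n_singles + n_clusters,
                               seed = seed, min_separation = 2.2)
  pos$multiplicity <- rep(c(1, multiplicity), c(n_singles, n_clusters))
  rp <- render_params(noise_sd = noise_sd, single_molecule_sd = intensity_sd)
  st <- render_stack(static_spots = pos, geometry = g, render = rp,
                     n_frames = 1, seed = seed + 1)
  list(geometry = g, truth = pos, stack = st, render = rp)
}
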