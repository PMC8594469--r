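# Synthetic-data generator: motion models, populations, geometries, rendering.

test_that("Brownian simulator honours degenerate and closed-form cases", {
  p0 <- brownian_params(D = 0, noise = 0)
  tr <- simulate_brownian_track(p0, origin = c(1, 2), seed = 5)
  expect_equal(unique(tr$x_um), 1)
  expect_equal(unique(tr$y_um), 2)
  expect_equal(track_displacement(tr), 0)

  # determinism contract
  p <- brownian_params()
  expect_identical(simulate_brownian_track(p, seed = 11),
                   simulate_brownian_track(p, seed = 11))
  expect_false(identical(simulate_brownian_track(p, seed = 11),
                         simulate_brownian_track(p, seed = 12)))

  expect_error(motion_params(frame_interval = 0), "frame_interval")
  expect_error(motion_params(diffusion_coefficient = -1))
})

test_that("ensemble MSD of 500 Brownian tracks matches 4*D*tau within 10%", {
  p <- brownian_params(D = 0.1, dt = 0.15, n = 100, noise = 0)
  pop <- simulate_population(p, 500, "none", seed = 42)
  em <- ensemble_curve(pop$tracks, 5, 0.15, "msd")
  expect_equal(em$value[1], 0)
  rel <- em$value[-1] / (4 * 0.1 * em$lag_s[-1]) - 1
  expect_lt(max(abs(rel)), 0.10)
})

test_that("directed simulator gives exact straight paths and known step size", {
  p <- motion_params(directed_speed = 2, direction_jitter = 0,
                     localization_noise = 0, frame_interval = 0.5,
                     n_frames = 21)
  tr <- simulate_directed_track(p, heading = pi / 7, seed = 1)
  expect_equal(track_displacement(tr), 20, tolerance = 1e-12)
  expect_equal(track_linearity(tr), 1, tolerance = 1e-12)

  # per-step displacement at 2.6 um/s, 7.36 fps: 2.6 / 7.36 = 0.3532609 um
  p2 <- motion_params(directed_speed = 2.6, direction_jitter = 0,
                      localization_noise = 0, frame_interval = 1 / 7.36,
                      n_frames = 20)
  tr2 <- simulate_directed_track(p2, heading = 1, seed = 2)
  steps <- sqrt(diff(tr2$x_um)^2 + diff(tr2$y_um)^2)
  expect_equal(unique(round(steps, 7)), 0.3532609)

  expect_error(
    simulate_directed_track(motion_params(directed_speed = 0), heading = 0),
    "directed_speed"
  )
  expect_error(motion_params(directed_speed = -1), "directed_speed")
})

test_that("moderate heading jitter keeps linearity above 0.7 for >=95% of tracks", {
  p <- motion_params(directed_speed = 2.6, direction_jitter = 0.1,
                     localization_noise = 0.03, frame_interval = 1 / 6.66,
                     n_frames = 100)
  lin <- vapply(1:300, function(i) {
    track_linearity(simulate_directed_track(p, heading = 0, seed = i))
  }, numeric(1))
  expect_gte(mean(lin > 0.7), 0.95)
})

test_that("population mixing and drug perturbations follow the control logic", {
  p <- motion_params(directed_fraction = 0.05, frame_interval = 0.15,
                     n_frames = 30)
  pop <- simulate_population(p, 1000, "none", seed = 3)
  expect_equal(sum(pop$labels$label == "directed"), 50)
  expect_equal(nrow(pop$labels), 1000)

  noc <- simulate_population(p, 1000, "nocodazole", seed = 3)
  expect_equal(sum(noc$labels$label == "directed"), 0)

  cyd <- simulate_population(p, 1000, "cytochalasinD", seed = 3)
  dmso <- simulate_population(p, 1000, "dmso", seed = 3)
  expect_equal(sum(cyd$labels$label == "directed"), 50)
  expect_identical(cyd$tracks, simulate_population(p, 1000, "none", seed = 3)$tracks)
  expect_identical(dmso$labels, cyd$labels)
})

test_that("cell geometries satisfy the nesting and seeding contracts", {
  g0 <- make_cell_geometry(irregularity = 0, seed = 1)
  # concentric discs: centroid at the raster centre
  ctr <- c(ncol(g0$cell_mask) / 2, nrow(g0$cell_mask) / 2) * g0$pixel_size
  expect_equal(g0$nucleus_centroid, ctr, tolerance = 1e-6)

  g <- test_geometry(seed = 21)
  expect_true(all(g$cell_mask[g$nucleus_mask]))
  expect_gt(sum(g$cell_mask & !g$nucleus_mask), 0)

  g2 <- test_geometry(seed = 22)
  expect_false(identical(g$cell_mask, g2$cell_mask))

  expect_error(make_cell_geometry(nucleus_radius_fraction = 0.95),
               "nucleus_radius_fraction")
})

test_that("spot placement patterns match their spatial definitions", {
  g <- test_geometry()
  ctd <- sample_spot_positions(g, "centroid", 100)
  expect_equal(unique(ctd$x_um), g$nucleus_centroid[1])
  expect_equal(unique(ctd$y_um), g$nucleus_centroid[2])

  # uniform: per-pixel counts consistent with multinomial sampling
  n <- 1e5
  u <- sample_spot_positions(g, "uniform", n, seed = 4)
  px <- g$pixel_size
  cyto <- g$cell_mask & !g$nucleus_mask
  cc <- floor(u$x_um / px) + 1L
  rr <- floor(u$y_um / px) + 1L
  expect_true(all(cyto[cbind(rr, cc)]))
  counts <- table(factor(paste(rr, cc), levels = {
    idx <- which(cyto, arr.ind = TRUE)
    paste(idx[, 1], idx[, 2])
  }))
  k <- sum(cyto)
  stat <- sum((as.integer(counts) - n / k)^2 / (n / k))
  df <- k - 1
  expect_lt(abs(stat - df), 4 * sqrt(2 * df))

  # peripheral sits farther from the nucleus centroid than uniform
  per <- sample_spot_positions(g, "peripheral", 5000, seed = 4)
  d <- function(s) mean(sqrt((s$x_um - g$nucleus_centroid[1])^2 +
                               (s$y_um - g$nucleus_centroid[2])^2))
  expect_gt(d(per), d(u))

  pn <- sample_spot_positions(g, "perinuclear", 5000, seed = 4)
  expect_lt(d(pn), d(u))
})

test_that("rendering produces calibrated Gaussian emitters over background", {
  g <- test_geometry()
  rp <- render_params(noise_sd = 0, single_molecule_sd = 0)
  st0 <- render_stack(geometry = g, render = rp, n_frames = 2)
  expect_true(all(st0$frames == rp$background_level))

  one <- data.frame(x_um = 10.1, y_um = 12.3, multiplicity = 1)
  st1 <- render_stack(static_spots = one, geometry = g, render = rp,
                      n_frames = 3)
  for (f in 1:3) {
    am <- which(st1$frames[, , f] == max(st1$frames[, , f]), arr.ind = TRUE)
    expect_lt(abs((am[1, "col"] - 0.5) * st1$pixel_size - 10.1), st1$pixel_size)
    expect_lt(abs((am[1, "row"] - 0.5) * st1$pixel_size - 12.3), st1$pixel_size)
  }

  # multiplicity-6 emitter integrates to 6x a single, and signal is conserved
  two <- data.frame(x_um = c(8, 17), y_um = c(8, 17), multiplicity = c(1, 6))
  st2 <- render_stack(static_spots = two, geometry = g, render = rp,
                      n_frames = 1)
  total <- sum(st2$frames[, , 1] - rp$background_level)
  expect_equal(total, 7 * rp$single_molecule_mean, tolerance = 0.05)

  expect_error(render_params(psf_sigma = 0), "psf_sigma")
  outside <- data.frame(x_um = -5, y_um = 3)
  expect_error(render_stack(static_spots = outside, geometry = g, render = rp),
               "bounds")
})
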