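# Linking and per-track motion metrics.

test_that("linking follows unambiguous chains, separated pairs, and the gap rule", {
  tr <- straight_track(v = 1, dt = 1, n = 10)
  one <- link_spots(tr[, c("frame", "x_um", "y_um")], max_link_dist = 2)
  expect_equal(length(unique(one$track_id)), 1)
  expect_equal(nrow(one), 10)

  # two parallel tracks >= 5 * max_link_dist apart: no identity switches
  a <- straight_track(v = 1, dt = 1, n = 15, origin = c(0, 0))
  b <- straight_track(v = 1, dt = 1, n = 15, origin = c(0, 10))
  linked <- link_spots(rbind(a, b)[, c("frame", "x_um", "y_um")],
                       max_link_dist = 2)
  expect_equal(length(unique(linked$track_id)), 2)
  for (id in unique(linked$track_id)) {
    ys <- linked$y_um[linked$track_id == id]
    expect_true(all(ys == ys[1]))
  }

  # a spot vanishing for max_gap + 1 frames splits the track
  gap1 <- tr[tr$frame != 4, ]
  expect_equal(length(unique(
    link_spots(gap1[, c("frame", "x_um", "y_um")], 4, max_gap = 1)$track_id
  )), 1)
  gap2 <- tr[!tr$frame %in% c(4, 5), ]
  expect_equal(length(unique(
    link_spots(gap2[, c("frame", "x_um", "y_um")], 4, max_gap = 2)$track_id
  )), 1)
  expect_equal(length(unique(
    link_spots(gap2[, c("frame", "x_um", "y_um")], 4, max_gap = 1)$track_id
  )), 2)

  # interpolated fill-ins are flagged and positioned linearly
  filled <- link_spots(gap1[, c("frame", "x_um", "y_um")], 4, max_gap = 1)
  virt <- filled[filled$interpolated, ]
  expect_equal(nrow(virt), 1)
  expect_equal(virt$frame, 4)
  expect_equal(virt$x_um, 4)

  # singleton spots yield no track
  lone <- data.frame(frame = c(0, 5), x_um = c(0, 50), y_um = c(0, 0))
  expect_equal(nrow(link_spots(lone, 1)), 0)
})

test_that("displacement, linearity and mean speed match hand computations", {
  t345 <- track_from_xy(c(0, 3), c(0, 4))
  expect_equal(track_displacement(t345), 5)

  loop <- track_from_xy(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_equal(track_displacement(loop), 0)
  expect_equal(track_linearity(loop), 0)

  hand <- track_from_xy(c(0, 1, 1), c(0, 0, 1))
  expect_equal(track_linearity(hand), sqrt(2) / 2, tolerance = 1e-9)
  expect_equal(track_displacement(hand), sqrt(2))
  expect_equal(track_path_length(hand), 2)

  straight <- straight_track(v = 2.6, dt = 1 / 7.36, n = 30)
  expect_equal(mean_speed(straight, 1 / 7.36), 2.6, tolerance = 1e-12)
  expect_equal(track_linearity(straight), 1)

  still <- track_from_xy(rep(1, 5), rep(2, 5))
  expect_equal(mean_speed(still, 1), 0)
  expect_message(expect_equal(track_linearity(still), 0), "zero path")

  # a noiseless directed simulator track travels v * t
  p <- motion_params(directed_speed = 2, direction_jitter = 0,
                     localization_noise = 0, frame_interval = 0.5,
                     n_frames = 21)
  sim <- simulate_directed_track(p, heading = 0.4, seed = 3)
  expect_equal(track_displacement(sim), 20, tolerance = 1e-12)
})

test_that("localization noise inflates mean speed in expectation", {
  ms <- function(noise) {
    p <- brownian_params(D = 0.1, dt = 0.15, n = 50, noise = noise)
    mean(vapply(1:200, function(i) {
      mean_speed(simulate_brownian_track(p, seed = i), 0.15)
    }, numeric(1)))
  }
  expect_gt(ms(0.05), ms(0))
})

test_that("MSD matches closed forms and the single-window identity", {
  v <- 1.7
  dt <- 0.2
  ct <- straight_track(v = v, dt = dt, n = 25, heading = 0.9)
  m <- compute_msd(ct, max_lag = 10, frame_interval = dt)
  expect_equal(m$msd, (v * m$lag_s)^2, tolerance = 1e-9)

  still <- track_from_xy(rep(0, 10), rep(0, 10))
  expect_true(all(compute_msd(still)$msd == 0))

  # MSD at the maximal lag equals the squared net displacement
  p <- brownian_params()
  tr <- simulate_brownian_track(p, seed = 8)
  full <- compute_msd(tr)
  expect_equal(full$msd[nrow(full)], track_displacement(tr)^2,
               tolerance = 1e-9)

  expect_error(compute_msd(still, max_lag = 10), "max_lag")
})

test_that("velocity autocorrelation separates persistent from reversing motion", {
  ct <- straight_track(v = 2, dt = 0.5, n = 20)
  vac <- velocity_autocorrelation(ct, max_lag = 5, frame_interval = 0.5)
  expect_equal(vac$vac, rep(1, 6), tolerance = 1e-9)

  zig <- track_from_xy(c(0, 1, 0, 1, 0, 1, 0), rep(0, 7))
  expect_equal(velocity_autocorrelation(zig, 1)$vac[2], -1)

  still <- track_from_xy(rep(0, 10), rep(0, 10))
  expect_message(v0 <- velocity_autocorrelation(still, 2), "all-zero")
  expect_equal(v0$vac, c(1, 0, 0))

  expect_error(velocity_autocorrelation(zig, max_lag = 6), "max_lag")
})

test_that("metrics are invariant under rigid motions of the coordinates", {
  p <- brownian_params(noise = 0)
  tr <- simulate_brownian_track(p, seed = 4)
  th <- 0.77
  rot <- tr
  rot$x_um <- cos(th) * tr$x_um - sin(th) * tr$y_um + 12
  rot$y_um <- sin(th) * tr$x_um + cos(th) * tr$y_um - 3
  m1 <- track_metrics(tr, p$frame_interval)
  m2 <- track_metrics(rot, p$frame_interval)
  for (col in c("displacement_um", "path_um", "linearity", "mean_speed_um_s",
                "msd_max_um2")) {
    expect_equal(m1[[col]], m2[[col]], tolerance = 1e-9)
  }
  expect_equal(compute_msd(tr)$msd, compute_msd(rot)$msd, tolerance = 1e-9)
})

test_that("relinked synthetic populations reproduce ground-truth metrics", {
  p <- motion_params(directed_fraction = 0.1, directed_speed = 1.5,
                     frame_interval = 0.15, n_frames = 25,
                     localization_noise = 0.02)
  pop <- simulate_population(p, 20, "none", seed = 9, field_size_um = 200)
  relinked <- link_spots(pop$tracks[, c("frame", "x_um", "y_um")],
                         max_link_dist = 1.0)
  expect_equal(length(unique(relinked$track_id)), 20)
  m_true <- track_metrics(pop$tracks, p$frame_interval)
  m_rel <- track_metrics(relinked, p$frame_interval)
  expect_equal(sort(m_rel$displacement_um), sort(m_true$displacement_um),
               tolerance = 1e-6)
})
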