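# Duration filter, displacement/linearity thresholds, directed fractions.

test_that("duration filter is strict and matches a brute-force recount", {
  dt <- 0.1
  mk <- function(id, n) straight_track(v = 1, dt = dt, n = n, track_id = id)
  short <- mk(1, 25)  # 2.4 s
  exact <- mk(2, 26)  # exactly 2.5 s
  long <- mk(3, 27)   # 2.6 s
  tracks <- rbind(short, exact, long)
  kept <- filter_by_duration(tracks, 2.5, dt)
  expect_equal(unique(kept$track_id), 3)

  # 100 tracks of uniform random duration 1-5 s vs a direct recount
  set.seed(77)
  ns <- sample(11:51, 100, replace = TRUE)
  mixed <- do.call(rbind, lapply(seq_along(ns), function(i) mk(i, ns[i])))
  kept2 <- filter_by_duration(mixed, 2.5, dt)
  brute <- sum((ns - 1) * dt > 2.5)
  expect_equal(length(unique(kept2$track_id)), brute)
})

test_that("minimum frame counts follow the strict duration rule", {
  expect_identical(min_frames(2.5, 6.66), 17L)
  expect_identical(min_frames(1.0, 10), 11L)
  expect_identical(min_frames(2.5, 7.36), 19L)
  expect_error(min_frames(0, 10))
})

test_that("threshold classification uses strict inequalities on both metrics", {
  m <- data.frame(
    track_id = 1:3,
    displacement_um = c(5, 3, 4.0),
    linearity = c(0.8, 0.95, 0.9),
    msd_max_um2 = c(25, 9, 16)
  )
  cl <- classify_tracks(m, classifier_thresholds())
  expect_equal(cl$motion_class,
               c("long_directed", "short_diffuse", "short_diffuse"))

  expect_equal(directed_fraction(cl), 100 / 3, tolerance = 1e-9)
  expect_equal(directed_fraction(
    data.frame(motion_class = rep(c("long_directed", "short_diffuse"),
                                  c(3, 97)))
  ), 3.0)
  expect_error(directed_fraction(cl[0, ]), "undefined|no tracks")
})

test_that("classifier is monotone in its thresholds", {
  p <- motion_params(directed_fraction = 0.2, frame_interval = 0.15,
                     n_frames = 60)
  pop <- simulate_population(p, 200, "none", seed = 5)
  m <- track_metrics(pop$tracks, p$frame_interval)
  counts <- vapply(seq(2, 10, by = 2), function(d) {
    sum(classify_tracks(m, classifier_thresholds(min_displacement = d))$
          motion_class == "long_directed")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  counts_l <- vapply(c(0.5, 0.7, 0.9, 0.99), function(l) {
    sum(classify_tracks(m, classifier_thresholds(min_linearity = l))$
          motion_class == "long_directed")
  }, numeric(1))
  expect_true(all(diff(counts_l) <= 0))
})

test_that("drug-perturbed populations reproduce the control phenotypes", {
  p <- motion_params(frame_interval = 0.15, n_frames = 100)
  analyse <- function(pert) {
    pop <- simulate_population(p, 400, pert, seed = 31)
    kept <- filter_by_duration(pop$tracks, 2.5, p$frame_interval)
    cl <- classify_tracks(track_metrics(kept, p$frame_interval))
    directed_fraction(cl)
  }
  expect_equal(analyse("nocodazole"), 0)
  f_none <- analyse("none")
  expect_gt(f_none, 0)
  expect_equal(analyse("cytochalasinD"), f_none)
  expect_equal(analyse("dmso"), f_none)
})

test_that("classified fractions recover the simulated ground truth", {
  p <- motion_params(directed_fraction = 0.05, frame_interval = 0.15,
                     n_frames = 100)
  rec <- vapply(1:10, function(s) {
    pop <- simulate_population(p, 200, "none", seed = s)
    kept <- filter_by_duration(pop$tracks, 2.5, p$frame_interval)
    cl <- classify_tracks(track_metrics(kept, p$frame_interval))
    directed_fraction(cl)
  }, numeric(1))
  expect_true(all(abs(rec - 5) <= 1.5))
})

test_that("control-derived thresholds bound the false-positive rate", {
  p <- brownian_params(D = 0.1, dt = 0.15, n = 60, noise = 0.03)
  ctrl <- simulate_population(p, 1000, "nocodazole", seed = 17)
  m <- track_metrics(ctrl$tracks, p$frame_interval)

  thr0 <- derive_thresholds(m, target_fpr = 0)
  expect_gte(thr0$min_displacement, max(m$displacement_um))
  cl0 <- classify_tracks(m, thr0)
  expect_equal(sum(cl0$motion_class == "long_directed"), 0)

  thr1 <- derive_thresholds(m, target_fpr = 0.01)
  passed <- sum(m$displacement_um > thr1$min_displacement &
                  m$linearity > thr1$min_linearity)
  expect_lte(passed, 10)

  # degenerate control falls back to defaults with a warning
  deg <- data.frame(track_id = 1:30, displacement_um = rep(1, 30),
                    linearity = rep(0.5, 30))
  expect_warning(thr_d <- derive_thresholds(deg), "degenerate")
  expect_equal(thr_d$min_displacement, 4)

  # derived thresholds keep high recall on a mixed population
  pm <- motion_params(directed_fraction = 0.05, frame_interval = 0.15,
                      n_frames = 60)
  mix <- simulate_population(pm, 600, "none", seed = 18)
  mm <- track_metrics(mix$tracks, pm$frame_interval)
  cl <- classify_tracks(mm, derive_thresholds(m, target_fpr = 0))
  truth <- mix$labels$label[match(cl$track_id, mix$labels$track_id)]
  recall <- sum(cl$motion_class == "long_directed" & truth == "directed") /
    sum(truth == "directed")
  expect_gte(recall, 0.9)
})

test_that("per-cell summaries count directed tracks by cell", {
  m <- data.frame(
    track_id = 1:6, cell_id = c(1, 1, 1, 2, 2, 2),
    motion_class = c("long_directed", "short_diffuse", "short_diffuse",
                     "short_diffuse", "short_diffuse", "short_diffuse")
  )
  s <- directed_fraction_per_cell(m)
  expect_equal(s$n_directed, c(1, 0))
  expect_equal(s$pct_directed, c(100 / 3, 0))
})
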