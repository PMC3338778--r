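test_that("path length, net displacement and D/T on hand-built tracks", {
  t345 <- make_track(c(0, 0, 3, 4, 3, 4))
  expect_equal(path_length(t345), 5)
  expect_equal(net_displacement(t345), 5)

  single <- make_track(c(2, 3))
  expect_equal(path_length(single), 0)
  expect_equal(net_displacement(single), 0)

  collinear <- straight_track(25, step = 1)
  expect_equal(path_length(collinear), 24)
  expect_equal(directionality_ratio(collinear), 1)

  lpath <- make_track(c(0, 0, 3, 0, 3, 4))  # legs 3 then 4
  expect_equal(path_length(lpath), 7)
  expect_equal(net_displacement(lpath), 5)
  expect_equal(directionality_ratio(lpath), 5 / 7)

  loop <- make_track(c(0, 0, 1, 0, 1, 1, 0, 1, 0, 0))
  expect_equal(net_displacement(loop), 0)
  expect_equal(directionality_ratio(loop), 0)

  stationary <- make_track(c(1, 1, 1, 1, 1, 1))
  expect_true(is.na(directionality_ratio(stationary)))
})

test_that("relative directionality normalises to the control mean", {
  groups <- list(WT = c(0.5, 0.5), HET = c(0.315, 0.315),
                 MUT = c(0.635, 0.635))
  out <- relative_directionality(groups, "WT")
  expect_equal(out[["WT"]], 100)
  expect_equal(out[["HET"]], 63)
  expect_equal(out[["MUT"]], 127)
  expect_error(relative_directionality(groups, "XX"), "control")
  expect_error(relative_directionality(list(WT = c(0, 0), A = c(1, 1))),
               "positive")
})

test_that("motion segmentation and time budgets", {
  fast <- straight_track(25, step = 5)
  expect_true(all(segment_motion(fast, 1) == "moving"))
  expect_equal(time_budget(segment_motion(fast, 1), 5),
               c(time_moving = 120, time_paused = 0))

  still <- make_track(rep(0, 10))
  expect_true(all(segment_motion(still, 1) == "paused"))

  mixed <- make_track(c(0, 0, 2, 0, 2.1, 0, 4.1, 0, 4.2, 0))
  expect_equal(segment_motion(mixed, 1),
               c("moving", "paused", "moving", "paused"))
  expect_equal(unname(time_budget(segment_motion(mixed, 1), 5)), c(10, 10))

  expect_error(segment_motion(fast, 0), "pause_threshold_um")
  expect_error(time_budget(character(0), 5), "no intervals")
})

test_that("time budget sums exactly to (n_points - 1) * dt", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    t <- random_walk_track(n, sd = stats::runif(1, 0.1, 4))
    tb <- time_budget(segment_motion(t, 1), t$dt_min)
    expect_identical(sum(tb), (n - 1) * t$dt_min)
  }
})

test_that("mean velocity in both modes", {
  t <- straight_track(25, step = 2.5)  # 2.5 um per 5-min interval
  expect_equal(mean_velocity(t, "observation"), 0.5)
  expect_equal(mean_velocity(t, "moving"), 0.5)
  still <- make_track(rep(0, 10))
  expect_equal(mean_velocity(still, "observation"), 0)
  expect_true(is.na(mean_velocity(still, "moving")))
  # default-mode velocity x observation time = path length, exactly
  set.seed(8)
  for (i in 1:20) {
    t <- random_walk_track(12)
    expect_equal(mean_velocity(t) * 11 * t$dt_min, path_length(t))
  }
})

test_that("direction-change counting", {
  expect_equal(count_direction_changes(straight_track(10)), 0)
  # zig-zag: alternating +/-90 degree turns, every pair exceeds 45 degrees
  zig <- make_track(c(0, 0, 1, 0, 1, 1, 2, 1, 2, 2, 3, 2))  # 6 points
  expect_equal(count_direction_changes(zig, 45), 4)  # n_points - 2
  # under isotropy about half of step pairs exceed 90 degrees
  p <- isotropic_params()
  ts <- simulate_tracks(p, 400, 25, 5, seed = 23)
  frac <- mean(vapply(ts$tracks, function(t) {
    count_direction_changes(t, 90) / 22
  }, numeric(1)))
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("group summaries: SEM formula, degenerate cohorts, exclusions", {
  t1 <- straight_track(5, 2); t2 <- straight_track(5, 2)
  sm <- summarize_group(list(t1, t2), group_label = "twins")
  expect_true(all(sm$summary$sem == 0))
  expect_error(summarize_group(list(t1)), ">= 2 tracks")

  # SEM matches the direct sd/sqrt(n) oracle on known values
  tracks <- lapply(c(1, 2, 4, 8), function(s) straight_track(5, s))
  sm <- summarize_group(tracks)
  tvals <- c(4, 8, 16, 32)
  expect_equal(sm$summary$mean[sm$summary$metric == "T_um"], mean(tvals))
  expect_equal(sm$summary$sem[sm$summary$metric == "T_um"],
               stats::sd(tvals) / 2)

  # stationary track's undefined ratio is excluded and counted
  sm <- summarize_group(list(t1, make_track(rep(0, 10))))
  expect_equal(sm$n_undefined_ratio, 1)
  expect_equal(sm$summary$n[sm$summary$metric == "dt_ratio"], 1)
})

test_that("D <= T and D/T invariance under rotation and scaling", {
  set.seed(77)
  for (i in seq_len(1e4)) {
    t <- random_walk_track(sample(2:12, 1))
    expect_true(net_displacement(t) <= path_length(t) + 1e-12)
  }
  t <- random_walk_track(15)
  r0 <- directionality_ratio(t)
  th <- 0.83
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t_rot <- track("r", t$positions %*% rot, t$dt_min)
  t_scl <- track("s", 3.7 * t$positions, t$dt_min)
  expect_equal(directionality_ratio(t_rot), r0, tolerance = 1e-12)
  expect_equal(directionality_ratio(t_scl), r0, tolerance = 1e-12)
})

test_that("track CSV round trip preserves positions and timing", {
  ts <- simulate_tracks(preset_params("WT"), 3, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_tracks_csv(ts, f)
  back <- read_tracks_csv(f)
  expect_equal(length(back), 3)
  orig <- ts$tracks[order(vapply(ts$tracks, `[[`, "", "track_id"))]
  for (i in seq_along(back)) {
    expect_equal(unname(back[[i]]$positions), unname(orig[[i]]$positions),
                 tolerance = 1e-6)
    expect_equal(back[[i]]$dt_min, 5)
  }
  unlink(f)
})
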