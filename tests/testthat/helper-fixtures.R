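# Small track builders used across test files.

make_track <- function(xy, dt_min = 5, id = "t1") {
  if (!is.matrix(xy)) xy <- matrix(xy, ncol = 2, byrow = TRUE)
  track(id, xy, dt_min = dt_min)
}

straight_track <- function(n_points = 25, step = 1, dt_min = 5) {
  make_track(cbind(seq_len(n_points) - 1, 0) * step, dt_min = dt_min)
}

# uncorrelated Gaussian random walk, cheap enough for 1e4-track properties
random_walk_track <- function(n_points = 10, sd = 2, dt_min = 5, id = "rw") {
  xy <- cbind(c(0, cumsum(stats::rnorm(n_points - 1, 0, sd))),
              c(0, cumsum(stats::rnorm(n_points - 1, 0, sd))))
  track(id, xy, dt_min = dt_min)
}

isotropic_params <- function(speed = 1) {
  motility_params(0, 1, speed_mean = speed, speed_sd = 0, turn_kappa = 0,
                  pause_jitter_um = 0)
}
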