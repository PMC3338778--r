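#!/usr/bin/env Rscript
# Calibrates the genotype motility presets against the published cohort
# summaries (total distance, velocity, time moving/paused; n = 5 cells,
# 25 points, dt = 5 min). Switching probabilities are set analytically from
# the published moving fraction; the mean speed while moving is then tuned
# by fixed-point iteration on large simulated cohorts so the realised mean
# total distance (which includes pause jitter and speed truncation) hits
# the published mean. Run from the repository root with the package
# installed; paste the printed table into .preset_table in
# R/simulate-tracks.R.

library(motanlage)

targets <- list(
  WT  = list(dist = 53, vel = 0.5, moving = 92,  paused = 32,
             p_mp = 0.100, turn_kappa = 0.8, speed_sd = 0.12),
  HET = list(dist = 74, vel = 0.6, moving = 101, paused = 24,
             p_mp = 0.070, turn_kappa = 1.6, speed_sd = 0.15),
  MUT = list(dist = 23, vel = 0.2, moving = 59,  paused = 66,
             p_mp = 0.160, turn_kappa = 0.8, speed_sd = 0.08)
)

n_cal <- 3000
for (g in names(targets)) {
  tg <- targets[[g]]
  f_move <- tg$moving / (tg$moving + tg$paused)   # published moving fraction
  p_pm <- tg$p_mp * f_move / (1 - f_move)
  speed <- tg$dist / (f_move * 24 * 5)            # ignore jitter, iterate
  for (it in 1:5) {
    par <- motility_params(tg$p_mp, p_pm, speed, tg$speed_sd, tg$turn_kappa)
    ts <- simulate_tracks(par, n_cal, 25, 5, seed = 1000 + it)
    mt <- mean(vapply(ts$tracks, path_length, numeric(1)))
    speed <- speed * tg$dist / mt
  }
  par <- motility_params(tg$p_mp, p_pm, speed, tg$speed_sd, tg$turn_kappa)
  ts <- simulate_tracks(par, n_cal, 25, 5, seed = 99)
  sm <- summarize_group(ts$tracks, group_label = g)$summary
  cat(sprintf(
    "%s = list(p_move_to_pause = %.3f, p_pause_to_move = %.3f,\n           speed_mean = %.3f, speed_sd = %.2f, turn_kappa = %.1f),\n",
    g, tg$p_mp, p_pm, speed, tg$speed_sd, tg$turn_kappa))
  cat(sprintf("  achieved: dist %.1f (target %g), vel %.2f (%g), moving %.1f (%g), paused %.1f (%g)\n",
              sm$mean[sm$metric == "T_um"], tg$dist,
              sm$mean[sm$metric == "velocity_um_min"], tg$vel,
              sm$mean[sm$metric == "time_moving_min"], tg$moving,
              sm$mean[sm$metric == "time_paused_min"], tg$paused))
}
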