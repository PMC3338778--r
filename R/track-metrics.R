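#' Per-track motility statistics
#'
#' Core trajectory statistics for time-lapse tracking of migrating cells:
#' total path length T, net start-to-end displacement D, the D/T
#' directionality ratio, mean velocity, moving/paused time budgets and
#' direction-change counts.
#'
#' @param track A [track()] object.
#' @name track_metrics
NULL

step_lengths <- function(track) {
  p <- track$positions
  if (nrow(p) < 2L) return(numeric(0))
  sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
}

#' @describeIn track_metrics Total path length T (um): sum of consecutive
#'   Euclidean step lengths; 0 for a single point.
#' @export
path_length <- function(track) {
  stopifnot(inherits(track, "track"))
  sum(step_lengths(track))
}

#' @describeIn track_metrics Net displacement D (um): Euclidean distance
#'   from the first to the last recorded position.
#' @export
net_displacement <- function(track) {
  stopifnot(inherits(track, "track"))
  p <- track$positions
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

#' @describeIn track_metrics Directionality ratio D/T in \[0, 1\]: 1 for
#'   perfectly straight motion, near 0 for wandering or returning paths.
#'   `NA` (undefined) when the cell never moved (T = 0).
#' @export
directionality_ratio <- function(track) {
  stopifnot(inherits(track, "track"))
  if (nrow(track$positions) < 2L) {
    stop("directionality ratio needs >= 2 points", call. = FALSE)
  }
  tt <- path_length(track)
  if (tt == 0) return(NA_real_)
  net_displacement(track) / tt
}

#' Group directionality as percent of a control group
#'
#' Normalises each group's mean D/T ratio to the control group's mean
#' (control = 100). Undefined ratios (`NA`) are dropped.
#'
#' @param groups Named list mapping group label to a numeric vector of D/T
#'   ratios.
#' @param control Label of the control group (present in `groups`).
#' @return Named numeric vector of percentages; the control maps to 100.
#' @export
relative_directionality <- function(groups, control = "WT") {
  if (!control %in% names(groups)) {
    stop("control group '", control, "' not present", call. = FALSE)
  }
  means <- vapply(groups, function(v) mean(v, na.rm = TRUE), numeric(1))
  if (!is.finite(means[[control]]) || means[[control]] <= 0) {
    stop("control group mean ratio must be positive", call. = FALSE)
  }
  100 * means / means[[control]]
}

#' Moving/paused segmentation and time budgets
#'
#' An interval is labelled moving when its displacement is at least
#' `pause_threshold_um`; smaller displacements (including pure centroid
#' jitter) count as paused. The default 1 um per 5-min interval (0.2 um/min)
#' sits at the mutant mean speed and above typical centroid noise.
#'
#' @param track A [track()] object with >= 2 points.
#' @param pause_threshold_um Positive displacement threshold per interval.
#' @return `segment_motion`: character vector of `"moving"`/`"paused"`, one
#'   per interval.
#' @export
segment_motion <- function(track, pause_threshold_um = 1.0) {
  stopifnot(inherits(track, "track"))
  stop_field(is.numeric(pause_threshold_um) && pause_threshold_um > 0,
             "pause_threshold_um", "must be positive")
  steps <- step_lengths(track)
  if (!length(steps)) stop("segmentation needs >= 2 points", call. = FALSE)
  ifelse(steps >= pause_threshold_um, "moving", "paused")
}

#' @rdname segment_motion
#' @param labels Character vector of interval labels from [segment_motion()].
#' @param dt_min Sampling interval, minutes.
#' @return `time_budget`: named numeric vector `c(time_moving, time_paused)`
#'   in minutes; the two always sum to `length(labels) * dt_min` exactly.
#' @export
time_budget <- function(labels, dt_min) {
  if (!length(labels)) stop("no intervals to budget", call. = FALSE)
  n_mov <- sum(labels == "moving")
  c(time_moving = n_mov * dt_min,
    time_paused = (length(labels) - n_mov) * dt_min)
}

#' Mean velocity of a track
#'
#' Default mode divides the total path length by the total observation time;
#' the alternate mode divides by time spent moving (undefined, `NA`, if the
#' cell never moved).
#'
#' @inheritParams segment_motion
#' @param mode `"observation"` (T / total time) or `"moving"`
#'   (T / time moving).
#' @return Velocity in um/min.
#' @export
mean_velocity <- function(track, mode = c("observation", "moving"),
                          pause_threshold_um = 1.0) {
  stopifnot(inherits(track, "track"))
  mode <- match.arg(mode)
  n <- nrow(track$positions)
  if (n < 2L) stop("velocity needs >= 2 points", call. = FALSE)
  total_t <- (n - 1L) * track$dt_min
  if (mode == "observation") return(path_length(track) / total_t)
  tb <- time_budget(segment_motion(track, pause_threshold_um), track$dt_min)
  if (tb[["time_moving"]] == 0) return(NA_real_)
  path_length(track) / tb[["time_moving"]]
}

#' Count direction changes along a track
#'
#' Counts consecutive pairs of moving steps whose heading change exceeds
#' `angle_threshold_deg`. Steps shorter than `min_step_um` are ignored so
#' pause jitter does not register as turning.
#'
#' @inheritParams segment_motion
#' @param angle_threshold_deg Heading-change threshold in degrees
#'   (default 45).
#' @param min_step_um Steps below this length are skipped (default 1e-9,
#'   i.e. only exact zero steps are skipped).
#' @return Integer count.
#' @export
count_direction_changes <- function(track, angle_threshold_deg = 45,
                                    min_step_um = 1e-9) {
  stopifnot(inherits(track, "track"))
  p <- track$positions
  if (nrow(p) < 3L) stop("direction changes need >= 3 points", call. = FALSE)
  dx <- diff(p[, 1]); dy <- diff(p[, 2])
  len <- sqrt(dx^2 + dy^2)
  keep <- len >= min_step_um
  dx <- dx[keep]; dy <- dy[keep]
  if (length(dx) < 2L) return(0L)
  ang <- atan2(dy, dx)
  turn <- diff(ang)
  turn <- abs(atan2(sin(turn), cos(turn)))  # wrap to [0, pi]
  sum(turn > angle_threshold_deg * pi / 180)
}

#' Summarise a cohort of tracks
#'
#' Computes per-track statistics and reports mean, SEM (= sd / sqrt(n)) and
#' n per metric. Undefined D/T ratios (stationary tracks) are excluded from
#' the ratio summary; the number excluded is recorded.
#'
#' @param tracks List of [track()] objects (or a `track_set`), >= 2 tracks.
#' @param pause_threshold_um Displacement threshold for [segment_motion()].
#' @param velocity_mode Passed to [mean_velocity()].
#' @param group_label Label attached to the summary.
#' @return A `group_motility_summary`: list with `group_label`, `n`,
#'   `per_track` (data frame of per-track stats) and `summary` (data frame
#'   metric/mean/sem/n), plus `n_undefined_ratio`.
#' @export
summarize_group <- function(tracks, pause_threshold_um = 1.0,
                            velocity_mode = "observation",
                            group_label = NULL) {
  if (inherits(tracks, "track_set")) {
    if (is.null(group_label)) group_label <- tracks$group_label
    tracks <- tracks$tracks
  }
  if (length(tracks) < 2L) stop("need >= 2 tracks", call. = FALSE)
  if (is.null(group_label)) group_label <- "group"

  per <- do.call(rbind, lapply(tracks, function(t) {
    labs <- segment_motion(t, pause_threshold_um)
    tb <- time_budget(labs, t$dt_min)
    data.frame(
      track_id = t$track_id,
      T_um = path_length(t),
      D_um = net_displacement(t),
      dt_ratio = directionality_ratio(t),
      velocity_um_min = mean_velocity(t, velocity_mode, pause_threshold_um),
      time_moving_min = tb[["time_moving"]],
      time_paused_min = tb[["time_paused"]],
      n_dir_changes = count_direction_changes(t),
      stringsAsFactors = FALSE
    )
  }))

  metrics <- c("T_um", "D_um", "dt_ratio", "velocity_um_min",
               "time_moving_min", "time_paused_min", "n_dir_changes")
  summ <- do.call(rbind, lapply(metrics, function(m) {
    v <- per[[m]]
    v <- v[!is.na(v)]
    data.frame(metric = m,
               mean = if (length(v)) mean(v) else NA_real_,
               sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = length(v), stringsAsFactors = FALSE)
  }))

  structure(list(group_label = group_label, n = length(tracks),
                 per_track = per, summary = summ,
                 n_undefined_ratio = sum(is.na(per$dt_ratio))),
            class = "group_motility_summary")
}

#' @export
print.group_motility_summary <- function(x, ...) {
  cat(sprintf("<group_motility_summary> %s (n = %d tracks)\n",
              x$group_label, x$n))
  print(x$summary, row.names = FALSE)
  if (x$n_undefined_ratio > 0) {
    cat(sprintf("  (%d undefined D/T ratio(s) excluded)\n",
                x$n_undefined_ratio))
  }
  invisible(x)
}
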