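#' Mean-square-displacement curves
#'
#' Two curve modes are supported. `displacement_msd()` is the standard
#' mean square displacement: for each lag tau the squared straight-line
#' displacement |r(t + tau) - r(t)|^2, time-averaged over all valid start
#' times within a track and then averaged over tracks. For an uncorrelated
#' random walk this curve is linear through the origin.
#' `path_squared_curve()` is the squared cumulative path-length variant
#' (T^2): for each lag tau the squared total path distance travelled from
#' t = 0 to tau, averaged over tracks. The path-squared curve dominates the
#' displacement curve pointwise because path length bounds displacement.
#'
#' @param tracks List of [track()] objects or a `track_set`.
#' @param lags_min Lags in minutes; each must be a positive multiple of the
#'   sampling interval and no larger than the track span. Default
#'   `seq(20, 120, by = 20)`.
#' @param time_average For `displacement_msd`, use overlapping windows
#'   (default) or only the start-anchored displacement per track.
#' @return An `msd_curve`: data frame with columns `lag_min` and
#'   `mean_square_um2`, plus attributes `mode` and `n_tracks`.
#' @export
displacement_msd <- function(tracks, lags_min = seq(20, 120, by = 20),
                             time_average = TRUE) {
  tracks <- as_track_list(tracks)
  lagk <- lag_steps(tracks, lags_min)
  ms <- vapply(seq_along(lags_min), function(j) {
    k <- lagk[j]
    vals <- unlist(lapply(tracks, function(t) {
      p <- t$positions
      n <- nrow(p)
      starts <- if (time_average) seq_len(n - k) else 1L
      (p[starts + k, 1] - p[starts, 1])^2 +
        (p[starts + k, 2] - p[starts, 2])^2
    }))
    mean(vals)
  }, numeric(1))
  msd_curve(lags_min, ms, mode = "displacement", n_tracks = length(tracks))
}

#' @rdname displacement_msd
#' @export
path_squared_curve <- function(tracks, lags_min = seq(20, 120, by = 20)) {
  tracks <- as_track_list(tracks)
  lagk <- lag_steps(tracks, lags_min)
  ms <- vapply(seq_along(lags_min), function(j) {
    k <- lagk[j]
    mean(vapply(tracks, function(t) {
      steps <- step_lengths(t)
      sum(steps[seq_len(k)])^2
    }, numeric(1)))
  }, numeric(1))
  msd_curve(lags_min, ms, mode = "path_squared", n_tracks = length(tracks))
}

msd_curve <- function(lag_min, mean_square_um2, mode, n_tracks) {
  if (is.unsorted(lag_min, strictly = TRUE)) {
    stop("lags must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(lag_min = lag_min, mean_square_um2 = mean_square_um2),
            mode = mode, n_tracks = n_tracks,
            class = c("msd_curve", "data.frame"))
}

as_track_list <- function(tracks) {
  if (inherits(tracks, "track_set")) tracks <- tracks$tracks
  if (inherits(tracks, "track")) tracks <- list(tracks)
  if (!length(tracks)) stop("no tracks supplied", call. = FALSE)
  tracks
}

lag_steps <- function(tracks, lags_min) {
  dt <- tracks[[1]]$dt_min
  if (!length(lags_min) || any(lags_min <= 0)) {
    stop("lags must be positive", call. = FALSE)
  }
  k <- lags_min / dt
  if (any(abs(k - round(k)) > 1e-8)) {
    stop("each lag must be a multiple of dt_min = ", dt, call. = FALSE)
  }
  k <- as.integer(round(k))
  span <- min(vapply(tracks, function(t) nrow(t$positions), integer(1))) - 1L
  if (any(k > span)) {
    stop("lag exceeds track span (", span * dt, " min)", call. = FALSE)
  }
  k
}

#' Ordinary least-squares fit of an MSD curve against lag time
#'
#' The x-intercept of the regression line is the randomness diagnostic:
#' purely random (uncorrelated) motion gives a line through the origin, so
#' an x-intercept near zero is consistent with a simple random walk.
#'
#' @param curve An `msd_curve` with >= 2 distinct lags.
#' @return A `regression_fit`: list with `slope` (um^2/min), `intercept`
#'   (um^2), `x_intercept` (min; `NA` when the slope is zero) and
#'   `r_squared`.
#' @export
linear_fit <- function(curve) {
  stopifnot(inherits(curve, "msd_curve"))
  if (nrow(curve) < 2L || length(unique(curve$lag_min)) < 2L) {
    stop("linear fit needs >= 2 distinct lags", call. = FALSE)
  }
  fit <- stats::lm(mean_square_um2 ~ lag_min, data = curve)
  co <- stats::coef(fit)
  slope <- unname(co[2]); intercept <- unname(co[1])
  x_int <- if (slope != 0) -intercept / slope else NA_real_
  sst <- sum((curve$mean_square_um2 - mean(curve$mean_square_um2))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(slope = slope, intercept = intercept,
                 x_intercept = x_int, r_squared = r2),
            class = "regression_fit")
}

#' Randomness diagnostic from the MSD regression x-intercept
#'
#' @param fit A `regression_fit` from [linear_fit()].
#' @param tol_min Tolerance in minutes on the |x-intercept|.
#' @return `"consistent_with_random"` or `"not_consistent"`.
#' @export
randomness_diagnostic <- function(fit, tol_min = 10) {
  stopifnot(inherits(fit, "regression_fit"))
  if (is.na(fit$x_intercept)) {
    warning("x-intercept undefined (zero slope); reporting not_consistent")
    return("not_consistent")
  }
  if (abs(fit$x_intercept) <= tol_min) "consistent_with_random"
  else "not_consistent"
}

#' Fit the persistent-random-walk (Fuerth) model to an MSD curve
#'
#' Fits MSD(tau) = 2 S^2 P \[tau - P (1 - exp(-tau / P))\] by least squares,
#' where S is the cell speed (um/min) and P the directional persistence
#' time (min). Uses bounded Nelder-Mead refinement from 8 deterministic
#' multi-starts; ties are broken by lowest residual then lowest P. When the
#' fitted P reaches the largest lag the motion is flagged ballistic (the
#' window cannot resolve the crossover).
#'
#' @param curve A displacement-mode `msd_curve` with >= 3 lags.
#' @return A `prw_fit`: list with `S`, `P`, `rss` and logical `ballistic`.
#' @export
fit_persistent_walk <- function(curve) {
  stopifnot(inherits(curve, "msd_curve"))
  if (!identical(attr(curve, "mode"), "displacement")) {
    stop("persistent-walk fit requires a displacement-mode curve",
         call. = FALSE)
  }
  if (nrow(curve) < 3L) stop("need >= 3 lags", call. = FALSE)
  tau <- curve$lag_min; y <- curve$mean_square_um2
  model <- function(s, p, tau) {
    if (p < 1e-9) return(2 * s^2 * p * tau)
    2 * s^2 * p * (tau - p * (1 - exp(-tau / p)))
  }
  rss_fun <- function(par) {
    s <- exp(par[1]); p <- exp(par[2])
    sum((model(s, p, tau) - y)^2)
  }
  # crude scale guesses from the curve itself
  slope_guess <- max(y[length(y)] / tau[length(tau)], 1e-12)
  s0 <- sqrt(slope_guess / 2)             # if P ~ 1 min
  starts <- expand.grid(s = s0 * c(0.3, 1, 3, 10),
                        p = c(min(tau) / 2, max(tau)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(log(c(starts$s[i], starts$p[i])), rss_fun,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    # quasi-Newton polish; Nelder-Mead alone stalls ~1e-5 from the optimum
    o <- tryCatch(stats::optim(o$par, rss_fun, method = "BFGS",
                               control = list(maxit = 500,
                                              reltol = 1e-14)),
                  error = function(e) o)
    cand <- list(S = exp(o$par[1]), P = exp(o$par[2]), rss = o$value)
    if (is.null(best) || cand$rss < best$rss * (1 - 1e-9) ||
        (abs(cand$rss - best$rss) <= best$rss * 1e-9 && cand$P < best$P)) {
      best <- cand
    }
  }
  best$ballistic <- best$P >= max(tau)
  class(best) <- "prw_fit"
  best
}

#' @export
print.prw_fit <- function(x, ...) {
  cat(sprintf("<prw_fit> S = %.4g um/min, P = %.4g min, rss = %.4g%s\n",
              x$S, x$P, x$rss, if (x$ballistic) " [ballistic]" else ""))
  invisible(x)
}

#' Write an MSD curve as CSV (`lag_min,mean_square_um2,mode,n_tracks`)
#' @param curve An `msd_curve`.
#' @param path Output file.
#' @export
write_msd_csv <- function(curve, path) {
  df <- data.frame(lag_min = curve$lag_min,
                   mean_square_um2 = curve$mean_square_um2,
                   mode = attr(curve, "mode"),
                   n_tracks = attr(curve, "n_tracks"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
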