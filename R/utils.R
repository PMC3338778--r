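# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Display rounding used by the published tables (base `round()` is
#' round-half-even): 26.5 becomes 27 and -2.25 becomes -2.3 at 1 decimal.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0L) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# von Mises sampler (Best & Fisher 1979 rejection method).
# kappa = 0 degenerates to the uniform distribution on (-pi, pi].
rvonmises <- function(n, mu = 0, kappa = 0) {
  stopifnot(kappa >= 0)
  if (kappa == 0) {
    return(stats::runif(n, -pi, pi) + mu)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.5 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    keep <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    out <- c(out, sign(u3[keep] - 0.5) * acos(f[keep]))
  }
  out[seq_len(n)] + mu
}

#' Mean resultant length of the von Mises turning distribution
#'
#' `I1(kappa)/I0(kappa)`: the per-step directional correlation of a
#' correlated random walk with turning concentration `kappa`. Maps the
#' simulator's `turn_kappa` onto a persistence time via
#' `P = dt (1 + rho) / (2 (1 - rho))`.
#'
#' @param kappa Non-negative concentration.
#' @return Correlation in \[0, 1).
#' @export
vm_mean_resultant <- function(kappa) {
  if (kappa == 0) return(0)
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

stop_field <- function(cond, field, msg) {
  if (!isTRUE(cond)) stop(sprintf("`%s` %s", field, msg), call. = FALSE)
}
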