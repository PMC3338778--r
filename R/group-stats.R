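#' Mean and standard error of the mean
#'
#' @param values Numeric vector with n >= 2.
#' @return A `summary_stat`: list with `n`, `mean`, `sem` (= sd / sqrt(n)).
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("mean_sem needs >= 2 non-missing values", call. = FALSE)
  }
  structure(list(n = length(values), mean = mean(values),
                 sem = stats::sd(values) / sqrt(length(values))),
            class = "summary_stat")
}

#' @rdname mean_sem
#' @param n,mean,sem Components of a precomputed summary (printed
#'   mean +/- SEM with group size), for tests driven from published numbers.
#' @export
summary_stat <- function(n, mean, sem) {
  stop_field(is.numeric(n) && n >= 2, "n", "must be >= 2")
  stop_field(is.numeric(sem) && sem >= 0, "sem", "must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sem = sem),
            class = "summary_stat")
}

test_result <- function(statistic, df, p_value, method, adjusted = FALSE,
                        ...) {
  structure(list(statistic = statistic, df = df,
                 p_value = min(max(p_value, 0), 1),
                 adjusted = adjusted, method = method, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: t = %.4g, df = %.4g, p = %.4g%s\n",
              x$method, x$statistic, x$df, x$p_value,
              if (x$adjusted) " (adjusted)" else ""))
  invisible(x)
}

#' Two-tailed Student's t-test (pooled variance) on raw data
#'
#' Pooled-variance (classical Student) unpaired test by default, matching
#' the convention of small-n developmental-biology group comparisons; a
#' Welch option is available. The paired test operates on differences.
#' When the pooled variance is zero with equal means, p = 1 by convention.
#'
#' @param a,b Numeric vectors (unpaired: each n >= 2; paired: equal lengths
#'   >= 2).
#' @param paired Logical.
#' @param welch Use Welch's unequal-variance test instead of pooled.
#' @return A `test_result` with `statistic`, `df`, `p_value`, `method`.
#' @export
t_test <- function(a, b, paired = FALSE, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired) {
    if (length(a) != length(b) || length(a) < 2L) {
      stop("paired test needs equal lengths >= 2", call. = FALSE)
    }
    d <- a - b
    n <- length(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
      p <- if (mean(d) == 0) 1 else 0
      return(test_result(if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                         n - 1, p, "paired t-test"))
    }
    tt <- mean(d) / (sdd / sqrt(n))
    return(test_result(tt, n - 1, 2 * stats::pt(-abs(tt), n - 1),
                       "paired t-test"))
  }
  if (length(a) < 2L || length(b) < 2L) {
    stop("unpaired test needs n >= 2 per group", call. = FALSE)
  }
  if (welch) {
    na <- length(a); nb <- length(b)
    va <- stats::var(a); vb <- stats::var(b)
    se2 <- va / na + vb / nb
    if (se2 == 0) {
      p <- if (mean(a) == mean(b)) 1 else 0
      return(test_result(0, na + nb - 2, p, "Welch t-test"))
    }
    tt <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    return(test_result(tt, df, 2 * stats::pt(-abs(tt), df), "Welch t-test"))
  }
  t_test_from_summary(mean_sem(a), mean_sem(b))
}

#' Pooled t-test from printed summaries (n, mean, SEM)
#'
#' Algebraically identical to [t_test()] on raw data whose summaries match.
#' Used to reproduce published p-values from mean +/- SEM figures.
#'
#' @param s1,s2 `summary_stat` objects (each n >= 2).
#' @return A `test_result`.
#' @export
t_test_from_summary <- function(s1, s2) {
  stopifnot(inherits(s1, "summary_stat"), inherits(s2, "summary_stat"))
  n1 <- s1$n; n2 <- s2$n
  v1 <- (s1$sem * sqrt(n1))^2
  v2 <- (s2$sem * sqrt(n2))^2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  if (sp2 == 0) {
    equal <- s1$mean == s2$mean
    return(test_result(if (equal) 0 else Inf * sign(s1$mean - s2$mean), df,
                       if (equal) 1 else 0, "unpaired t-test (pooled)"))
  }
  tt <- (s1$mean - s2$mean) / sqrt(sp2 * (1 / n1 + 1 / n2))
  test_result(tt, df, 2 * stats::pt(-abs(tt), df), "unpaired t-test (pooled)")
}

# Null max-|t| sample for a many-to-one design: k treatment groups compared
# against one control with a pooled variance estimate on df degrees of
# freedom. Returns an n_mc x k matrix of null t statistics.
dunnett_null_t <- function(n_control, n_treat, n_mc) {
  k <- length(n_treat)
  n_all <- c(n_control, n_treat)
  df <- sum(n_all) - (k + 1)
  z0 <- stats::rnorm(n_mc, 0, 1 / sqrt(n_control))
  s2 <- stats::rchisq(n_mc, df) / df
  tmat <- matrix(0, n_mc, k)
  for (j in seq_len(k)) {
    zj <- stats::rnorm(n_mc, 0, 1 / sqrt(n_treat[j]))
    tmat[, j] <- (zj - z0) /
      sqrt(s2 * (1 / n_treat[j] + 1 / n_control))
  }
  tmat
}

#' Dunnett many-to-one comparisons by Monte Carlo
#'
#' Compares each treatment group against a single control with familywise
#' (two-sided) error control. The observed statistics are classical Dunnett
#' t statistics with a pooled variance across all groups; adjusted p-values
#' are tail probabilities of the max-|t| statistic under the joint null,
#' estimated by seeded Monte Carlo rather than table lookup, which handles
#' unbalanced designs uniformly.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param control Name of the control group.
#' @param alpha Familywise level used for the `significant` flag.
#' @param n_mc Monte-Carlo replicates (>= 1000; default 1e5).
#' @param seed Integer seed for the null simulation.
#' @return List of `test_result` objects (one per non-control group), each
#'   with unadjusted `p_unadjusted` and familywise-adjusted `p_value`,
#'   plus attribute `critical_t` (the Monte-Carlo critical value at
#'   `alpha`).
#' @export
dunnett <- function(groups, control = "WT", alpha = 0.05, n_mc = 1e5,
                    seed = 1L) {
  if (!control %in% names(groups)) {
    stop("control group '", control, "' not present", call. = FALSE)
  }
  if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (n_mc < 1e3) stop("n_mc must be >= 1000", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2L)) stop("each group needs n >= 2", call. = FALSE)

  treat <- setdiff(names(groups), control)
  k <- length(treat)
  n0 <- ns[[control]]
  nt <- ns[treat]
  df <- sum(ns) - length(groups)
  sp2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    df
  tobs <- vapply(treat, function(lab) {
    (mean(groups[[lab]]) - mean(groups[[control]])) /
      sqrt(sp2 * (1 / length(groups[[lab]]) + 1 / n0))
  }, numeric(1))

  with_seed(seed, {
    tnull <- dunnett_null_t(n0, nt, n_mc)
    maxt <- apply(abs(tnull), 1, max)
    crit <- stats::quantile(maxt, 1 - alpha, names = FALSE)
    res <- lapply(seq_len(k), function(j) {
      p_adj <- mean(maxt >= abs(tobs[j]))
      p_raw <- 2 * stats::pt(-abs(tobs[j]), df)
      test_result(unname(tobs[j]), df, max(p_adj, p_raw), adjusted = TRUE,
                  method = paste0("Dunnett MC (", treat[j], " vs ",
                                  control, ")"),
                  p_unadjusted = p_raw,
                  significant = abs(tobs[j]) > crit,
                  group = treat[j])
    })
    names(res) <- treat
    attr(res, "critical_t") <- crit
    res
  })
}

#' Monte-Carlo critical value for the balanced many-to-one max-|t| statistic
#'
#' @param n_control,n_treat Group sizes (n_treat a vector, one per treatment
#'   group).
#' @param alpha Familywise level.
#' @param n_mc Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return The two-sided familywise critical value on the t scale.
#' @export
dunnett_critical <- function(n_control, n_treat, alpha = 0.05, n_mc = 1e5,
                             seed = 1L) {
  with_seed(seed, {
    maxt <- apply(abs(dunnett_null_t(n_control, n_treat, n_mc)), 1, max)
    stats::quantile(maxt, 1 - alpha, names = FALSE)
  })
}
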