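#' Percent positive cells in a sorted population
#'
#' @param positive Number of marker-positive cells (>= 0).
#' @param total Total cells (> 0, >= positive).
#' @return Percentage, 100 * positive / total.
#' @export
percent_positive <- function(positive, total) {
  stop_field(is.numeric(total) && total > 0, "total", "must be > 0")
  stop_field(is.numeric(positive) && positive >= 0 && positive <= total,
             "positive", "must be in [0, total]")
  100 * positive / total
}

#' Specification of a DNA-content mixture
#'
#' Describes a propidium-iodide style DNA-content distribution as a
#' three-component mixture: a Gaussian G1 peak at 2N, a Gaussian G2/M peak
#' at `g2_position` times the G1 mean, and an S-phase plateau of cells
#' replicating between the two, broadened by the same coefficient of
#' variation.
#'
#' @param fractions Numeric length-3 `(g1, s, g2)`; non-negative, summing
#'   to 1 within 1e-9.
#' @param cv Coefficient of variation of the 2N peak (> 0).
#' @param n_cells Number of cells to draw (> 0).
#' @param g2_position G2 peak position as a multiple of the G1 mean
#'   (default 2).
#' @return A `dna_histogram_spec`.
#' @export
dna_histogram_spec <- function(fractions, cv = 0.05, n_cells = 10000,
                               g2_position = 2.0) {
  stop_field(length(fractions) == 3 && all(fractions >= 0) &&
               abs(sum(fractions) - 1) <= 1e-9,
             "fractions", "must be 3 non-negative values summing to 1")
  stop_field(cv > 0, "cv", "must be > 0")
  stop_field(n_cells > 0, "n_cells", "must be > 0")
  structure(list(fractions = c(g1 = fractions[1], s = fractions[2],
                               g2 = fractions[3]),
                 cv = cv, n_cells = as.integer(n_cells),
                 g2_position = g2_position),
            class = "dna_histogram_spec")
}

#' Simulate a DNA-content histogram
#'
#' Per-cell DNA content is drawn from the mixture described by the spec
#' (G1 mean fixed at 100 arbitrary units) and binned on a regular grid.
#'
#' @param spec A [dna_histogram_spec()].
#' @param seed Integer seed.
#' @param n_bins Number of bins (default 256) over \[0, 3 x G1 mean\].
#' @return A `dna_histogram`: list with `bin_edges`, `counts` and the
#'   generating `spec`.
#' @export
simulate_dna_histogram <- function(spec, seed = 1L, n_bins = 256L) {
  stopifnot(inherits(spec, "dna_histogram_spec"))
  mu <- 100
  with_seed(seed, {
    phase <- sample(c("g1", "s", "g2"), spec$n_cells, replace = TRUE,
                    prob = spec$fractions)
    content <- numeric(spec$n_cells)
    n1 <- sum(phase == "g1"); n2 <- sum(phase == "g2")
    ns <- sum(phase == "s")
    if (n1) content[phase == "g1"] <- stats::rnorm(n1, mu, spec$cv * mu)
    if (n2) {
      m2 <- spec$g2_position * mu
      content[phase == "g2"] <- stats::rnorm(n2, m2, spec$cv * m2)
    }
    if (ns) {
      u <- stats::runif(ns, mu, spec$g2_position * mu)
      content[phase == "s"] <- stats::rnorm(ns, u, spec$cv * u)
    }
    edges <- seq(0, 3 * mu, length.out = n_bins + 1L)
    content <- pmin(pmax(content, 0), 3 * mu - 1e-9)
    counts <- tabulate(findInterval(content, edges, rightmost.closed = TRUE),
                       nbins = n_bins)
    structure(list(bin_edges = edges, counts = counts, spec = spec),
              class = "dna_histogram")
  })
}

#' Construct a DNA histogram from edges and counts
#' @param bin_edges Increasing numeric vector.
#' @param counts Non-negative integer counts, one fewer than edges.
#' @return A `dna_histogram`.
#' @export
dna_histogram <- function(bin_edges, counts) {
  if (length(counts) != length(bin_edges) - 1L || any(counts < 0) ||
      sum(counts) <= 0 || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("invalid histogram: need increasing edges and positive total count",
         call. = FALSE)
  }
  structure(list(bin_edges = bin_edges, counts = counts),
            class = "dna_histogram")
}

# per-bin probability of the three components at parameters (mu, cv, r);
# the S component integrates the broadened plateau by midpoint quadrature
phase_component_probs <- function(edges, mu, cv, r, n_quad = 32L) {
  p_g1 <- diff(stats::pnorm(edges, mu, cv * mu))
  p_g2 <- diff(stats::pnorm(edges, r * mu, cv * r * mu))
  u <- mu + (seq_len(n_quad) - 0.5) / n_quad * (r * mu - mu)
  p_s <- rowMeans(vapply(u, function(ui) diff(stats::pnorm(edges, ui,
                                                           cv * ui)),
                         numeric(length(edges) - 1L)))
  cbind(g1 = p_g1, s = p_s, g2 = p_g2)
}

#' Estimate G1/S/G2 phase fractions from a DNA-content histogram
#'
#' Least-squares fit of the three-component model (Gaussian G1, Gaussian
#' G2 constrained to 1.9-2.1 times the G1 mean, broadened S plateau in
#' between) to the binned counts. The G1 mean is initialised at the
#' histogram's dominant mode; mixture weights are parameterised by softmax
#' so the estimated fractions always lie in \[0, 1\] and sum to 1.
#'
#' @param hist A `dna_histogram`.
#' @return A `phase_fractions`: list with `g1`, `s`, `g2` (summing to 1),
#'   `g1_mean`, `cv`, `g2_position`, `rss`.
#' @export
estimate_phase_fractions <- function(hist) {
  stopifnot(inherits(hist, "dna_histogram"))
  edges <- hist$bin_edges
  counts <- hist$counts
  if (sum(counts > 0) < 2L) {
    stop("degenerate histogram: fewer than 2 nonzero bins", call. = FALSE)
  }
  n <- sum(counts)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  mu0 <- mids[which.max(counts)]
  # initial gating: below 1.35 mu -> G1, above 1.7 mu -> G2
  f0 <- c(g1 = sum(counts[mids < 1.35 * mu0]),
          s = sum(counts[mids >= 1.35 * mu0 & mids <= 1.7 * mu0]),
          g2 = sum(counts[mids > 1.7 * mu0])) / n
  f0 <- pmax(f0, 1e-3); f0 <- f0 / sum(f0)

  unpack <- function(par) {
    mu <- exp(par[1]); cv <- exp(par[2])
    r <- 1.9 + 0.2 * stats::plogis(par[3])
    w <- exp(c(par[4], par[5], 0))
    list(mu = mu, cv = cv, r = r, f = w / sum(w))
  }
  obj <- function(par) {
    p <- unpack(par)
    if (p$cv < 1e-4 || p$cv > 0.5) return(1e12)
    probs <- phase_component_probs(edges, p$mu, p$cv, p$r)
    pred <- n * as.numeric(probs %*% p$f)
    sum((pred - counts)^2)
  }
  par0 <- c(log(mu0), log(0.05), 0, log(f0[1] / f0[3]), log(f0[2] / f0[3]))
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  p <- unpack(fit$par)
  structure(list(g1 = unname(p$f[1]), s = unname(p$f[2]),
                 g2 = unname(p$f[3]), g1_mean = p$mu, cv = p$cv,
                 g2_position = p$r, rss = fit$value),
            class = "phase_fractions")
}

#' @export
print.phase_fractions <- function(x, ...) {
  cat(sprintf("<phase_fractions> G1 %.1f%%, S %.1f%%, G2 %.1f%% (G1 mean %.3g, cv %.3g)\n",
              100 * x$g1, 100 * x$s, 100 * x$g2, x$g1_mean, x$cv))
  invisible(x)
}

#' Read / write a DNA histogram CSV (`bin_left,bin_right,count`)
#' @param hist A `dna_histogram`.
#' @param path File path.
#' @export
write_histogram_csv <- function(hist, path) {
  e <- hist$bin_edges
  utils::write.csv(data.frame(bin_left = e[-length(e)], bin_right = e[-1],
                              count = hist$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram_csv
#' @export
read_histogram_csv <- function(path) {
  df <- utils::read.csv(path)
  dna_histogram(c(df$bin_left, df$bin_right[nrow(df)]), df$count)
}
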