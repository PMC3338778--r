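test_that("motility_params validates its fields by name", {
  expect_error(motility_params(1.2, 0.5, 1), "p_move_to_pause")
  expect_error(motility_params(0.5, -0.1, 1), "p_pause_to_move")
  expect_error(motility_params(0.5, 0.5, -1), "speed_mean")
  expect_error(motility_params(0.5, 0.5, 1, turn_kappa = -2), "turn_kappa")
})

test_that("simulate_tracks rejects non-positive sizes by name", {
  p <- isotropic_params()
  expect_error(simulate_tracks(p, 0), "n_cells")
  expect_error(simulate_tracks(p, 2, n_points = 0), "n_points")
  expect_error(simulate_tracks(p, 2, dt_min = -5), "dt_min")
})

test_that("degenerate persistent limit gives fixed-length, near-straight steps", {
  p <- motility_params(0, 1, speed_mean = 1, speed_sd = 0,
                       turn_kappa = 1e6, pause_jitter_um = 0)
  ts <- simulate_tracks(p, 3, n_points = 25, dt_min = 5, seed = 7)
  for (t in ts$tracks) {
    steps <- sqrt(rowSums(diff(t$positions)^2))
    expect_equal(steps, rep(5, 24), tolerance = 1e-9)
    # near-straight: D/T close to 1
    expect_gt(directionality_ratio(t), 0.999)
  }
})

test_that("generators are pure functions of (spec, seed)", {
  p <- preset_params("WT")
  expect_identical(simulate_tracks(p, 4, seed = 11),
                   simulate_tracks(p, 4, seed = 11))
  expect_false(identical(simulate_tracks(p, 4, seed = 11),
                         simulate_tracks(p, 4, seed = 12)))
  s1 <- simulate_adhesion_scene(5, 3, seed = 3)
  expect_identical(s1, simulate_adhesion_scene(5, 3, seed = 3))
  spec <- data.frame(gene = "g1", category = "actin", wt_mean = 10,
                     het_mean = 10, mut_mean = 20, noise_sd = 1)
  expect_identical(simulate_expression(spec, seed = 5),
                   simulate_expression(spec, seed = 5))
  ds <- dna_histogram_spec(c(0.5, 0.3, 0.2), n_cells = 500)
  expect_identical(simulate_dna_histogram(ds, seed = 2),
                   simulate_dna_histogram(ds, seed = 2))
})

test_that("two-state chain converges to its stationary moving fraction", {
  p_mp <- 0.12; p_pm <- 0.30
  p <- motility_params(p_mp, p_pm, speed_mean = 1, speed_sd = 0,
                       turn_kappa = 0, pause_jitter_um = 0)
  n_int <- 1e5
  ts <- simulate_tracks(p, 1, n_points = n_int + 1, dt_min = 5, seed = 13)
  steps <- sqrt(rowSums(diff(ts$tracks[[1]]$positions)^2))
  f_hat <- mean(steps > 1e-9)  # moving steps have length 5, paused exactly 0
  f <- p_pm / (p_mp + p_pm)
  # asymptotic SE of the occupancy fraction of a 2-state chain with
  # lag-1 autocorrelation rho = 1 - p_mp - p_pm
  rho <- 1 - p_mp - p_pm
  se <- sqrt(f * (1 - f) * (1 + rho) / (1 - rho) / n_int)
  expect_lt(abs(f_hat - f), 3 * se)
})

test_that("preset_params rejects unknown groups and labels its output", {
  expect_error(preset_params("KO"), "unknown group")
  expect_s3_class(preset_params("MUT"), "motility_params")
  expect_identical(preset_params("HET")$group_label, "HET")
})

test_that("adhesion scenes respect counts, polarity and validation", {
  sc <- simulate_adhesion_scene(3, 0, 2.0, 0, seed = 1)
  expect_equal(nrow(sc$puncta), 3)
  proj <- (sc$puncta$x_um - sc$centroid[1]) * sc$polarity_axis[1] +
    (sc$puncta$y_um - sc$centroid[2]) * sc$polarity_axis[2]
  expect_true(all(proj > 0))
  expect_equal(sqrt(sum(sc$polarity_axis^2)), 1, tolerance = 1e-12)
  expect_true(all(sc$puncta$area_um2 > 0))

  empty <- simulate_adhesion_scene(0, 0, seed = 1)
  expect_equal(nrow(empty$puncta), 0)
  expect_error(simulate_adhesion_scene(-1, 2, seed = 1), "count_leading")
})

test_that("rendering: empty scene is a zero grid, single punctum peaks there", {
  empty <- simulate_adhesion_scene(0, 0, seed = 1)
  img <- render_puncta_image(empty, noise_sd = 0)
  expect_true(all(img == 0))

  one <- simulate_adhesion_scene(1, 0, 2, 0, seed = 2)
  img <- render_puncta_image(one, pixel_size_um = 0.2, noise_sd = 0)
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  org <- attr(img, "origin_um")
  px <- attr(img, "pixel_size_um")
  expect_lt(abs(org[["x"]] + (peak[["col"]] - 1) * px - one$puncta$x_um), px)
  expect_lt(abs(org[["y"]] + (peak[["row"]] - 1) * px - one$puncta$y_um), px)
  expect_error(render_puncta_image(one, pixel_size_um = 0), "pixel_size_um")
})

test_that("zero-noise expression reproduces its spec exactly", {
  spec <- data.frame(gene = c("a", "b"), category = "actin",
                     wt_mean = c(10, 40), het_mean = c(12, 35),
                     mut_mean = c(30, 20), noise_sd = 0)
  expr <- simulate_expression(spec, outlier_rate = 0, seed = 9)
  for (g in seq_len(nrow(spec))) {
    for (geno in c("WT", "HET", "MUT")) {
      v <- expr$value[expr$gene == spec$gene[g] & expr$genotype == geno]
      mu <- spec[[c(WT = "wt_mean", HET = "het_mean",
                    MUT = "mut_mean")[[geno]]]][g]
      expect_identical(v, rep(mu, 3))
    }
  }
})

test_that("outlier_rate = 1 corrupts one replicate per gene x genotype", {
  spec <- data.frame(gene = c("a", "b", "c"), category = "actin",
                     wt_mean = 100, het_mean = 100, mut_mean = 100,
                     noise_sd = 1)
  expr <- simulate_expression(spec, outlier_rate = 1, seed = 17)
  corr <- attr(expr, "corrupted")
  expect_equal(nrow(corr), 9)  # 3 genes x 3 genotypes
  # the downstream filter flags a replicate in every cell
  for (i in seq_len(nrow(corr))) {
    v <- expr$value[expr$gene == corr$gene[i] &
                      expr$genotype == corr$genotype[i]]
    expect_false(is.na(replicate_filter(v)$flagged))
  }
})

test_that("dna histogram spec validation and single-peak limit", {
  expect_error(dna_histogram_spec(c(0.5, 0.5, 0.5)), "fractions")
  spec <- dna_histogram_spec(c(1, 0, 0), cv = 0.01, n_cells = 20000)
  h <- simulate_dna_histogram(spec, seed = 4)
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  expect_lt(abs(mids[which.max(h$counts)] - 100), 2)
  # narrow: 99% of mass within 5% of the peak
  near <- abs(mids - 100) < 5
  expect_gt(sum(h$counts[near]) / sum(h$counts), 0.99)
})
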