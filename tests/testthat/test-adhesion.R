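test_that("detection: blank images, min-area filtering, separated spots", {
  empty <- simulate_adhesion_scene(0, 0, seed = 1)
  img <- render_puncta_image(empty, noise_sd = 0)
  expect_equal(nrow(detect_puncta(img, threshold = 0.05)), 0)

  # one spot whose area falls below the minimum survives thresholding but
  # is filtered out
  one <- simulate_adhesion_scene(1, 0, 0.3, 0, seed = 2)
  img1 <- render_puncta_image(one, pixel_size_um = 0.2, psf_sigma_um = 0.3,
                              noise_sd = 0)
  high <- detect_puncta(img1, threshold = 0.9 * max(img1),
                        min_area_um2 = 10)
  expect_equal(nrow(high), 0)

  # three well-separated spots recovered with centroids within one pixel
  sc <- simulate_adhesion_scene(2, 1, 2, 0, seed = 3, spread_um = 25)
  img3 <- render_puncta_image(sc, pixel_size_um = 0.2, psf_sigma_um = 0.4,
                              noise_sd = 0)
  det <- detect_puncta(img3, threshold = 0.02, min_area_um2 = 0.1)
  expect_equal(nrow(det), 3)
  for (i in seq_len(3)) {
    d <- sqrt((det$x_um - sc$puncta$x_um[i])^2 +
                (det$y_um - sc$puncta$y_um[i])^2)
    expect_lt(min(d), 0.2)
  }
  expect_equal(det$equivalent_diameter_um, sqrt(4 * det$area_um2 / pi),
               tolerance = 1e-12)
  expect_error(detect_puncta(img3, pixel_size_um = -1, threshold = 0.02),
               "pixel_size_um")
})

test_that("edge partition: sides, ties, zero axis, rotation invariance", {
  pn <- data.frame(x_um = c(1, 2, 0.5), y_um = c(0.2, -0.1, 0))
  expect_true(all(partition_edges(pn, c(0, 0), c(1, 0)) == "leading"))

  mirror <- data.frame(x_um = c(2, -2), y_um = c(1, -1))
  expect_equal(partition_edges(mirror, c(0, 0), c(1, 0)),
               c("leading", "trailing"))

  # exact zero projection is assigned trailing (documented tie rule)
  tie <- data.frame(x_um = 0, y_um = 5)
  expect_equal(partition_edges(tie, c(0, 0), c(1, 0)), "trailing")
  expect_error(partition_edges(tie, c(0, 0), c(0, 0)), "non-zero")

  # joint rotation of puncta, centroid and axis leaves the labels alone
  sc <- simulate_adhesion_scene(7, 5, seed = 11)
  lab0 <- partition_edges(sc$puncta, sc$centroid, sc$polarity_axis)
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- as.matrix(sc$puncta[, c("x_um", "y_um")]) %*% t(rot)
  lab1 <- partition_edges(data.frame(x_um = xy[, 1], y_um = xy[, 2]),
                          as.numeric(rot %*% sc$centroid),
                          as.numeric(rot %*% sc$polarity_axis))
  expect_identical(lab0, lab1)
})

test_that("simulated scenes round-trip through partition and detection", {
  sc <- simulate_adhesion_scene(14, 12, 2.14, 0.5, seed = 21)
  lab <- partition_edges(sc$puncta, sc$centroid, sc$polarity_axis)
  expect_equal(sum(lab == "leading"), 14)
  expect_equal(sum(lab == "trailing"), 12)

  prof <- cell_adhesion_profile("c1", sc$puncta, sc$centroid,
                                sc$polarity_axis)
  expect_equal(prof$count_leading + prof$count_trailing, nrow(sc$puncta))
})

test_that("maturity classes follow the nascent/mature size bands", {
  expect_equal(classify_maturity(c(0.5, 3, 1.5, 2, 10, 11)),
               c("nascent", "mature", "intermediate", "mature", "mature",
                 "intermediate"))
  expect_error(classify_maturity(0), "equivalent_diameter_um")
})

test_that("group summary reproduces the published per-cell arithmetic", {
  # 18 cells totalling 475 puncta (255 leading / 220 trailing):
  # per-cell means 26.4, 14.2, 12.2 display as 26, 14, 12
  lead <- c(rep(14, 15), rep(15, 3))   # 255
  trail <- c(rep(12, 14), rep(13, 4))  # 220
  cells <- lapply(seq_len(18), function(i) {
    sc <- simulate_adhesion_scene(lead[i], trail[i], 2.14, 0.3,
                                  seed = 100 + i, cell_id = paste0("c", i))
    cell_adhesion_profile(sc$cell_id, sc$puncta, sc$centroid,
                          sc$polarity_axis)
  })
  summ <- group_adhesion_summary(cells)
  g <- function(m, f) summ[[f]][summ$metric == m]
  expect_equal(g("count_total", "total"), 475)
  expect_equal(g("count_leading", "total"), 255)
  expect_equal(g("count_total", "display"), 26)
  expect_equal(g("count_leading", "display"), 14)
  expect_equal(g("count_trailing", "display"), 12)
  expect_equal(g("count_total", "mean"), 475 / 18, tolerance = 1e-12)

  one <- group_adhesion_summary(cells[1])
  expect_true(is.na(one$sem[one$metric == "count_total"]))
  expect_error(group_adhesion_summary(list()), "no cells")
})

test_that("puncta CSV round trip with sidecar axis", {
  sc <- simulate_adhesion_scene(4, 3, seed = 31)
  f <- tempfile(fileext = ".csv")
  write_puncta_csv(sc, f)
  back <- read_puncta_csv(f)[[1]]
  expect_equal(back$puncta$x_um, sc$puncta$x_um, tolerance = 1e-6)
  expect_equal(back$polarity_axis, sc$polarity_axis, tolerance = 1e-6)
  lab0 <- partition_edges(sc$puncta, sc$centroid, sc$polarity_axis)
  lab1 <- partition_edges(back$puncta, back$centroid, back$polarity_axis)
  expect_identical(lab0, lab1)
  unlink(c(f, paste0(f, ".axis.csv")))
})
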