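#' Simulate a focal-adhesion puncta scene for one cell
#'
#' Places `count_leading` puncta with strictly positive projection on the
#' cell's polarity axis and `count_trailing` with strictly negative
#' projection, at known ground truth, so detection and edge partitioning can
#' be validated by round trip. Puncta areas are truncated-normal in um^2.
#'
#' @param count_leading,count_trailing Non-negative puncta counts.
#' @param size_mean_um2,size_sd_um2 Mean and SD of punctum area (um^2);
#'   draws are truncated below at 0.05 um^2.
#' @param seed Integer seed.
#' @param cell_id Identifier (default `"cell1"`).
#' @param spread_um Spatial spread of puncta along and across the axis.
#' @return An `adhesion_scene`: list with `cell_id`, `centroid`,
#'   `polarity_axis` (unit vector), `puncta` (data frame `x_um,y_um,
#'   area_um2`) and `truth_counts = c(leading, trailing)`.
#' @export
simulate_adhesion_scene <- function(count_leading, count_trailing,
                                    size_mean_um2 = 3, size_sd_um2 = 0.5,
                                    seed = 1L, cell_id = "cell1",
                                    spread_um = 10) {
  stop_field(is.numeric(count_leading) && count_leading >= 0,
             "count_leading", "must be >= 0")
  stop_field(is.numeric(count_trailing) && count_trailing >= 0,
             "count_trailing", "must be >= 0")
  stop_field(size_mean_um2 > 0, "size_mean_um2", "must be > 0")
  stop_field(size_sd_um2 >= 0, "size_sd_um2", "must be >= 0")
  nl <- as.integer(count_leading); nt <- as.integer(count_trailing)

  with_seed(seed, {
    theta <- stats::runif(1, -pi, pi)
    axis <- c(cos(theta), sin(theta))
    centroid <- c(0, 0)
    n <- nl + nt
    # along-axis coordinate strictly positive (leading) / negative (trailing)
    along <- c(0.5 + abs(stats::rnorm(nl, 0, spread_um / 2)),
               -(0.5 + abs(stats::rnorm(nt, 0, spread_um / 2))))
    across <- stats::rnorm(n, 0, spread_um / 2)
    perp <- c(-axis[2], axis[1])
    xy <- cbind(centroid[1] + along * axis[1] + across * perp[1],
                centroid[2] + along * axis[2] + across * perp[2])
    areas <- pmax(0.05, stats::rnorm(n, size_mean_um2, size_sd_um2))
    puncta <- data.frame(x_um = xy[, 1][seq_len(n)],
                         y_um = xy[, 2][seq_len(n)],
                         area_um2 = areas[seq_len(n)])
    structure(list(cell_id = cell_id, centroid = centroid,
                   polarity_axis = axis, puncta = puncta,
                   truth_counts = c(leading = nl, trailing = nt)),
              class = "adhesion_scene")
  })
}

#' Render a puncta scene as a 2-D intensity image
#'
#' Each punctum becomes an isotropic Gaussian blob centred at its position
#' with SD `psf_sigma_um` and integrated intensity proportional to its area;
#' Gaussian read noise is added per pixel. The grid covers the puncta
#' bounding box plus a margin.
#'
#' @param scene An `adhesion_scene`.
#' @param pixel_size_um Pixel pitch (> 0), default 0.2.
#' @param psf_sigma_um Blob SD in um, default 0.4.
#' @param noise_sd Additive Gaussian noise SD (intensity units), default 0.
#' @param seed Integer seed (used only for the noise).
#' @param margin_um Margin beyond the bounding box, default 3.
#' @return Numeric matrix of intensities with attributes `pixel_size_um`,
#'   `origin_um` (world coordinates of pixel (1,1) centre).
#' @export
render_puncta_image <- function(scene, pixel_size_um = 0.2,
                                psf_sigma_um = 0.4, noise_sd = 0,
                                seed = 1L, margin_um = 3) {
  stopifnot(inherits(scene, "adhesion_scene"))
  stop_field(pixel_size_um > 0, "pixel_size_um", "must be > 0")
  p <- scene$puncta
  if (nrow(p)) {
    xr <- range(p$x_um) + c(-margin_um, margin_um)
    yr <- range(p$y_um) + c(-margin_um, margin_um)
  } else {
    xr <- c(-margin_um, margin_um); yr <- c(-margin_um, margin_um)
  }
  nx <- max(2L, ceiling(diff(xr) / pixel_size_um))
  ny <- max(2L, ceiling(diff(yr) / pixel_size_um))
  xs <- xr[1] + (seq_len(nx) - 0.5) * pixel_size_um
  ys <- yr[1] + (seq_len(ny) - 0.5) * pixel_size_um
  img <- matrix(0, ny, nx)  # row = y, col = x
  for (i in seq_len(nrow(p))) {
    gx <- stats::dnorm(xs, p$x_um[i], psf_sigma_um)
    gy <- stats::dnorm(ys, p$y_um[i], psf_sigma_um)
    img <- img + p$area_um2[i] * (gy %o% gx) * pixel_size_um^2
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(stats::rnorm(nx * ny, 0, noise_sd),
                                        ny, nx))
  }
  attr(img, "pixel_size_um") <- pixel_size_um
  attr(img, "origin_um") <- c(x = xs[1], y = ys[1])
  img
}

# two-pass 8-connectivity labelling via union-find on a binary matrix
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (x in seq_len(nx)) {
    for (y in seq_len(ny)) {
      if (!mask[y, x]) next
      nb <- integer(0)
      if (y > 1 && mask[y - 1, x]) nb <- c(nb, lab[y - 1, x])
      if (x > 1) {
        if (mask[y, x - 1]) nb <- c(nb, lab[y, x - 1])
        if (y > 1 && mask[y - 1, x - 1]) nb <- c(nb, lab[y - 1, x - 1])
        if (y < ny && mask[y + 1, x - 1]) nb <- c(nb, lab[y + 1, x - 1])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[y, x] <- nxt
      } else {
        roots <- unique(vapply(nb, find, integer(1)))
        r <- min(roots)
        lab[y, x] <- r
        for (o in roots[roots != r]) parent[o] <- r
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

#' Detect puncta in an intensity image
#'
#' Absolute threshold, 8-connected components, minimum-area filter;
#' per-component intensity-weighted centroid and pixel area, converted to
#' physical units. Equivalent diameter is sqrt(4 area / pi).
#'
#' @param image Numeric matrix from [render_puncta_image()] (or any raster
#'   with the same attributes; if absent, `pixel_size_um` must be given and
#'   the origin is assumed at half a pixel).
#' @param pixel_size_um Pixel pitch (> 0); defaults to the image attribute.
#' @param threshold Absolute intensity threshold.
#' @param min_area_um2 Components smaller than this are discarded.
#' @return Data frame `x_um,y_um,area_um2,equivalent_diameter_um`, one row
#'   per punctum.
#' @export
detect_puncta <- function(image, pixel_size_um = attr(image, "pixel_size_um"),
                          threshold, min_area_um2 = 0.1) {
  if (is.null(pixel_size_um) || !is.numeric(pixel_size_um) ||
      pixel_size_um <= 0) {
    stop("`pixel_size_um` must be > 0", call. = FALSE)
  }
  origin <- attr(image, "origin_um")
  if (is.null(origin)) origin <- c(x = pixel_size_um / 2,
                                   y = pixel_size_um / 2)
  mask <- image > threshold
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) {
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0),
                      equivalent_diameter_um = numeric(0)))
  }
  out <- lapply(seq_len(k), function(j) {
    idx <- which(lab == j, arr.ind = TRUE)
    area <- nrow(idx) * pixel_size_um^2
    if (area < min_area_um2) return(NULL)
    w <- image[lab == j]
    w <- pmax(w, 0); if (sum(w) == 0) w <- rep(1, length(w))
    cx <- origin[["x"]] + (sum(w * (idx[, 2] - 1)) / sum(w)) * pixel_size_um
    cy <- origin[["y"]] + (sum(w * (idx[, 1] - 1)) / sum(w)) * pixel_size_um
    data.frame(x_um = cx, y_um = cy, area_um2 = area,
               equivalent_diameter_um = sqrt(4 * area / pi))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(x_um = numeric(0), y_um = numeric(0),
                                      area_um2 = numeric(0),
                                      equivalent_diameter_um = numeric(0))
  rownames(out) <- NULL
  out
}

#' Partition puncta into leading and trailing edges
#'
#' A punctum is leading when its projection on the polarity axis (relative
#' to the cell centroid) is strictly positive; exact zeros are assigned
#' trailing (deterministic tie rule). The axis is normalised internally.
#'
#' @param puncta Data frame with `x_um`, `y_um` columns.
#' @param centroid Numeric length-2 cell centroid (um).
#' @param polarity_axis Numeric length-2 vector with non-zero norm.
#' @return Character vector `"leading"`/`"trailing"`, one per punctum.
#' @export
partition_edges <- function(puncta, centroid, polarity_axis) {
  nrm <- sqrt(sum(polarity_axis^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("polarity axis must have non-zero norm", call. = FALSE)
  }
  ax <- polarity_axis / nrm
  proj <- (puncta$x_um - centroid[1]) * ax[1] +
    (puncta$y_um - centroid[2]) * ax[2]
  ifelse(proj > 0, "leading", "trailing")
}

#' Classify focal-adhesion maturity from equivalent diameter
#'
#' Nascent adhesions are small transient structures under 1 um; mature
#' adhesions, coupled to actin stress fibres, span 2-10 um. Diameters in
#' between (or above 10 um) are reported as intermediate.
#'
#' @param equivalent_diameter_um Numeric vector of diameters (um).
#' @return Character vector `"nascent"`/`"intermediate"`/`"mature"`.
#' @export
classify_maturity <- function(equivalent_diameter_um) {
  d <- equivalent_diameter_um
  stop_field(all(d > 0), "equivalent_diameter_um", "must be > 0")
  out <- rep("intermediate", length(d))
  out[d < 1] <- "nascent"
  out[d >= 2 & d <= 10] <- "mature"
  out
}

#' Per-cell adhesion profile
#'
#' @param cell_id Identifier.
#' @param puncta Data frame with `x_um,y_um,area_um2`.
#' @param centroid,polarity_axis Passed to [partition_edges()].
#' @return A `cell_adhesion_profile`: list with per-punctum edge labels,
#'   counts and mean equivalent diameters per edge (NA for empty edges).
#' @export
cell_adhesion_profile <- function(cell_id, puncta, centroid, polarity_axis) {
  edge <- partition_edges(puncta, centroid, polarity_axis)
  dia <- sqrt(4 * puncta$area_um2 / pi)
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  structure(list(
    cell_id = cell_id, puncta = puncta, edge_of = edge,
    count_leading = sum(edge == "leading"),
    count_trailing = sum(edge == "trailing"),
    mean_size_leading_um = mean_or_na(dia[edge == "leading"]),
    mean_size_trailing_um = mean_or_na(dia[edge == "trailing"])
  ), class = "cell_adhesion_profile")
}

#' Group summary of adhesion counts and sizes
#'
#' Integer totals plus per-cell mean and SEM of counts and mean sizes,
#' overall and per edge. Display columns round half away from zero, the
#' convention of the published tables.
#'
#' @param cells List of `cell_adhesion_profile` objects (>= 1).
#' @return A data frame with one row per metric: `metric`, `total`,
#'   `mean`, `sem`, `n`, `display` (rounded mean).
#' @export
group_adhesion_summary <- function(cells) {
  if (!length(cells)) stop("no cells supplied", call. = FALSE)
  stopifnot(all(vapply(cells, inherits, logical(1), "cell_adhesion_profile")))
  n <- length(cells)
  get <- function(f) vapply(cells, f, numeric(1))
  counts_all <- get(function(c) c$count_leading + c$count_trailing)
  counts_lead <- get(function(c) c$count_leading)
  counts_trail <- get(function(c) c$count_trailing)
  size_all <- get(function(c) {
    d <- sqrt(4 * c$puncta$area_um2 / pi)
    if (length(d)) mean(d) else NA_real_
  })
  size_lead <- get(function(c) c$mean_size_leading_um)
  size_trail <- get(function(c) c$mean_size_trailing_um)

  row <- function(metric, v, total = NA_real_, digits = 0L) {
    v_ok <- v[!is.na(v)]
    m <- if (length(v_ok)) mean(v_ok) else NA_real_
    s <- if (length(v_ok) >= 2) stats::sd(v_ok) / sqrt(length(v_ok))
         else NA_real_
    data.frame(metric = metric, total = total, mean = m, sem = s,
               n = length(v_ok), display = round_half_away(m, digits),
               stringsAsFactors = FALSE)
  }
  rbind(
    row("count_total", counts_all, sum(counts_all)),
    row("count_leading", counts_lead, sum(counts_lead)),
    row("count_trailing", counts_trail, sum(counts_trail)),
    row("size_um", size_all, digits = 2L),
    row("size_leading_um", size_lead, digits = 2L),
    row("size_trailing_um", size_trail, digits = 2L)
  )
}

#' Read / write puncta CSV (`cell_id,x_um,y_um,area_um2`) with an optional
#' sidecar (`cell_id,cx,cy,axis_x,axis_y`) giving centroid and polarity axis
#'
#' @param scene An `adhesion_scene`.
#' @param path Puncta CSV path.
#' @param sidecar_path Sidecar CSV path (default `path` + `.axis.csv`).
#' @return `write_puncta_csv`: `path`, invisibly. `read_puncta_csv`: a list
#'   of `adhesion_scene` objects (truth counts unknown, set to NA).
#' @export
write_puncta_csv <- function(scene, path,
                             sidecar_path = paste0(path, ".axis.csv")) {
  df <- cbind(cell_id = scene$cell_id, scene$puncta)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- data.frame(cell_id = scene$cell_id,
                     cx = scene$centroid[1], cy = scene$centroid[2],
                     axis_x = scene$polarity_axis[1],
                     axis_y = scene$polarity_axis[2])
  utils::write.csv(side, sidecar_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_puncta_csv
#' @export
read_puncta_csv <- function(path, sidecar_path = paste0(path, ".axis.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- utils::read.csv(sidecar_path, stringsAsFactors = FALSE)
  lapply(split(df, df$cell_id), function(d) {
    s <- side[side$cell_id == d$cell_id[1], ]
    structure(list(cell_id = d$cell_id[1],
                   centroid = c(s$cx[1], s$cy[1]),
                   polarity_axis = c(s$axis_x[1], s$axis_y[1]),
                   puncta = d[, c("x_um", "y_um", "area_um2")],
                   truth_counts = c(leading = NA_integer_,
                                    trailing = NA_integer_)),
              class = "adhesion_scene")
  })
}
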