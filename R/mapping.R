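# Shape-space maps: PCA of similarity fingerprints, 300x300 binning,
# per-pixel property statistics, HSL and rod/disc/sphere color coding.

#' PCA projection of similarity fingerprints
#'
#' Mean-centered covariance PCA (via [stats::prcomp()]) of the
#' similarity-fingerprint matrix, returning per-entry scores on the
#' first two components. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param simfp a similarity-fingerprint tibble
#'   ([similarity_fingerprints()]) or any tibble of `entry_id` plus
#'   numeric columns.
#' @return a tibble `entry_id`, `PC1`, `PC2` with the fitted model (a
#'   `shape_pca` object) in the `"model"` attribute.
#' @export
pca_project <- function(simfp) {
  num <- simfp[, vapply(simfp, is.numeric, logical(1)), drop = FALSE]
  m <- as.matrix(num)
  if (nrow(m) < 3) abort_contract("PCA needs at least 3 entries")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(fit$rotation))) {
    k <- which.max(abs(fit$rotation[, j]))
    if (fit$rotation[k, j] < 0) {
      fit$rotation[, j] <- -fit$rotation[, j]
      fit$x[, j] <- -fit$x[, j]
    }
  }
  model <- structure(
    list(
      sdev = fit$sdev, rotation = fit$rotation, center = fit$center,
      input_dim = ncol(m), n = nrow(m)
    ),
    class = "shape_pca"
  )
  n_pc <- ncol(fit$x)
  out <- tibble(
    entry_id = simfp$entry_id %||% paste0("row", seq_len(nrow(m))),
    PC1 = fit$x[, 1],
    PC2 = if (n_pc >= 2) fit$x[, 2] else 0
  )
  attr(out, "model") <- model
  out
}

#' @export
print.shape_pca <- function(x, ...) {
  ev <- x$sdev^2 / sum(x$sdev^2)
  cat(sprintf("shape-space PCA: %d entries, %d dims; PC1+PC2 explain %.1f%% of variance\n",
              x$n, x$input_dim, 100 * sum(ev[1:min(2, length(ev))])))
  invisible(x)
}

#' Tidy a shape-space PCA model
#'
#' @param x a `shape_pca` model (the `"model"` attribute of
#'   [pca_project()] output).
#' @param ... unused.
#' @return `tidy()`: one row per component with standard deviation and
#'   explained-variance fraction; `glance()`: a one-row model summary.
#' @export
#' @exportS3Method generics::tidy
tidy.shape_pca <- function(x, ...) {
  ev <- x$sdev^2 / sum(x$sdev^2)
  tibble(
    component = seq_along(x$sdev),
    std_dev = x$sdev,
    variance_fraction = ev,
    cumulative_variance = cumsum(ev)
  )
}

#' @rdname tidy.shape_pca
#' @export
#' @exportS3Method generics::glance
glance.shape_pca <- function(x, ...) {
  ev <- x$sdev^2 / sum(x$sdev^2)
  tibble(
    n = x$n, input_dim = x$input_dim,
    var_pc1 = ev[1], var_pc2 = if (length(ev) >= 2) ev[2] else 0,
    var_pc12 = sum(ev[1:min(2, length(ev))])
  )
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Bin PCA scores onto a square map grid
#'
#' One absolute bin width is used for both axes: the global extremes
#' over the joint PC1/PC2 values define the range `dPC = pc_max -
#' pc_min` and the bin width `dPC / grid_size`. Pixel indices are
#' 0-based, `floor((pc - pc_min) / width)`, clamped so the maximum falls
#' in the last bin. A degenerate zero range sends everything to pixel
#' (0, 0).
#'
#' @param scores a tibble with `entry_id`, `PC1`, `PC2`.
#' @param grid_size pixels per side (default 300).
#' @return a `map_grid` tibble `entry_id`, `PC1`, `PC2`, `ix`, `iy`
#'   with grid metadata in attributes `grid_size`, `pc_min`, `pc_max`,
#'   `bin_width`.
#' @export
bin_to_grid <- function(scores, grid_size = 300L) {
  if (nrow(scores) < 1) abort_contract("no entries to bin")
  pc <- c(scores$PC1, scores$PC2)
  if (any(!is.finite(pc))) abort_contract("non-finite PC scores")
  pc_min <- min(pc)
  pc_max <- max(pc)
  dpc <- pc_max - pc_min
  if (dpc <= 0) {
    ix <- iy <- rep(0L, nrow(scores))
    w <- 0
  } else {
    w <- dpc / grid_size
    clampbin <- function(v) pmin(as.integer(floor((v - pc_min) / w)), grid_size - 1L)
    ix <- clampbin(scores$PC1)
    iy <- clampbin(scores$PC2)
  }
  out <- tibble(entry_id = scores$entry_id, PC1 = scores$PC1, PC2 = scores$PC2,
                ix = ix, iy = iy)
  attr(out, "grid_size") <- as.integer(grid_size)
  attr(out, "pc_min") <- pc_min
  attr(out, "pc_max") <- pc_max
  attr(out, "bin_width") <- w
  class(out) <- c("map_grid", class(out))
  out
}

#' Molecular volume occupancy
#'
#' A compactness descriptor: the volume of the sphere whose radius is
#' the mean atom-to-centroid distance, divided by the atom count
#' (Angstrom^3 per atom). Compact globular structures score low,
#' extended ones high.
#'
#' @param structure a `pdb_structure` (heavy atoms).
#' @return mvo in Angstrom^3 per atom.
#' @export
#' @examples
#' mvo(make_point_cloud(cbind(c(0, 2), 0, 0))) # two atoms 2 A apart
mvo <- function(structure) {
  p <- coords_matrix(structure)
  n <- nrow(p)
  ctr <- colMeans(p)
  d_avg <- mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
  (4 / 3) * pi * d_avg^3 / n
}

#' Normalized principal moments of inertia
#'
#' Eigenvalues I1 <= I2 <= I3 of the unit-mass inertia tensor about the
#' centroid, reported as (I1/I3, I2/I3). The pair locates a shape in
#' the rod-disc-sphere triangle: a collinear rod gives (0, 1), a flat
#' disc (0.5, 0.5), a sphere-like shape (1, 1). A single point (zero
#' tensor) is defined as (1, 1). Unit masses keep the descriptor purely
#' geometric, consistent with the other shape descriptors.
#'
#' @param structure a `pdb_structure`.
#' @return a named numeric vector `c(npmi1, npmi2)`.
#' @export
npmi <- function(structure) {
  p <- coords_matrix(structure)
  q <- sweep(p, 2, colMeans(p))
  r2 <- rowSums(q^2)
  it <- diag(3) * sum(r2) - crossprod(q)
  ev <- sort(eigen(it, symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)
  if (ev[3] <= 0) return(c(npmi1 = 1, npmi2 = 1))
  c(npmi1 = ev[1] / ev[3], npmi2 = ev[2] / ev[3])
}

#' Per-entry property table for map coloring
#'
#' Computes for one preprocessed structure the properties aggregated at
#' map pixels: heavy-atom count, the fractions of positively charged,
#' negatively charged and hydrophobic atoms, the molecular volume
#' occupancy, and the normalized principal moments of inertia.
#'
#' @param structure a preprocessed `pdb_structure` (categories assigned
#'   on the fly if absent).
#' @return a one-row tibble `entry_id`, `hac`, `frac_positive`,
#'   `frac_negative`, `frac_hydrophobic`, `mvo`, `npmi1`, `npmi2`.
#' @export
structure_properties <- function(structure) {
  if (is.null(structure$is_positive)) structure <- assign_categories(structure)
  n <- nrow(structure)
  pm <- npmi(structure)
  tibble(
    entry_id = attr(structure, "entry_id") %||% NA_character_,
    hac = n,
    frac_positive = sum(structure$is_positive) / n,
    frac_negative = sum(structure$is_negative) / n,
    frac_hydrophobic = sum(structure$is_hydrophobic) / n,
    mvo = mvo(structure),
    npmi1 = pm[["npmi1"]],
    npmi2 = pm[["npmi2"]]
  )
}

map_properties <- c("hac", "frac_positive", "frac_negative", "frac_hydrophobic", "mvo")

#' Per-pixel property statistics of a map grid
#'
#' Joins the binned entries with their property table and aggregates
#' each occupied pixel: occupancy count, arithmetic mean and population
#' standard deviation of each scalar property, and mean nPMI
#' coordinates. The population (not sample) standard deviation keeps
#' single-entry pixels well defined (sd = 0).
#'
#' @param grid a `map_grid` ([bin_to_grid()]).
#' @param properties property rows ([structure_properties()]) covering
#'   every binned entry.
#' @return a tibble with one row per occupied pixel: `ix`, `iy`,
#'   `count`, `<property>_avg`, `<property>_sd`, `npmi1_avg`,
#'   `npmi2_avg`.
#' @export
pixel_statistics <- function(grid, properties) {
  joined <- dplyr::left_join(as_tibble(grid), properties, by = "entry_id")
  if (anyNA(joined$hac)) {
    abort_contract("properties missing for some binned entries")
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  joined %>%
    dplyr::group_by(.data$ix, .data$iy) %>%
    dplyr::summarise(
      count = dplyr::n(),
      dplyr::across(dplyr::all_of(map_properties),
                    list(avg = mean, sd = pop_sd), .names = "{.col}_{.fn}"),
      npmi1_avg = mean(.data$npmi1),
      npmi2_avg = mean(.data$npmi2),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$ix, .data$iy)
}

map_schemes <- c("occupancy", "hac", "mvo", "frac_positive", "frac_negative",
                 "frac_hydrophobic", "npmi")

#' Color map pixels by a property scheme
#'
#' HSL schemes (occupancy and the scalar properties) map the pixel
#' average linearly onto the hue path blue - cyan - green - yellow -
#' red - magenta (240 degrees down to -60), with the value range taken
#' between the 1st and 99th percentile of pixel averages (or the global
#' min/max with `normalize = "global"`); saturation fades to grey as
#' the pixel standard deviation grows relative to its 99th percentile;
#' lightness is 0.5. The `"npmi"` scheme colors by closeness of the
#' mean (nPMI1, nPMI2) point to the triangle summits: red for the rod
#' (0, 1), green for the sphere (1, 1), blue for the disc (0.5, 0.5).
#'
#' @param stats pixel statistics from [pixel_statistics()].
#' @param scheme one of `r paste0('"', map_schemes, '"', collapse = ", ")`.
#' @param normalize `"percentile"` (1st-99th, outlier-resistant) or
#'   `"global"` (min/max).
#' @return `stats` with columns `R`, `G`, `B` (0-255 integers) added.
#' @export
color_pixels <- function(stats, scheme = "occupancy",
                         normalize = c("percentile", "global")) {
  scheme <- match.arg(scheme, map_schemes)
  normalize <- match.arg(normalize)
  if (scheme == "npmi") {
    summits <- rbind(rod = c(0, 1), sphere = c(1, 1), disc = c(0.5, 0.5))
    max_pair <- max(stats::dist(summits))
    pt <- cbind(stats$npmi1_avg, stats$npmi2_avg)
    chan <- vapply(1:3, function(k) {
      d <- sqrt((pt[, 1] - summits[k, 1])^2 + (pt[, 2] - summits[k, 2])^2)
      pmax(0, pmin(1, 1 - d / max_pair))
    }, numeric(nrow(stats)))
    if (nrow(stats) == 1) chan <- matrix(chan, nrow = 1)
    rgb01 <- chan
  } else {
    if (scheme == "occupancy") {
      avg <- as.numeric(stats$count)
      sd <- rep(0, nrow(stats))
    } else {
      avg <- stats[[paste0(scheme, "_avg")]]
      sd <- stats[[paste0(scheme, "_sd")]]
    }
    rng <- if (normalize == "percentile") {
      stats::quantile(avg, c(0.01, 0.99), names = FALSE)
    } else {
      range(avg)
    }
    if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
    t <- pmax(0, pmin(1, (avg - rng[1]) / (rng[2] - rng[1])))
    hue <- 240 - 300 * t
    sd99 <- stats::quantile(sd, 0.99, names = FALSE)
    sat <- if (sd99 > 0) 1 - pmin(1, sd / sd99) else rep(1, length(sd))
    rgb01 <- hsl_to_rgb(hue, sat, rep(0.5, length(hue)))
  }
  stats$R <- as.integer(round(rgb01[, 1] * 255))
  stats$G <- as.integer(round(rgb01[, 2] * 255))
  stats$B <- as.integer(round(rgb01[, 3] * 255))
  attr(stats, "scheme") <- scheme
  stats
}

#' Render a map to a PNG image and a pixel table
#'
#' Writes a `grid_size` x `grid_size` PNG (empty pixels white, the
#' y/PC2 axis pointing up) and a tab-separated pixel table with
#' occupancy, property averages and standard deviations, and the RGB
#' color of each occupied pixel.
#'
#' @param grid a `map_grid`.
#' @param stats pixel statistics ([pixel_statistics()]).
#' @param scheme color scheme, see [color_pixels()].
#' @param png_path,tsv_path output paths (either may be `NULL` to
#'   skip).
#' @param normalize passed to [color_pixels()].
#' @return invisibly, the colored pixel table.
#' @export
render_map <- function(grid, stats, scheme = "occupancy",
                       png_path = NULL, tsv_path = NULL,
                       normalize = "percentile") {
  gs <- attr(grid, "grid_size")
  colored <- color_pixels(stats, scheme, normalize)
  if (!is.null(png_path)) {
    img <- array(1, dim = c(gs, gs, 3))
    row <- gs - colored$iy # iy = 0 at the bottom
    col <- colored$ix + 1L
    idx <- cbind(row, col)
    img[cbind(idx, 1)] <- colored$R / 255
    img[cbind(idx, 2)] <- colored$G / 255
    img[cbind(idx, 3)] <- colored$B / 255
    ok <- tryCatch({
      png::writePNG(img, png_path)
      TRUE
    }, error = function(e) abort_input(sprintf("cannot write PNG '%s': %s",
                                               png_path, conditionMessage(e))))
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(colored, tsv_path, progress = FALSE)
  }
  invisible(colored)
}

#' Locate an entry on a map grid
#'
#' @param grid a `map_grid`.
#' @param entry one entry id present in the grid.
#' @return a list: `ix`, `iy` and `entries`, the ids sharing the pixel
#'   (including the query).
#' @export
locate_entry <- function(grid, entry) {
  hit <- which(grid$entry_id == entry)
  if (length(hit) == 0) abort_notfound(sprintf("entry '%s' not on the map", entry))
  ix <- grid$ix[hit[1]]
  iy <- grid$iy[hit[1]]
  list(ix = ix, iy = iy, entries = grid$entry_id[grid$ix == ix & grid$iy == iy])
}

#' Plot a shape-space map with ggplot2
#'
#' @param object a `map_grid`.
#' @param stats optional pixel statistics; computed occupancy-only when
#'   omitted.
#' @param scheme color scheme, see [color_pixels()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.map_grid <- function(object, stats = NULL, scheme = "occupancy", ...) {
  if (is.null(stats)) {
    colored <- object %>%
      as_tibble() %>%
      dplyr::count(.data$ix, .data$iy, name = "count")
    colored$hex <- grDevices::gray(1 - pmin(1, colored$count / max(colored$count)))
  } else {
    colored <- color_pixels(stats, scheme)
    colored$hex <- grDevices::rgb(colored$R, colored$G, colored$B, maxColorValue = 255)
  }
  ggplot2::ggplot(colored, ggplot2::aes(x = .data$ix, y = .data$iy)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hex)) +
    ggplot2::scale_fill_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "PC1 pixel", y = "PC2 pixel") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
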