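test_that("PCA projection matches a covariance eigendecomposition oracle", {
  m <- withr::with_seed(21, matrix(stats::rnorm(500), 50, 10))
  sim <- dplyr::bind_cols(tibble::tibble(entry_id = sprintf("e%02d", 1:50)),
                          tibble::as_tibble(m, .name_repair = "minimal"))
  names(sim)[-1] <- paste0("S_", 1:10)
  pr <- pca_project(sim)
  model <- attr(pr, "model")
  # eigenvalue oracle: direct covariance eigendecomposition
  ev_oracle <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(model$sdev^2, ev_oracle, tolerance = 1e-10)
  # projecting through all components reconstructs the centered data
  centered <- sweep(m, 2, colMeans(m))
  scores_all <- centered %*% model$rotation
  expect_equal(scores_all %*% t(model$rotation), centered,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(pr$PC1, scores_all[, 1], ignore_attr = TRUE)
  # loadings orthonormal, variance fractions sane
  expect_equal(crossprod(model$rotation), diag(10), tolerance = 1e-10, ignore_attr = TRUE)
  td <- tidy(model)
  expect_true(all(td$variance_fraction >= 0 & td$variance_fraction <= 1))
  expect_true(all(diff(td$variance_fraction) <= 1e-12))
  expect_equal(sum(td$variance_fraction), 1, tolerance = 1e-12)
})

test_that("degenerate PCA inputs behave predictably", {
  same <- dplyr::bind_cols(tibble::tibble(entry_id = paste0("e", 1:5)),
                           tibble::as_tibble(matrix(3, 5, 4, dimnames = list(NULL, paste0("S_", 1:4)))))
  pr <- pca_project(same)
  expect_equal(pr$PC1, rep(0, 5), tolerance = 1e-12)
  # rank-1 data: PC1 explains everything, PC2 scores vanish
  t <- 1:6
  r1 <- dplyr::bind_cols(tibble::tibble(entry_id = paste0("e", 1:6)),
                         tibble::as_tibble(outer(t, c(1, 2, -1)), .name_repair = "minimal"))
  names(r1)[-1] <- paste0("S_", 1:3)
  pr1 <- pca_project(r1)
  g <- glance(attr(pr1, "model"))
  expect_equal(g$var_pc1, 1, tolerance = 1e-10)
  expect_equal(pr1$PC2, rep(0, 6), tolerance = 1e-8)
  expect_error(pca_project(same[1:2, ]), class = "pdbshape_error_contract")
})

test_that("grid binning uses one absolute bin width with a clamped top edge", {
  scores <- tibble::tibble(entry_id = c("a", "b", "c"),
                           PC1 = c(0, 3, 1.505), PC2 = c(0, 1, 0.2))
  g <- bin_to_grid(scores, grid_size = 300)
  expect_equal(attr(g, "bin_width"), 0.01) # range 0..3 over both axes
  expect_equal(g$ix[1], 0)
  expect_equal(g$iy[1], 0)
  expect_equal(g$ix[2], 299) # pc_max clamps into the last bin
  expect_equal(g$ix[3], 150)
  # conservation on uniform random scores
  sc <- withr::with_seed(31, tibble::tibble(
    entry_id = paste0("e", 1:500), PC1 = stats::runif(500), PC2 = stats::runif(500)
  ))
  gg <- bin_to_grid(sc, grid_size = 40)
  expect_equal(nrow(gg), 500)
  expect_true(all(gg$ix >= 0 & gg$ix <= 39 & gg$iy >= 0 & gg$iy <= 39))
  counts <- dplyr::count(tibble::as_tibble(gg), ix, iy)
  expect_equal(sum(counts$n), 500)
  # degenerate zero range
  flat <- bin_to_grid(tibble::tibble(entry_id = "a", PC1 = 2, PC2 = 2))
  expect_equal(c(flat$ix, flat$iy), c(0L, 0L))
})

test_that("molecular volume occupancy follows the sphere formula", {
  expect_equal(mvo(make_point_cloud(matrix(0, 1, 3))), 0)
  two <- make_point_cloud(cbind(c(0, 2), 0, 0)) # d_avg = 1
  expect_equal(mvo(two), (4 / 3) * pi / 2, tolerance = 1e-12)
  s <- random_cloud(100, 5)
  k <- 2.5
  scaled <- make_point_cloud(as.matrix(s[, c("x", "y", "z")]) * k)
  expect_equal(mvo(scaled), k^3 * mvo(s), tolerance = 1e-10)
  moved <- pdbshape:::transform_structure(s, pdbshape:::random_rotation(2), c(5, -1, 9))
  expect_equal(mvo(moved), mvo(s), tolerance = 1e-10)
})

test_that("normalized inertia moments locate canonical shapes in the triangle", {
  rod <- make_point_cloud(cbind(seq(0, 49), 0, 0))
  expect_equal(npmi(rod), c(npmi1 = 0, npmi2 = 1), tolerance = 1e-12)
  square <- make_point_cloud(rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0)))
  expect_equal(npmi(square), c(npmi1 = 0.5, npmi2 = 0.5), tolerance = 1e-12)
  octa <- make_point_cloud(rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)
  ))
  expect_equal(npmi(octa), c(npmi1 = 1, npmi2 = 1), tolerance = 1e-12)
  expect_equal(npmi(make_point_cloud(matrix(7, 1, 3))), c(npmi1 = 1, npmi2 = 1))
  # ordering invariant on arbitrary fixtures
  for (seed in 1:8) {
    v <- npmi(random_cloud(40, seed))
    expect_true(0 <= v[1] && v[1] <= v[2] && v[2] <= 1)
  }
})

map_fixture <- function(n = 24) {
  structs <- lapply(seq_len(n), function(i) {
    assign_categories(make_coil("GSTNQKLEDVRF", seed = i, entry_id = sprintf("coil%02d", i)))
  })
  db <- dplyr::bind_rows(lapply(structs, fingerprint_3dp))
  props <- dplyr::bind_rows(lapply(structs, structure_properties))
  sf <- similarity_fingerprints(db, n_refs = 8, seed = 3)
  grid <- bin_to_grid(pca_project(sf), grid_size = 30)
  list(grid = grid, props = props, db = db)
}

test_that("pixel statistics aggregate counts, means and population sd", {
  fx <- map_fixture()
  st <- pixel_statistics(fx$grid, fx$props)
  expect_equal(sum(st$count), nrow(fx$db))
  expect_true(all(st[st$count == 1, ]$hac_sd == 0))
  # count-weighted pixel means reproduce the global property mean
  expect_equal(sum(st$hac_avg * st$count) / sum(st$count), mean(fx$props$hac),
               tolerance = 1e-12)
  # hand-checked two-entry pixel
  g2 <- tibble::tibble(entry_id = c("a", "b"), PC1 = 0, PC2 = 0, ix = 0L, iy = 0L)
  attr(g2, "grid_size") <- 30L
  p2 <- tibble::tibble(entry_id = c("a", "b"), hac = c(100, 300),
                       frac_positive = 0, frac_negative = 0, frac_hydrophobic = 0,
                       mvo = 0, npmi1 = 0.5, npmi2 = 0.5)
  st2 <- pixel_statistics(g2, p2)
  expect_equal(st2$hac_avg, 200)
  expect_equal(st2$hac_sd, 100) # population sd
  expect_error(pixel_statistics(fx$grid, fx$props[-1, ]),
               class = "pdbshape_error_contract")
})

test_that("rendered maps write deterministic pixel tables and valid colors", {
  fx <- map_fixture()
  st <- pixel_statistics(fx$grid, fx$props)
  png1 <- tempfile(fileext = ".png")
  tsv1 <- tempfile(fileext = ".tsv")
  out <- render_map(fx$grid, st, scheme = "hac", png_path = png1, tsv_path = tsv1)
  expect_true(file.exists(png1))
  img <- png::readPNG(png1)
  expect_equal(dim(img)[1:2], c(30, 30))
  tab <- readr::read_tsv(tsv1, show_col_types = FALSE)
  expect_equal(sum(tab$count), nrow(fx$db))
  expect_true(all(tab$R %in% 0:255 & tab$G %in% 0:255 & tab$B %in% 0:255))
  # byte-identical on rerun
  tsv2 <- tempfile(fileext = ".tsv")
  render_map(fx$grid, st, scheme = "hac", tsv_path = tsv2)
  expect_identical(readLines(tsv1), readLines(tsv2))
})

test_that("HSL coloring spans blue to magenta and fades with spread", {
  st <- tibble::tibble(
    ix = 0:2, iy = 0L, count = 1L,
    hac_avg = c(10, 55, 100), hac_sd = c(0, 0, 0),
    frac_positive_avg = 0, frac_positive_sd = 0,
    frac_negative_avg = 0, frac_negative_sd = 0,
    frac_hydrophobic_avg = 0, frac_hydrophobic_sd = 0,
    mvo_avg = 0, mvo_sd = 0, npmi1_avg = 0, npmi2_avg = 1
  )
  col <- color_pixels(st, "hac", normalize = "global")
  # minimum -> saturated blue
  expect_equal(unlist(col[1, c("R", "G", "B")]), c(R = 0, G = 0, B = 255),
               ignore_attr = TRUE)
  # maximum -> magenta-ish (red + blue, no green)
  expect_gt(col$R[3], 200)
  expect_equal(col$G[3], 0)
  # spread fades toward grey (saturation loss)
  st$hac_sd <- c(5, 5, 5)
  grey <- color_pixels(st, "hac", normalize = "global")
  expect_true(all(abs(unlist(grey[1, c("R", "G", "B")]) - 127) <= 1))
})

test_that("nPMI coloring makes rods red-dominant", {
  rods <- lapply(1:6, function(i) {
    jitter_structure(make_point_cloud(cbind(seq(0, 60, by = 1.5), 0, 0)),
                     sd = 0.05, seed = i, entry_id = paste0("rod", i))
  })
  props <- dplyr::bind_rows(lapply(rods, function(s) structure_properties(assign_categories(s))))
  grid <- tibble::tibble(entry_id = props$entry_id, PC1 = seq_along(rods), PC2 = 0,
                         ix = seq_along(rods) - 1L, iy = 0L)
  attr(grid, "grid_size") <- 10L
  st <- pixel_statistics(grid, props)
  col <- color_pixels(st, "npmi")
  expect_true(all(col$R > col$G & col$R > col$B))
})

test_that("entries are locatable on the map with their co-occupants", {
  fx <- map_fixture()
  loc <- locate_entry(fx$grid, "coil05")
  i <- which(fx$grid$entry_id == "coil05")
  expect_equal(loc$ix, fx$grid$ix[i])
  expect_equal(loc$iy, fx$grid$iy[i])
  expect_true("coil05" %in% loc$entries)
  # identical fingerprints share a pixel
  db2 <- fx$db
  db2$entry_id[2] <- "twin"
  db2[2, -1] <- db2[1, -1]
  sf2 <- similarity_fingerprints(db2, n_refs = 8, seed = 3)
  g2 <- bin_to_grid(pca_project(sf2), grid_size = 30)
  l1 <- locate_entry(g2, db2$entry_id[1])
  expect_true("twin" %in% l1$entries)
  expect_error(locate_entry(fx$grid, "ghost"), class = "pdbshape_error_notfound")
})

test_that("rods and globules separate on the map by shape descriptors", {
  structs <- c(
    lapply(1:8, function(i) {
      assign_categories(jitter_structure(
        make_point_cloud(cbind(seq(0, 90, by = 1.2), 0, 0)),
        sd = 0.2, seed = i, entry_id = paste0("rod", i)
      ))
    }),
    lapply(1:8, function(i) assign_categories(random_cloud(76, 400 + i, entry_id = paste0("glob", i))))
  )
  props <- dplyr::bind_rows(lapply(structs, structure_properties))
  is_rod <- startsWith(props$entry_id, "rod")
  # cluster separation: between-group distance exceeds within-group spread
  centers <- c(mean(props$npmi1[is_rod]), mean(props$npmi1[!is_rod]))
  spread <- max(stats::sd(props$npmi1[is_rod]), stats::sd(props$npmi1[!is_rod]))
  expect_gt(abs(diff(centers)) - spread, 0)
})

test_that("maps autoplot to ggplot objects in both flavors", {
  fx <- map_fixture()
  expect_s3_class(ggplot2::autoplot(fx$grid), "ggplot")
  st <- pixel_statistics(fx$grid, fx$props)
  expect_s3_class(ggplot2::autoplot(fx$grid, stats = st, scheme = "mvo"), "ggplot")
})
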