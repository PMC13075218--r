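make_scene <- function(seed = 1, n_plane = 1200, blob = TRUE) {
  set.seed(seed)
  cloud <- tibble::tibble(x = runif(n_plane, 0, 10), y = runif(n_plane, 0, 10), z = 0)
  if (blob) {
    cloud <- dplyr::bind_rows(
      cloud,
      tibble::tibble(
        x = rnorm(300, 5, 0.5), y = rnorm(300, 5, 0.5),
        z = runif(300, 1.5, 3)
      )
    )
  }
  cloud
}

test_that("progressive TIN densification separates ground from canopy", {
  cloud <- make_scene(1)
  cls <- classify_ground(cloud)
  # all plane points recovered (allowing the odd exactly-on-hull-edge point)
  expect_gte(mean(cls$cloud$class[1:1200] == "ground"), 0.999)
  expect_equal(mean(cls$cloud$class[1201:1500] == "non-ground"), 1)

  # sloped terrain: TIN elevation within the distance threshold of the truth
  set.seed(2)
  slope <- tibble::tibble(x = runif(1000, 0, 10), y = runif(1000, 0, 10))
  slope$z <- 0.1 * slope$x
  cls2 <- classify_ground(slope, dist_threshold = 0.3)
  q <- expand.grid(x = seq(0.5, 9.5, 0.5), y = seq(0.5, 9.5, 0.5))
  err <- abs(tin_elevation(cls2$ground, q$x, q$y) - 0.1 * q$x)
  expect_lt(max(err), 0.3)

  expect_error(
    classify_ground(tibble::tibble(x = 1, y = 1, z = 0)),
    class = "canopyn_degenerate_geometry"
  )
})

test_that("height normalization flattens ground and preserves tree heights", {
  cloud <- make_scene(3)
  cls <- classify_ground(cloud)
  norm <- suppressWarnings(normalize_heights(cls$cloud, cls$ground))
  expect_lt(max(abs(norm$z[1:1200])), 0.3)
  expect_equal(max(norm$z), 3, tolerance = 0.05)
  expect_error(
    normalize_heights(tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0)), cls$ground),
    class = "canopyn_degenerate_geometry"
  )
})

test_that("canopy maxima model rasterizes, fills and smooths correctly", {
  # flat ground only: all-zero raster
  flat <- make_scene(4, blob = FALSE)
  cmm0 <- canopy_maxima_model(flat, resolution = 0.5, smooth_window = 3)
  expect_equal(max(abs(cmm0$z)), 0)

  # one tree: raster max near PH, attenuated by smoothing
  t1 <- generate_tree_point_cloud(3, 2, 1.5, point_density = 800, seed = 5)
  cmm1 <- canopy_maxima_model(t1, resolution = 0.25, smooth_window = 3)
  expect_gt(max(cmm1$z), 2.5)
  expect_lte(max(cmm1$z), 3.0 + 1e-9)

  # two separated trees: two local maxima
  t2 <- generate_tree_point_cloud(2.6, 1.8, 1.3, point_density = 800, centre = c(6, 0), seed = 6)
  cmm2 <- canopy_maxima_model(dplyr::bind_rows(t1, t2), resolution = 0.25)
  mk <- canopyn:::local_maxima_cells(cmm2$z, cmm2$z >= 0.5)
  expect_equal(nrow(mk), 2)

  expect_error(canopy_maxima_model(t1, resolution = 0), "resolution")
})

test_that("marker-controlled watershed partitions crowns between trees", {
  t1 <- generate_tree_point_cloud(3, 2, 1.5, point_density = 600, seed = 1)
  t2 <- generate_tree_point_cloud(2.6, 1.8, 1.3, point_density = 600, centre = c(6, 0), seed = 2)
  cloud <- dplyr::bind_rows(dplyr::mutate(t1, true = 1L), dplyr::mutate(t2, true = 2L))
  cls <- classify_ground(cloud)
  norm <- normalize_heights(cls$cloud, cls$ground)
  cmm <- canopy_maxima_model(norm, resolution = 0.25, smooth_window = 3)
  seg <- segment_trees(cmm, cloud = norm)
  expect_equal(nrow(seg$markers), 2)

  # each generated crown keeps >= 95% of its points under one label
  crown_rows <- cloud$part == "crown"
  for (k in 1:2) {
    rows <- crown_rows & cloud$true == k
    lab <- as.integer(names(which.max(table(seg$points$tree[rows]))))
    expect_gte(mean(seg$points$tree[rows] == lab), 0.95)
  }
  # labels partition the above-threshold cells: no gaps, no overlaps
  above <- cmm$z >= 0.5
  expect_true(all(seg$labels[above] > 0))
  expect_true(all(seg$labels[!above] == 0))

  # single tree with an explicit apex marker
  cmm1 <- canopy_maxima_model(t1, resolution = 0.25)
  seg1 <- segment_trees(cmm1, markers = data.frame(x = 0, y = 0))
  expect_equal(nrow(seg1$segments), 1)
  expect_gt(seg1$segments$n_cells, 10)

  # markers dropped on flat ground are flagged as degenerate
  expect_warning(
    seg2 <- segment_trees(cmm1, markers = data.frame(x = c(0, 5), y = c(0, 5))),
    "below min_height"
  )
  expect_true(any(seg2$markers$degenerate))
  flat <- canopy_maxima_model(make_scene(7, blob = FALSE), resolution = 0.5)
  expect_error(segment_trees(flat), class = "canopyn_no_signal")
})

test_that("tree metrics recover construction parameters", {
  # unit cube corners: PH = CD = CV = 1 with no crown-base truncation
  cube <- tibble::tibble(
    x = c(0, 1, 0, 1, 0, 1, 0, 1), y = c(0, 0, 1, 1, 0, 0, 1, 1),
    z = c(0, 0, 0, 0, 1, 1, 1, 1)
  )
  tm <- tree_metrics(cube, "cube")
  expect_equal(c(tm$ph, tm$cd, tm$cv), c(1, 1, 1))

  # parameter sweep at low jitter: PH, CD within 5%, CV within 10%
  cases <- expand.grid(ph = c(2.5, 3.2), cd = c(1.6, 2.2))
  for (i in seq_len(nrow(cases))) {
    ph <- cases$ph[i]
    cd <- cases$cd[i]
    depth <- 0.5 * ph
    cl <- generate_tree_point_cloud(ph, cd, depth,
      point_density = 1500, jitter_sd = 0.03, seed = 20 + i
    )
    tm <- tree_metrics(cl, "t")
    expect_lt(abs(tm$ph - ph) / ph, 0.05)
    expect_lt(abs(tm$cd - cd) / cd, 0.05)
    va <- 4 / 3 * pi * (cd / 2)^2 * (depth / 2)
    expect_lt(abs(tm$cv - va) / va, 0.10)
  }

  # four-point tetrahedron through the metrics path
  tet <- tibble::tibble(x = c(0, 1, 0, 0), y = c(0, 0, 1, 0), z = c(0, 0, 0, 1))
  expect_equal(tree_metrics(tet, "tet")$cv, 1 / 6)

  expect_error(
    tree_metrics(tibble::tibble(x = c(0, 1), y = c(0, 0), z = c(1, 1)), "thin"),
    class = "canopyn_degenerate_geometry"
  )
})

test_that("combined structural correlation behaves like a multiple correlation", {
  set.seed(9)
  metrics <- tibble::tibble(
    tree_id = as.character(1:60),
    ph = runif(60, 2, 4), cd = runif(60, 1.5, 2.5), cv = runif(60, 2, 8)
  )
  expect_equal(combined_structural_correlation(metrics, metrics$ph), 1.0)
  expect_gt(
    combined_structural_correlation(metrics, metrics$cv + rnorm(60, 0, 0.1)),
    0.95
  )
  # independent noise: small correlation in most draws
  hits <- vapply(1:20, function(s) {
    set.seed(100 + s)
    abs(combined_structural_correlation(metrics, rnorm(60))) < 0.4
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  ind <- combined_structural_correlation(metrics, metrics$ph, method = "individual")
  expect_equal(unname(ind["ph"]), 1.0)
  bad <- dplyr::mutate(metrics, cv = ph)
  expect_error(combined_structural_correlation(bad, metrics$ph), "rank")
})
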