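#' Progressive-densification TIN ground classification
#'
#' Classifies a raw point cloud into ground and non-ground returns. A sparse
#' seed TIN is built from the lowest return in each grid cell; points are then
#' added iteratively when their perpendicular distance to the containing TIN
#' facet and their angles to the facet's vertices fall below the thresholds,
#' and the TIN is re-densified until no further point qualifies.
#'
#' @param cloud A data frame with columns `x`, `y`, `z` (m).
#' @param cell_size Seed-grid cell size in m; the cloud must span at least
#'   2 x 2 cells.
#' @param dist_threshold Maximum perpendicular point-to-facet distance (m).
#' @param angle_threshold Maximum point-to-facet-vertex angle (degrees).
#' @param max_iter Safety cap on densification rounds.
#'
#' @return A list with `cloud` (the input plus a `class` column, `"ground"`
#'   or `"non-ground"`) and `ground` (a [ground_tin()] over the ground
#'   points).
#' @export
classify_ground <- function(cloud, cell_size = 1, dist_threshold = 0.3,
                            angle_threshold = 10, max_iter = 20) {
  check_cloud(cloud)
  assert_scalar_number(cell_size, "cell_size", lower = 0, strict_lower = TRUE)
  assert_scalar_number(dist_threshold, "dist_threshold", lower = 0, strict_lower = TRUE)
  assert_scalar_number(angle_threshold, "angle_threshold", lower = 0, strict_lower = TRUE)
  nx <- diff(range(cloud$x)) / cell_size
  ny <- diff(range(cloud$y)) / cell_size
  if (nrow(cloud) < 3 || nx < 1 || ny < 1) {
    stop_input("cloud must span at least 2 x 2 seed cells.",
      class = "canopyn_degenerate_geometry"
    )
  }
  ix <- floor((cloud$x - min(cloud$x)) / cell_size)
  iy <- floor((cloud$y - min(cloud$y)) / cell_size)
  cell <- paste(ix, iy)
  seed_idx <- vapply(
    split(seq_len(nrow(cloud)), cell),
    function(i) i[which.min(cloud$z[i])], integer(1)
  )
  is_ground <- rep(FALSE, nrow(cloud))
  is_ground[seed_idx] <- TRUE

  # Bounding-box corner vertices (elevation of the nearest seed) extend the
  # TIN hull over the whole footprint so edge points can be evaluated.
  corners <- expand.grid(x = range(cloud$x), y = range(cloud$y))
  corners$z <- vapply(seq_len(4), function(k) {
    cloud$z[seed_idx[which.min(
      (cloud$x[seed_idx] - corners$x[k])^2 + (cloud$y[seed_idx] - corners$y[k])^2
    )]]
  }, numeric(1))
  build_tin <- function() {
    ground_tin(rbind(
      data.frame(x = cloud$x[is_ground], y = cloud$y[is_ground], z = cloud$z[is_ground]),
      corners
    ))
  }
  tin <- build_tin()
  ang_max <- angle_threshold * pi / 180
  for (iter in seq_len(max_iter)) {
    cand <- which(!is_ground)
    if (length(cand) == 0) break
    tri <- tin_locate(tin, cloud$x[cand], cloud$y[cand])
    ok <- !is.na(tri)
    if (!any(ok)) break
    cand <- cand[ok]
    tri <- tri[ok]
    pl <- tin_planes(tin, tri)
    nn <- sqrt(pl[, "nx"]^2 + pl[, "ny"]^2 + pl[, "nz"]^2)
    v1 <- tin$tris[tri, 1]
    dperp <- abs(
      pl[, "nx"] * (cloud$x[cand] - tin$x[v1]) +
        pl[, "ny"] * (cloud$y[cand] - tin$y[v1]) +
        pl[, "nz"] * (cloud$z[cand] - tin$z[v1])
    ) / nn
    accept <- dperp < dist_threshold
    for (col in 1:3) {
      v <- tin$tris[cbind(tri, col)]
      seg <- sqrt((cloud$x[cand] - tin$x[v])^2 +
        (cloud$y[cand] - tin$y[v])^2 +
        (cloud$z[cand] - tin$z[v])^2)
      ang <- asin(pmin(1, dperp / pmax(seg, 1e-12)))
      accept <- accept & ang < ang_max
    }
    if (!any(accept)) break
    is_ground[cand[accept]] <- TRUE
    tin <- build_tin()
  }
  out <- dplyr::mutate(
    tibble::as_tibble(cloud),
    class = ifelse(is_ground, "ground", "non-ground")
  )
  list(cloud = out, ground = tin)
}

check_cloud <- function(cloud) {
  if (!is.data.frame(cloud) || !all(c("x", "y", "z") %in% names(cloud))) {
    stop_input("point cloud must be a data frame with columns x, y, z.")
  }
  if (nrow(cloud) == 0) {
    stop_input("point cloud is empty.", class = "canopyn_degenerate_geometry")
  }
  if (nrow(cloud) < 2) {
    stop_input("point cloud has a single point; nothing to model.",
      class = "canopyn_degenerate_geometry"
    )
  }
  if (any(!is.finite(cloud$x)) || any(!is.finite(cloud$y)) || any(!is.finite(cloud$z))) {
    stop_input("point coordinates must be finite.")
  }
  invisible(cloud)
}

#' Normalize point heights against a ground model
#'
#' Replaces each point's `z` by its height above the TIN ground surface.
#' Points outside the TIN hull are normalized against the nearest facet's
#' plane (with a warning from the elevation query).
#'
#' @param cloud A data frame with columns `x`, `y`, `z` (any extra columns,
#'   e.g. `class`, are preserved).
#' @param ground A `canopyn_tin` from [ground_tin()] / [classify_ground()].
#'
#' @return The cloud with `z` replaced by height above ground (m).
#' @export
normalize_heights <- function(cloud, ground) {
  check_cloud(cloud)
  if (!inherits(ground, "canopyn_tin")) {
    stop_input("`ground` must be a canopyn_tin.")
  }
  elev <- tin_elevation(ground, cloud$x, cloud$y)
  dplyr::mutate(tibble::as_tibble(cloud), z = .data$z - elev)
}

#' Smoothed canopy maxima model
#'
#' Rasterizes a height-normalized cloud to the per-cell maximum height,
#' fills empty cells by iterative neighbourhood interpolation, and applies a
#' boxcar (moving-average) smoothing window - the surface on which individual
#' trees are detected and segmented.
#'
#' @param cloud A height-normalized cloud (`z` = height above ground, m).
#' @param resolution Cell size in m.
#' @param smooth_window Odd boxcar width in cells (1 = no smoothing).
#'
#' @return An object of class `canopyn_cmm`: list with `z` (matrix, x by y),
#'   `x0`, `y0` (cell-centre origin) and `res`.
#' @export
canopy_maxima_model <- function(cloud, resolution = 0.25, smooth_window = 3) {
  check_cloud(cloud)
  assert_scalar_number(resolution, "resolution", lower = 0, strict_lower = TRUE)
  if (smooth_window %% 2 == 0) stop_input("`smooth_window` must be odd.")
  x0 <- min(cloud$x)
  y0 <- min(cloud$y)
  ix <- pmin(floor((cloud$x - x0) / resolution) + 1, ceiling(max(1, diff(range(cloud$x)) / resolution)))
  iy <- pmin(floor((cloud$y - y0) / resolution) + 1, ceiling(max(1, diff(range(cloud$y)) / resolution)))
  nxc <- max(ix)
  nyc <- max(iy)
  z <- matrix(NA_real_, nxc, nyc)
  ord <- order(cloud$z) # later (higher) writes win
  z[cbind(ix[ord], iy[ord])] <- cloud$z[ord]
  # fill empties from the 3x3 neighbourhood mean, repeatedly
  while (anyNA(z)) {
    filled <- neighbourhood_mean(z)
    still <- is.na(z)
    z[still] <- filled[still]
    if (all(is.na(filled[still]))) break # isolated raster; give up
  }
  z[is.na(z)] <- 0
  if (smooth_window > 1) {
    z <- boxcar2d(z, smooth_window)
  }
  structure(
    list(z = z, x0 = x0 + resolution / 2, y0 = y0 + resolution / 2, res = resolution),
    class = "canopyn_cmm"
  )
}

neighbourhood_mean <- function(z) {
  nx <- nrow(z)
  ny <- ncol(z)
  s <- matrix(0, nx, ny)
  cnt <- matrix(0, nx, ny)
  for (dx in -1:1) {
    for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      xt <- max(1, 1 - dx):min(nx, nx - dx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      yt <- max(1, 1 - dy):min(ny, ny - dy)
      v <- z[xs, ys, drop = FALSE]
      ok <- !is.na(v)
      v[!ok] <- 0
      s[xt, yt] <- s[xt, yt] + v
      cnt[xt, yt] <- cnt[xt, yt] + ok
    }
  }
  out <- s / cnt
  out[cnt == 0] <- NA_real_
  out
}

boxcar2d <- function(z, w) {
  half <- (w - 1) / 2
  nx <- nrow(z)
  ny <- ncol(z)
  s <- matrix(0, nx, ny)
  cnt <- matrix(0, nx, ny)
  for (dx in -half:half) {
    for (dy in -half:half) {
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      xt <- max(1, 1 - dx):min(nx, nx - dx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      yt <- max(1, 1 - dy):min(ny, ny - dy)
      s[xt, yt] <- s[xt, yt] + z[xs, ys]
      cnt[xt, yt] <- cnt[xt, yt] + 1
    }
  }
  s / cnt
}

#' @export
print.canopyn_cmm <- function(x, ...) {
  cat(sprintf(
    "Canopy maxima model: %d x %d cells at %.2f m, max height %.2f m\n",
    nrow(x$z), ncol(x$z), x$res, max(x$z)
  ))
  invisible(x)
}

#' Tidy a canopy maxima model
#'
#' @param x A `canopyn_cmm`.
#' @param ... Unused.
#' @return A tibble with `x`, `y`, `height`.
#' @export
tidy.canopyn_cmm <- function(x, ...) {
  nx <- nrow(x$z)
  ny <- ncol(x$z)
  tibble::tibble(
    x = x$x0 + (rep(seq_len(nx), ny) - 1) * x$res,
    y = x$y0 + (rep(seq_len(ny), each = nx) - 1) * x$res,
    height = as.vector(x$z)
  )
}

#' Marker-controlled watershed tree segmentation
#'
#' Floods the inverted canopy maxima model from tree-apex markers: cells are
#' visited in order of decreasing height and join the basin of their highest
#' already-labelled neighbour, so every above-threshold cell receives exactly
#' one tree label. Markers default to the local maxima of the smoothed model
#' above `min_height`. Markers placed below `min_height` produce empty,
#' degenerate segments and are flagged with a warning.
#'
#' @param cmm A `canopyn_cmm` from [canopy_maxima_model()].
#' @param markers Optional data frame of marker coordinates (`x`, `y` in m).
#'   If `NULL`, local maxima above `min_height` are detected.
#' @param min_height Minimum canopy height (m) for a cell to be segmented.
#' @param cloud Optional height-normalized cloud; if given, points inherit
#'   the label of their cell (0 = unsegmented).
#'
#' @return A list with `labels` (integer matrix, 0 = background), `markers`
#'   (tibble: label, x, y, height, degenerate), `segments` (tibble: label,
#'   n_cells) and, when `cloud` is supplied, `points` (cloud + `tree` column).
#' @export
segment_trees <- function(cmm, markers = NULL, min_height = 0.5, cloud = NULL) {
  if (!inherits(cmm, "canopyn_cmm")) stop_input("`cmm` must be a canopyn_cmm.")
  z <- cmm$z
  nx <- nrow(z)
  ny <- ncol(z)
  mask <- z >= min_height

  if (is.null(markers)) {
    mk <- local_maxima_cells(z, mask)
    if (nrow(mk) == 0) {
      stop_input("no markers found above `min_height`.", class = "canopyn_no_signal")
    }
  } else {
    if (!all(c("x", "y") %in% names(markers)) || nrow(markers) == 0) {
      stop_input("`markers` must have columns x, y and at least one row.")
    }
    mk <- data.frame(
      ix = pmin(pmax(round((markers$x - cmm$x0) / cmm$res) + 1, 1), nx),
      iy = pmin(pmax(round((markers$y - cmm$y0) / cmm$res) + 1, 1), ny)
    )
  }
  mk$height <- z[cbind(mk$ix, mk$iy)]
  mk$degenerate <- !mask[cbind(mk$ix, mk$iy)]
  if (any(mk$degenerate)) {
    rlang::warn(sprintf(
      "%d marker(s) sit below min_height; their segments are empty.",
      sum(mk$degenerate)
    ))
  }
  if (all(mk$degenerate)) {
    stop_input("all markers are below `min_height`.", class = "canopyn_no_signal")
  }

  labels <- matrix(0L, nx, ny)
  live <- which(!mk$degenerate)
  for (k in seq_along(live)) {
    labels[mk$ix[live[k]], mk$iy[live[k]]] <- k
  }
  lab_of_marker <- integer(nrow(mk))
  lab_of_marker[live] <- seq_along(live)

  cells <- which(mask & labels == 0L)
  cells <- cells[order(z[cells], decreasing = TRUE)]
  repeat {
    changed <- FALSE
    for (cell in cells) {
      if (labels[cell] != 0L) next
      cx <- (cell - 1) %% nx + 1
      cy <- (cell - 1) %/% nx + 1
      best_lab <- 0L
      best_z <- -Inf
      for (dx in -1:1) {
        for (dy in -1:1) {
          if (dx == 0 && dy == 0) next
          ux <- cx + dx
          uy <- cy + dy
          if (ux < 1 || ux > nx || uy < 1 || uy > ny) next
          l <- labels[ux, uy]
          if (l > 0L && z[ux, uy] > best_z) {
            best_z <- z[ux, uy]
            best_lab <- l
          }
        }
      }
      if (best_lab > 0L) {
        labels[cell] <- best_lab
        changed <- TRUE
      }
    }
    cells <- cells[labels[cells] == 0L]
    if (!changed || length(cells) == 0) break
  }
  if (length(cells) > 0) { # isolated patches: nearest live marker
    for (cell in cells) {
      cx <- (cell - 1) %% nx + 1
      cy <- (cell - 1) %/% nx + 1
      d2 <- (mk$ix[live] - cx)^2 + (mk$iy[live] - cy)^2
      labels[cell] <- which.min(d2)
    }
  }

  marker_tbl <- tibble::tibble(
    label = lab_of_marker,
    x = cmm$x0 + (mk$ix - 1) * cmm$res,
    y = cmm$y0 + (mk$iy - 1) * cmm$res,
    height = mk$height, degenerate = mk$degenerate
  )
  seg_tbl <- tibble::tibble(label = seq_along(live)) |>
    dplyr::mutate(n_cells = vapply(
      .data$label, function(l) sum(labels == l), integer(1)
    ))
  out <- list(labels = labels, markers = marker_tbl, segments = seg_tbl)
  if (!is.null(cloud)) {
    check_cloud(cloud)
    ix <- pmin(pmax(round((cloud$x - cmm$x0) / cmm$res) + 1, 1), nx)
    iy <- pmin(pmax(round((cloud$y - cmm$y0) / cmm$res) + 1, 1), ny)
    out$points <- dplyr::mutate(
      tibble::as_tibble(cloud),
      tree = labels[cbind(ix, iy)]
    )
  }
  out
}

local_maxima_cells <- function(z, mask) {
  nx <- nrow(z)
  ny <- ncol(z)
  is_max <- mask
  for (dx in -1:1) {
    for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      shifted <- matrix(-Inf, nx, ny)
      xs <- max(1, 1 + dx):min(nx, nx + dx)
      xt <- max(1, 1 - dx):min(nx, nx - dx)
      ys <- max(1, 1 + dy):min(ny, ny + dy)
      yt <- max(1, 1 - dy):min(ny, ny - dy)
      shifted[xt, yt] <- z[xs, ys]
      is_max <- is_max & (z >= shifted)
    }
  }
  idx <- which(is_max)
  if (length(idx) == 0) {
    return(data.frame(ix = integer(0), iy = integer(0)))
  }
  ix <- (idx - 1) %% nx + 1
  iy <- (idx - 1) %/% nx + 1
  # collapse plateau/adjacent maxima (within 2 cells) to their highest cell
  ord <- order(z[idx], decreasing = TRUE)
  keep <- logical(0)
  kept <- matrix(numeric(0), 0, 2)
  for (k in ord) {
    if (nrow(kept) == 0 || all((kept[, 1] - ix[k])^2 + (kept[, 2] - iy[k])^2 > 4)) {
      kept <- rbind(kept, c(ix[k], iy[k]))
      keep <- c(keep, k)
    }
  }
  data.frame(ix = ix[keep], iy = iy[keep])
}

#' Per-tree structural metrics: PH, CD, CV
#'
#' From a single tree's height-normalized points: plant height (PH) is the
#' maximum height; crown diameter (CD) is the mean of the east-west and
#' north-south horizontal extents of the crown points; canopy volume (CV) is
#' the volume of the crown points' 3D convex hull.
#'
#' The crown base separating trunk from crown returns is estimated from the
#' vertical profile: heights are binned and the crown starts at the lowest
#' bin whose horizontal spread reaches a quarter of the maximum spread (a
#' trunk is laterally narrow, a crown is not). Supply `crown_base` to
#' override. Ground-classified points (`class == "ground"` or
#' `part == "ground"`) are dropped first.
#'
#' @param cloud One tree's height-normalized points (`x`, `y`, `z`).
#' @param tree_id Identifier used in messages and the output row.
#' @param crown_base Optional fixed crown-base height (m).
#'
#' @return A one-row tibble: `tree_id`, `ph`, `cd`, `cv`, `crown_base`,
#'   `n_points`, `n_crown`.
#' @export
#'
#' @examples
#' cl <- generate_tree_point_cloud(3, 2, 1.5, seed = 1)
#' tree_metrics(cl, "t1")
tree_metrics <- function(cloud, tree_id = "tree", crown_base = NULL) {
  check_cloud(cloud)
  for (col in c("class", "part")) {
    if (col %in% names(cloud)) cloud <- cloud[cloud[[col]] != "ground", ]
  }
  if (nrow(cloud) < 2) {
    stop_input(sprintf("tree '%s': fewer than 2 non-ground points.", tree_id),
      class = "canopyn_degenerate_geometry"
    )
  }
  ph <- max(cloud$z)
  if (ph <= 0) {
    stop_input(sprintf("tree '%s': no points above ground.", tree_id),
      class = "canopyn_degenerate_geometry"
    )
  }
  if (is.null(crown_base)) crown_base <- estimate_crown_base(cloud)
  crown <- cloud[cloud$z >= crown_base, ]
  if (nrow(crown) < 4) {
    stop_input(
      sprintf("tree '%s': fewer than 4 crown points; CV undefined.", tree_id),
      class = "canopyn_degenerate_geometry"
    )
  }
  cd <- mean(c(diff(range(crown$x)), diff(range(crown$y))))
  cv <- tryCatch(
    convex_hull_volume(cbind(crown$x, crown$y, crown$z)),
    canopyn_degenerate_geometry = function(e) {
      stop_input(
        sprintf("tree '%s': degenerate crown geometry (%s)", tree_id, conditionMessage(e)),
        class = "canopyn_degenerate_geometry"
      )
    }
  )
  tibble::tibble(
    tree_id = tree_id, ph = ph, cd = cd, cv = cv,
    crown_base = crown_base, n_points = nrow(cloud), n_crown = nrow(crown)
  )
}

# Lowest height bin whose horizontal spread reaches 25% of the maximum
# spread; 0 when the profile is uniform (e.g. a box of points).
estimate_crown_base <- function(cloud, n_bins = 20, frac = 0.25) {
  zr <- range(cloud$z)
  if (diff(zr) < 1e-9) {
    return(zr[1])
  }
  breaks <- seq(zr[1], zr[2], length.out = n_bins + 1)
  bin <- cut(cloud$z, breaks, include.lowest = TRUE, labels = FALSE)
  cx <- stats::median(cloud$x)
  cy <- stats::median(cloud$y)
  rad <- sqrt((cloud$x - cx)^2 + (cloud$y - cy)^2)
  spread <- tapply(rad, bin, function(r) stats::quantile(r, 0.9))
  spread_full <- rep(0, n_bins)
  spread_full[as.integer(names(spread))] <- spread
  thr <- frac * max(spread_full)
  first <- which(spread_full >= thr)[1]
  if (is.na(first)) {
    return(zr[1])
  }
  breaks[first]
}

#' Extract structural metrics for a list of tree clouds
#'
#' Convenience wrapper mapping [tree_metrics()] over a named list of
#' height-normalized single-tree clouds.
#'
#' @param clouds Named list of tree clouds (names become `tree_id`).
#' @param ... Passed to [tree_metrics()].
#' @return A tibble with one row per tree.
#' @export
extract_tree_metrics <- function(clouds, ...) {
  purrr::imap_dfr(clouds, function(cl, id) tree_metrics(cl, tree_id = id, ...))
}

#' Association between a trait and the combined structural triplet
#'
#' Reports the rank correlation between a trait and the best least-squares
#' linear combination of PH, CD and CV (a multiple-correlation construction):
#' the trait is regressed on the three metrics and the Spearman correlation
#' between trait and fitted values is returned. Set `method = "individual"`
#' for per-metric Spearman correlations instead.
#'
#' @param metrics A tibble with columns `ph`, `cd`, `cv` (one row per tree).
#' @param trait Numeric trait vector (length = rows of `metrics`, `>= 5`).
#' @param method `"combined"` (default) or `"individual"`.
#'
#' @return For `"combined"`, a single correlation; for `"individual"`, a
#'   named vector of three correlations.
#' @export
combined_structural_correlation <- function(metrics, trait,
                                            method = c("combined", "individual")) {
  method <- match.arg(method)
  if (!all(c("ph", "cd", "cv") %in% names(metrics))) {
    stop_input("`metrics` needs columns ph, cd, cv.")
  }
  if (length(trait) != nrow(metrics) || length(trait) < 5) {
    stop_input("`trait` must match `metrics` rows and have length >= 5.")
  }
  if (method == "individual") {
    return(vapply(
      metrics[, c("ph", "cd", "cv")],
      function(m) spearman_cor(m, trait), numeric(1)
    ))
  }
  x <- as.matrix(metrics[, c("ph", "cd", "cv")])
  if (qr(cbind(1, x))$rank < 4) {
    stop_input("structural design is rank-deficient.")
  }
  fit <- stats::lm.fit(cbind(1, x), trait)
  spearman_cor(trait, fit$fitted.values)
}
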