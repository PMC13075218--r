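# 2D Delaunay triangulation (Bowyer-Watson incremental insertion) and a
# triangulated irregular network (TIN) built on it. Used by the progressive
# densification ground filter; queries interpolate elevation barycentrically.

orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Returns a T x 3 matrix of 1-based indices into (x, y). Duplicated (x, y)
# locations keep their first occurrence. Errors if the input is degenerate
# (fewer than 3 distinct non-collinear points).
delaunay_triangulate <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y lengths differ.")
  keep <- !duplicated(cbind(x, y))
  map <- which(keep)
  xs <- x[keep]
  ys <- y[keep]
  n <- length(xs)
  if (n < 3) stop_input("need at least 3 distinct points.", class = "canopyn_degenerate_geometry")

  cx <- mean(range(xs))
  cy <- mean(range(ys))
  r <- max(diff(range(xs)), diff(range(ys)), 1e-9)
  px <- c(cx - 30 * r, cx + 30 * r, cx, xs)
  py <- c(cy - 10 * r, cy - 10 * r, cy + 30 * r, ys)
  tris <- matrix(c(1L, 2L, 3L), 1)
  if (orient2d(px[1], py[1], px[2], py[2], px[3], py[3]) < 0) {
    tris <- tris[, c(1, 3, 2), drop = FALSE]
  }

  for (pi_ in seq_len(n) + 3L) {
    dx <- px[pi_]
    dy <- py[pi_]
    a <- tris[, 1]
    b <- tris[, 2]
    cc <- tris[, 3]
    ax <- px[a] - dx
    ay <- py[a] - dy
    bx <- px[b] - dx
    by <- py[b] - dy
    cx2 <- px[cc] - dx
    cy2 <- py[cc] - dy
    det <- (ax * ax + ay * ay) * (bx * cy2 - by * cx2) -
      (bx * bx + by * by) * (ax * cy2 - ay * cx2) +
      (cx2 * cx2 + cy2 * cy2) * (ax * by - ay * bx)
    bad <- det > 0
    if (!any(bad)) next # duplicate or exactly cocircular-degenerate; skip
    bt <- tris[bad, , drop = FALSE]
    e1 <- rbind(bt[, 1:2], bt[, 2:3], bt[, c(3, 1)])
    key <- paste(pmin(e1[, 1], e1[, 2]), pmax(e1[, 1], e1[, 2]))
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    boundary <- e1[once, , drop = FALSE]
    new_tris <- cbind(boundary, pi_)
    # drop degenerate slivers (collinear with the new point)
    area <- orient2d(
      px[new_tris[, 1]], py[new_tris[, 1]],
      px[new_tris[, 2]], py[new_tris[, 2]],
      px[new_tris[, 3]], py[new_tris[, 3]]
    )
    new_tris <- new_tris[area > 0, , drop = FALSE]
    tris <- rbind(tris[!bad, , drop = FALSE], new_tris)
  }

  real <- tris[, 1] > 3 & tris[, 2] > 3 & tris[, 3] > 3
  tris <- tris[real, , drop = FALSE] - 3L
  if (nrow(tris) == 0) {
    stop_input("all points are collinear; cannot triangulate.",
      class = "canopyn_degenerate_geometry"
    )
  }
  matrix(map[tris], ncol = 3)
}

#' Build a ground TIN from classified ground points
#'
#' Triangulates the (x, y) locations of ground points (Delaunay) and attaches
#' their elevations, yielding a piecewise-linear ground surface that can be
#' queried anywhere inside its convex hull.
#'
#' @param ground A data frame of ground points with columns `x`, `y`, `z`.
#'
#' @return An object of class `canopyn_tin`.
#' @export
ground_tin <- function(ground) {
  if (!all(c("x", "y", "z") %in% names(ground))) {
    stop_input("`ground` needs columns x, y, z.")
  }
  if (nrow(ground) < 3) {
    stop_input("need at least 3 ground points.", class = "canopyn_degenerate_geometry")
  }
  tris <- delaunay_triangulate(ground$x, ground$y)
  structure(
    list(
      x = ground$x, y = ground$y, z = ground$z, tris = tris
    ),
    class = "canopyn_tin"
  )
}

#' @export
print.canopyn_tin <- function(x, ...) {
  cat(sprintf(
    "Ground TIN: %d vertices, %d triangles\n",
    length(x$x), nrow(x$tris)
  ))
  invisible(x)
}

# Locate the triangle containing each query point (NA if outside the hull).
tin_locate <- function(tin, qx, qy) {
  m <- length(qx)
  out <- rep(NA_integer_, m)
  remaining <- seq_len(m)
  tol <- -1e-9 * max(diff(range(tin$x)), diff(range(tin$y)), 1)
  for (t in seq_len(nrow(tin$tris))) {
    if (length(remaining) == 0) break
    v <- tin$tris[t, ]
    ax <- tin$x[v[1]]
    ay <- tin$y[v[1]]
    bx <- tin$x[v[2]]
    by <- tin$y[v[2]]
    cx <- tin$x[v[3]]
    cy <- tin$y[v[3]]
    d1 <- orient2d(ax, ay, bx, by, qx[remaining], qy[remaining])
    d2 <- orient2d(bx, by, cx, cy, qx[remaining], qy[remaining])
    d3 <- orient2d(cx, cy, ax, ay, qx[remaining], qy[remaining])
    inside <- d1 >= tol & d2 >= tol & d3 >= tol
    if (any(inside)) {
      out[remaining[inside]] <- t
      remaining <- remaining[!inside]
    }
  }
  out
}

# Plane coefficients (z = a*x + b*y + c) for each triangle index.
tin_planes <- function(tin, tri_idx) {
  v1 <- tin$tris[tri_idx, 1]
  v2 <- tin$tris[tri_idx, 2]
  v3 <- tin$tris[tri_idx, 3]
  ux <- tin$x[v2] - tin$x[v1]
  uy <- tin$y[v2] - tin$y[v1]
  uz <- tin$z[v2] - tin$z[v1]
  wx <- tin$x[v3] - tin$x[v1]
  wy <- tin$y[v3] - tin$y[v1]
  wz <- tin$z[v3] - tin$z[v1]
  nx <- uy * wz - uz * wy
  ny <- uz * wx - ux * wz
  nz <- ux * wy - uy * wx
  a <- -nx / nz
  b <- -ny / nz
  c <- tin$z[v1] - a * tin$x[v1] - b * tin$y[v1]
  cbind(a = a, b = b, c = c, nx = nx, ny = ny, nz = nz)
}

#' Query ground elevation from a TIN
#'
#' Linear (barycentric) interpolation inside the TIN's convex hull. Queries
#' outside the hull are extrapolated from the plane of the facet nearest to
#' the query, with a warning.
#'
#' @param tin A `canopyn_tin` from [ground_tin()].
#' @param x,y Query coordinates (equal-length vectors).
#'
#' @return Elevations (m), one per query.
#' @export
tin_elevation <- function(tin, x, y) {
  if (!inherits(tin, "canopyn_tin")) stop_input("`tin` must come from ground_tin().")
  if (length(x) != length(y)) stop_input("x and y lengths differ.")
  if (length(x) == 0) return(numeric(0))
  tri <- tin_locate(tin, x, y)
  out <- rep(NA_real_, length(x))
  inside <- !is.na(tri)
  if (any(inside)) {
    pl <- tin_planes(tin, tri[inside])
    out[inside] <- pl[, "a"] * x[inside] + pl[, "b"] * y[inside] + pl[, "c"]
  }
  if (any(!inside)) {
    rlang::warn(sprintf(
      "%d query point(s) outside the TIN hull; extrapolating from the nearest facet.",
      sum(!inside)
    ))
    # nearest vertex, then the plane of one triangle incident to it
    vert_tri <- rep(NA_integer_, length(tin$x))
    for (col in 3:1) vert_tri[tin$tris[, col]] <- seq_len(nrow(tin$tris))
    qi <- which(!inside)
    for (q in qi) {
      nv <- which.min((tin$x - x[q])^2 + (tin$y - y[q])^2)
      pl <- tin_planes(tin, vert_tri[nv])
      out[q] <- pl[1, "a"] * x[q] + pl[1, "b"] * y[q] + pl[1, "c"]
    }
  }
  out
}
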