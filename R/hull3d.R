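# Incremental 3D convex hull (quickhull-style point insertion) and its
# volume. Faces are stored with outward-oriented vertex triples; inserting a
# point removes the faces it sees and rebuilds the cone over the horizon.

cross3 <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

# points: n x 3 matrix. Returns list(vertices, faces) where faces is F x 3
# with outward counter-clockwise orientation.
convex_hull_3d <- function(points) {
  pts <- unique(round(points, 12))
  n <- nrow(pts)
  if (is.null(n) || n < 4) {
    stop_input("need at least 4 distinct points for a 3D hull.",
      class = "canopyn_degenerate_geometry"
    )
  }
  scale <- max(apply(pts, 2, function(c) diff(range(c))), 1e-12)
  eps <- 1e-10 * scale

  # initial simplex: two extreme points, then max-area, then max-volume
  i1 <- which.min(pts[, 1])
  d <- rowSums(sweep(pts, 2, pts[i1, ])^2)
  i2 <- which.max(d)
  if (d[i2] < eps^2) {
    stop_input("points are coincident.", class = "canopyn_degenerate_geometry")
  }
  u <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  cr <- cbind(
    rel[, 2] * u[3] - rel[, 3] * u[2],
    rel[, 3] * u[1] - rel[, 1] * u[3],
    rel[, 1] * u[2] - rel[, 2] * u[1]
  )
  area2 <- rowSums(cr^2)
  i3 <- which.max(area2)
  if (sqrt(area2[i3]) < eps * sqrt(sum(u^2))) {
    stop_input("points are collinear.", class = "canopyn_degenerate_geometry")
  }
  nrm <- cross3(pts[i2, ] - pts[i1, ], pts[i3, ] - pts[i1, ])
  h <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] < eps) {
    stop_input("points are coplanar; hull volume undefined.",
      class = "canopyn_degenerate_geometry"
    )
  }

  centroid <- colMeans(pts[c(i1, i2, i3, i4), ])
  faces <- rbind(
    c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4)
  )
  orient_face <- function(f) {
    nrm <- cross3(pts[f[2], ] - pts[f[1], ], pts[f[3], ] - pts[f[1], ])
    if (sum(nrm * (centroid - pts[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient_face))
  face_geometry <- function(faces) {
    a <- pts[faces[, 1], , drop = FALSE]
    b <- pts[faces[, 2], , drop = FALSE]
    cc <- pts[faces[, 3], , drop = FALSE]
    u <- b - a
    v <- cc - a
    nrm <- cbind(
      u[, 2] * v[, 3] - u[, 3] * v[, 2],
      u[, 3] * v[, 1] - u[, 1] * v[, 3],
      u[, 1] * v[, 2] - u[, 2] * v[, 1]
    )
    list(normal = nrm, offset = rowSums(nrm * a))
  }
  geo <- face_geometry(faces)

  rest <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (p in rest) {
    dist <- as.numeric(geo$normal %*% pts[p, ]) - geo$offset
    nf <- sqrt(rowSums(geo$normal^2))
    visible <- dist > eps * nf
    if (!any(visible)) next
    vis_faces <- faces[visible, , drop = FALSE]
    edges <- rbind(
      vis_faces[, 1:2], vis_faces[, 2:3], vis_faces[, c(3, 1)]
    )
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
    horizon <- edges[once, , drop = FALSE]
    new_faces <- cbind(horizon, p)
    faces <- rbind(faces[!visible, , drop = FALSE], new_faces)
    geo <- face_geometry(faces)
  }
  list(vertices = pts, faces = faces)
}

#' Volume of the 3D convex hull of a point set
#'
#' Computes the convex hull by incremental point insertion and returns its
#' volume as the sum of signed tetrahedra from the hull centroid over the
#' outward-oriented faces. Invariant under rigid rotation and translation.
#'
#' @param points An n x 3 numeric matrix or a data frame with columns
#'   `x`, `y`, `z` (metres).
#'
#' @return Volume in m3.
#' @export
#'
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' convex_hull_volume(cube) # 1
convex_hull_volume <- function(points) {
  if (is.data.frame(points)) {
    points <- as.matrix(points[, c("x", "y", "z")])
  }
  if (!is.matrix(points) || ncol(points) != 3 || any(!is.finite(points))) {
    stop_input("`points` must be a finite n x 3 matrix.")
  }
  hull <- convex_hull_3d(points)
  pts <- hull$vertices
  faces <- hull$faces
  ctr <- colMeans(pts[unique(as.vector(faces)), , drop = FALSE])
  a <- sweep(pts[faces[, 1], , drop = FALSE], 2, ctr)
  b <- sweep(pts[faces[, 2], , drop = FALSE], 2, ctr)
  cc <- sweep(pts[faces[, 3], , drop = FALSE], 2, ctr)
  vol6 <- a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
    a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
    a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(vol6) / 6
}
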