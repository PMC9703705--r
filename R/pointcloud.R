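#' Colored 3D point cloud
#'
#' The universal geometry carrier of the package: `coords` holds XYZ
#' positions in reconstruction units and `colors` the per-point RGB
#' intensities on the 0--255 scale. An optional `units_per_cm` factor
#' records the metric scale of the reconstruction (how many coordinate
#' units correspond to one centimetre); when present, areas derived from
#' the cloud are also reported in cm^2.
#'
#' @param coords numeric N x 3 matrix of XYZ coordinates.
#' @param colors numeric N x 3 matrix of R, G, B intensities in
#'   `[0, 255]`. Columns are taken in R, G, B order.
#' @param units_per_cm optional positive scalar: coordinate units per
#'   centimetre. `NULL` (default) leaves traits in reconstruction units.
#' @return An object of class `pointcloud`: a list with elements
#'   `coords`, `colors`, `units_per_cm`.
#' @examples
#' cl <- point_cloud(matrix(rnorm(30), 10, 3),
#'                   matrix(120, 10, 3))
#' cl
#' @export
point_cloud <- function(coords, colors, units_per_cm = NULL) {
  coords <- as.matrix(coords)
  colors <- as.matrix(colors)
  storage.mode(coords) <- "double"
  storage.mode(colors) <- "double"
  if (ncol(coords) != 3L)
    stop("'coords' must have 3 columns (x, y, z)")
  if (ncol(colors) != 3L)
    stop("'colors' must have 3 columns (r, g, b)")
  if (nrow(coords) != nrow(colors))
    stop("'coords' and 'colors' must have the same number of rows")
  if (nrow(coords) < 1L)
    stop("point cloud must contain at least one point")
  if (anyNA(coords) || anyNA(colors))
    stop("point cloud contains missing values")
  if (min(colors) < 0 || max(colors) > 255)
    stop("color intensities must lie in [0, 255]")
  if (!is.null(units_per_cm)) {
    units_per_cm <- as.numeric(units_per_cm)
    if (length(units_per_cm) != 1L || !is.finite(units_per_cm) ||
        units_per_cm <= 0)
      stop("'units_per_cm' must be a positive scalar")
  }
  colnames(coords) <- c("x", "y", "z")
  colnames(colors) <- c("r", "g", "b")
  structure(list(coords = coords, colors = colors,
                 units_per_cm = units_per_cm),
            class = "pointcloud")
}

#' Number of points in a cloud
#'
#' @param cloud a [point_cloud()] object.
#' @return Integer point count.
#' @export
n_points <- function(cloud) {
  stopifnot(inherits(cloud, "pointcloud"))
  nrow(cloud$coords)
}

#' @export
print.pointcloud <- function(x, ...) {
  cat(sprintf("Colored point cloud: %d points\n", nrow(x$coords)))
  rg <- apply(x$coords, 2, range)
  cat(sprintf("  extent  x: [%.3g, %.3g]  y: [%.3g, %.3g]  z: [%.3g, %.3g]\n",
              rg[1, 1], rg[2, 1], rg[1, 2], rg[2, 2], rg[1, 3], rg[2, 3]))
  cat(sprintf("  mean RGB: (%.0f, %.0f, %.0f)\n",
              mean(x$colors[, 1]), mean(x$colors[, 2]), mean(x$colors[, 3])))
  if (!is.null(x$units_per_cm))
    cat(sprintf("  metric scale: %g units per cm\n", x$units_per_cm))
  invisible(x)
}

#' Subset a point cloud
#'
#' @param cloud a [point_cloud()] object.
#' @param i integer or logical index vector over points.
#' @return The sub-cloud, retaining the metric scale.
#' @export
subset_cloud <- function(cloud, i) {
  stopifnot(inherits(cloud, "pointcloud"))
  point_cloud(cloud$coords[i, , drop = FALSE],
              cloud$colors[i, , drop = FALSE],
              units_per_cm = cloud$units_per_cm)
}

#' Apply a rigid motion to a point cloud
#'
#' Rotates and translates the coordinates, leaving colors untouched.
#' Used mostly to verify that digital traits are intrinsic (invariant
#' under rigid motion of the reconstruction frame).
#'
#' @param cloud a [point_cloud()] object.
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric offset (default zero).
#' @return The transformed cloud.
#' @export
transform_cloud <- function(cloud, rotation = diag(3),
                            translation = c(0, 0, 0)) {
  stopifnot(inherits(cloud, "pointcloud"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("'rotation' must be a 3 x 3 matrix")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("'rotation' must be orthonormal")
  co <- cloud$coords %*% t(rotation)
  co <- sweep(co, 2, as.numeric(translation), "+")
  point_cloud(co, cloud$colors, units_per_cm = cloud$units_per_cm)
}

#' Random rotation matrix
#'
#' Draws a rotation uniformly from SO(3) (QR of a Gaussian matrix with
#' sign fix). Handy for rigid-invariance checks.
#'
#' @param seed optional integer seed for reproducibility.
#' @return A 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    m <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(m)
    q <- qr.Q(qr_)
    d <- sign(diag(qr.R(qr_)))
    d[d == 0] <- 1
    q <- q %*% diag(d)
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Median nearest-neighbour spacing of a point set
#'
#' Estimates the typical inter-point spacing as the median distance to
#' the nearest neighbour, computed with a grid hash over the full set
#' (an evenly spaced subsample of query points keeps the cost bounded
#' for large clouds). This spacing drives the default voxel size
#' (`2 x` spacing) and the default alpha radius of the concave boundary
#' (`3 x` spacing of the projected points).
#'
#' @param coords numeric matrix with 2 or 3 columns.
#' @param sample_n maximum number of query points (default 2000).
#' @return Positive scalar spacing, in the units of `coords`.
#' @export
median_nn_spacing <- function(coords, sample_n = 2000L) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!ncol(coords) %in% c(2L, 3L))
    stop("'coords' must have 2 or 3 columns")
  if (nrow(coords) < 2L)
    stop("need at least 2 points to measure spacing")
  d <- .nn_spacing_cpp(coords, as.integer(sample_n))
  d <- d[is.finite(d)]
  if (!length(d))
    stop("could not measure point spacing (coincident points?)")
  m <- median(d)
  if (m <= 0) {
    # coincident duplicates dominate; fall back to positive distances
    dpos <- d[d > 0]
    if (!length(dpos))
      stop("all sampled points are coincident")
    m <- median(dpos)
  }
  m
}
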