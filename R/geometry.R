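#' Fit the intrinsic panicle coordinate frame by PCA
#'
#' The frame takes the first principal direction of the point
#' coordinates as the Z-axis (the panicle's long axis), the second as
#' the X-axis and their cross product as the Y-axis, with the origin at
#' the lowest cloud point along Z. Sign conventions make the frame a
#' deterministic function of the geometry: the Z sign is chosen so that
#' `dot(z_axis, up_hint) >= 0` (PCA eigenvectors are sign-ambiguous and
#' "up" must come from the capture rig), and the X sign so that the
#' third central moment of the X projections is non-negative. With both
#' fixed, the frame — and every trait computed in it — is equivariant
#' under rigid motion of the cloud.
#'
#' @param cloud a [point_cloud()] object with at least 3 non-collinear
#'   points.
#' @param up_hint length-3 vector indicating the vertical of the
#'   capture rig (default world +Z).
#' @return An object of class `panicle_frame`: list with `origin`,
#'   `z_axis`, `x_axis`, `y_axis` (orthonormal), and `eigenvalues`.
#' @export
fit_panicle_frame <- function(cloud, up_hint = c(0, 0, 1)) {
  stopifnot(inherits(cloud, "pointcloud"))
  co <- cloud$coords
  if (nrow(co) < 3L)
    stop("frame fitting needs at least 3 points")
  up_hint <- as.numeric(up_hint)
  if (length(up_hint) != 3L || all(up_hint == 0))
    stop("'up_hint' must be a non-zero length-3 vector")
  ctr <- colMeans(co)
  cc <- sweep(co, 2, ctr)
  S <- crossprod(cc) / nrow(cc)
  ev <- eigen(S, symmetric = TRUE)
  scale2 <- sum(diag(S))
  if (scale2 <= 0)
    stop("degenerate geometry: all points coincident")
  if (ev$values[2] / ev$values[1] < 1e-10)
    stop("degenerate geometry: points are collinear")
  z <- ev$vectors[, 1]
  if (sum(z * up_hint) < 0) z <- -z
  x <- ev$vectors[, 2]
  if (mean((cc %*% x)^3) < 0) x <- -x
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  origin <- co[which.min(co %*% z), ]
  structure(list(origin = as.numeric(origin),
                 z_axis = as.numeric(z),
                 x_axis = as.numeric(x),
                 y_axis = as.numeric(y),
                 eigenvalues = ev$values),
            class = "panicle_frame")
}

#' @export
print.panicle_frame <- function(x, ...) {
  cat("Panicle frame (PCA)\n")
  cat(sprintf("  z-axis: (%.3f, %.3f, %.3f)  variance share %.1f%%\n",
              x$z_axis[1], x$z_axis[2], x$z_axis[3],
              100 * x$eigenvalues[1] / sum(x$eigenvalues)))
  cat(sprintf("  origin: (%.3g, %.3g, %.3g)\n",
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

# coordinates of the cloud in the frame (columns x, y, z)
.frame_coords <- function(coords, frame) {
  p <- sweep(coords, 2, frame$origin)
  m <- p %*% cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Voxelize a point cloud
#'
#' Bins points into cubic voxels of side `voxel_size`, anchored at the
#' minimum corner of the (possibly frame-transformed) coordinates. The
#' number of occupied voxels is the voxel count trait VC, a volume
#' proxy for the panicle.
#'
#' @param cloud a [point_cloud()] object.
#' @param voxel_size positive grid resolution; default `2 x` median
#'   nearest-neighbour spacing.
#' @param frame optional [fit_panicle_frame()] result; when given,
#'   binning happens in the intrinsic frame coordinates so VC is
#'   invariant under rigid motion of the cloud.
#' @return An object of class `voxel_grid`: list with `voxel_size`,
#'   `occupied` (integer matrix of voxel indices), `voxel_count` and
#'   `point_voxel` (voxel row of each point).
#' @export
voxelize <- function(cloud, voxel_size = NULL, frame = NULL) {
  stopifnot(inherits(cloud, "pointcloud"))
  co <- cloud$coords
  if (!is.null(frame)) {
    stopifnot(inherits(frame, "panicle_frame"))
    co <- .frame_coords(co, frame)
  }
  if (is.null(voxel_size))
    voxel_size <- 2 * median_nn_spacing(co)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("'voxel_size' must be a positive number")
  ix <- .voxel_keys(co, voxel_size)
  keys <- .encode_keys(ix)
  uk <- unique(keys)
  structure(list(voxel_size = voxel_size,
                 occupied = ix[!duplicated(keys), , drop = FALSE],
                 voxel_count = length(uk),
                 point_voxel = match(keys, uk)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d occupied voxels (size %.4g) from %d points\n",
              x$voxel_count, x$voxel_size, length(x$point_voxel)))
  invisible(x)
}

.project2d <- function(coords, frame, angle_deg) {
  p <- sweep(coords, 2, frame$origin)
  th <- angle_deg * pi / 180
  u <- cos(th) * frame$x_axis + sin(th) * frame$y_axis
  cbind(p %*% u, p %*% frame$z_axis)
}

.shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

.hull_area <- function(xy) {
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy)
  if (length(h) < 3L) return(0)
  .shoelace(xy[h, , drop = FALSE])
}

.thin_grid <- function(xy, ct) {
  key <- floor(sweep(xy, 2, apply(xy, 2, min)) / ct)
  keep <- !duplicated(key[, 1] + (max(key[, 1]) + 2) * key[, 2])
  xy[keep, , drop = FALSE]
}

.alpha_area <- function(xy, alpha = NULL) {
  if (nrow(xy) < 3L) return(0)
  spacing <- tryCatch(median_nn_spacing(xy), error = function(e) NA_real_)
  if (!is.finite(spacing) || spacing <= 0) return(0)
  # thin to one representative original point per spacing-sized cell:
  # equalizes the (possibly very uneven) projected sampling density and
  # keeps the triangulation near-linear in silhouette area
  pts <- .thin_grid(xy, spacing)
  if (nrow(pts) < 3L) return(0)
  hull <- .hull_area(pts)
  if (hull <= 0) return(0)
  if (nrow(pts) > 10000L) {
    # re-thin with the cell size that yields ~10k occupied cells over
    # the hull, so the triangulation cost is bounded by silhouette
    # area, not sampling density
    pts <- .thin_grid(xy, sqrt(hull / 10000))
    if (nrow(pts) < 3L) return(0)
  }
  if (is.null(alpha)) {
    # typical uniform-equivalent spacing of the thinned silhouette;
    # robust to rim pile-up, unlike the raw nearest-neighbour median
    alpha <- 3 * sqrt(hull / nrow(pts))
  }
  mn <- apply(pts, 2, min)
  s <- max(apply(pts, 2, max) - mn)
  if (s <= 0) return(0)
  pn <- sweep(pts, 2, mn) / s
  tri <- .delaunay_cpp(pn)
  if (nrow(tri) == 0L) return(0)
  a <- pn[tri[, 1], , drop = FALSE]
  b <- pn[tri[, 2], , drop = FALSE]
  cc <- pn[tri[, 3], , drop = FALSE]
  K <- abs((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) -
           (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])) / 2
  la <- sqrt(rowSums((b - cc)^2))
  lb <- sqrt(rowSums((a - cc)^2))
  lc <- sqrt(rowSums((a - b)^2))
  R <- ifelse(K > 0, la * lb * lc / (4 * K), Inf)
  sum(K[R <= alpha / s]) * s^2
}

.raster_area <- function(xy, cell = NULL) {
  if (nrow(xy) < 3L) return(0)
  spacing <- tryCatch(median_nn_spacing(xy), error = function(e) NA_real_)
  if (!is.finite(spacing) || spacing <= 0) return(0)
  if (is.null(cell)) {
    thin <- .thin_grid(xy, spacing)
    hull <- .hull_area(thin)
    cell <- if (hull > 0) sqrt(hull / nrow(thin)) else spacing
  }
  ext <- max(apply(xy, 2, max) - apply(xy, 2, min))
  if (ext / cell > 2048) cell <- ext / 2048  # cap grid size
  ij <- floor(sweep(xy, 2, apply(xy, 2, min)) / cell)
  pad <- 4L
  nr <- max(ij[, 1]) + 1L + 2L * pad
  nc <- max(ij[, 2]) + 1L + 2L * pad
  M <- matrix(0, nr, nc)
  M[cbind(ij[, 1] + pad + 1L, ij[, 2] + pad + 1L)] <- 1
  brush <- EBImage::makeBrush(5, shape = "disc")
  closed <- EBImage::closing(M, brush)
  filled <- EBImage::fillHull(closed)
  sum(filled > 0) * cell^2
}

#' Projected area of a cloud at one sweep angle
#'
#' Projects the cloud orthogonally onto a plane that contains the
#' frame's Z-axis and whose normal is the Y-axis rotated by `angle_deg`
#' around Z, then returns the area enclosed by the boundary of the
#' projected 2D points. The default boundary is a concave alpha shape:
#' Delaunay triangles with circumradius at most `alpha = 3 x` the
#' typical spacing of the projected points (measured after
#' density-equalizing thinning as `sqrt(hull area / n)`, which is
#' robust to the rim pile-up that orthogonal projection produces).
#' It tracks the branched silhouette of a panicle better than a convex
#' hull; `convex_hull` and a morphological `raster` occupancy estimate
#' are available for cross-checks.
#'
#' @param cloud a [point_cloud()] object (typically the segmented
#'   panicle).
#' @param frame a [fit_panicle_frame()] result.
#' @param angle_deg rotation of the projection plane around Z, degrees.
#' @param method boundary estimator: `"alpha_shape"` (default),
#'   `"convex_hull"`, or `"raster"`.
#' @param alpha optional alpha radius override (coordinate units).
#' @param cell optional raster cell size override.
#' @return The enclosed area, in cm^2 when the cloud carries a
#'   `units_per_cm` scale, otherwise in squared coordinate units.
#'   Fewer than 3 distinct projected points give area 0 with a warning.
#' @export
projected_area <- function(cloud, frame, angle_deg = 0,
                           method = c("alpha_shape", "convex_hull",
                                      "raster"),
                           alpha = NULL, cell = NULL) {
  stopifnot(inherits(cloud, "pointcloud"), inherits(frame, "panicle_frame"))
  method <- match.arg(method)
  xy <- .project2d(cloud$coords, frame, angle_deg)
  if (nrow(unique(xy)) < 3L) {
    warning("fewer than 3 distinct projected points; area is 0")
    return(0)
  }
  area <- switch(method,
                 alpha_shape = .alpha_area(xy, alpha = alpha),
                 convex_hull = .hull_area(xy),
                 raster = .raster_area(xy, cell = cell))
  if (!is.null(cloud$units_per_cm))
    area <- area / cloud$units_per_cm^2
  area
}

#' Rotational projected-area sweep
#'
#' Rotates the projection plane around the panicle Z-axis in steps of
#' `step_deg` over `[0, 180)` — orthogonal projection is invariant
#' under a 180-degree turn of the plane — and records the enclosed
#' area at each angle. With the default 5-degree step this yields 36
#' projected areas, whose mean is the projected panicle area (PPA)
#' used to normalize gas-exchange fluxes. The areas for planes
#' perpendicular to the frame X- and Y-axes are reported alongside.
#'
#' @inheritParams projected_area
#' @param step_deg angular step in degrees; must divide 180 (default 5).
#' @return An object of class `projection_sweep`: list with `angles`,
#'   `areas`, `area_max`, `area_min`, `area_mean`, `area_perp_x`,
#'   `area_perp_y`, `step_deg`, `method`, and `units` (`"cm^2"` or
#'   `"units^2"`).
#' @export
projection_sweep <- function(cloud, frame = NULL, step_deg = 5,
                             method = c("alpha_shape", "convex_hull",
                                        "raster"),
                             alpha = NULL, cell = NULL) {
  stopifnot(inherits(cloud, "pointcloud"))
  method <- match.arg(method)
  if (is.null(frame)) frame <- fit_panicle_frame(cloud)
  if (!is.numeric(step_deg) || length(step_deg) != 1L || step_deg <= 0 ||
      abs(180 / step_deg - round(180 / step_deg)) > 1e-9)
    stop("'step_deg' must be a positive divisor of 180")
  angles <- seq(0, 180 - step_deg, by = step_deg)
  areas <- vapply(angles, function(a)
    projected_area(cloud, frame, a, method = method,
                   alpha = alpha, cell = cell),
    numeric(1))
  structure(list(angles = angles,
                 areas = areas,
                 area_max = max(areas),
                 area_min = min(areas),
                 area_mean = mean(areas),
                 area_perp_x = projected_area(cloud, frame, 90,
                                              method = method,
                                              alpha = alpha, cell = cell),
                 area_perp_y = projected_area(cloud, frame, 0,
                                              method = method,
                                              alpha = alpha, cell = cell),
                 step_deg = step_deg,
                 method = method,
                 units = if (is.null(cloud$units_per_cm)) "units^2"
                         else "cm^2"),
            class = "projection_sweep")
}

#' @export
print.projection_sweep <- function(x, ...) {
  cat(sprintf("Projection sweep: %d angles (step %g deg), method %s\n",
              length(x$angles), x$step_deg, x$method))
  cat(sprintf("  area mean %.4g, min %.4g, max %.4g [%s]\n",
              x$area_mean, x$area_min, x$area_max, x$units))
  invisible(x)
}

#' @export
plot.projection_sweep <- function(x, ...) {
  graphics::plot(x$angles, x$areas, type = "b", pch = 16,
                 xlab = "plane rotation (degrees)",
                 ylab = sprintf("projected area [%s]", x$units),
                 main = "Rotational projected-area sweep", ...)
  graphics::abline(h = x$area_mean, lty = 2)
  invisible(x)
}

#' Whole-cloud green and red color proportions
#'
#' Default (`mode = "intensity"`): the ratio of summed green channel
#' intensity to the summed red plus green intensity over all points,
#' G / (R + G), a proxy for surface chlorophyll; `red_prop` is the
#' complement R / (R + G). `mode = "classify"` instead counts points
#' classified green (G > R) versus red (R > G), ignoring ties, which
#' estimates the fraction of green-dominant points directly.
#'
#' @param cloud a [point_cloud()] object.
#' @param mode `"intensity"` (default) or `"classify"`.
#' @return Named numeric vector `c(green_prop = , red_prop = )`,
#'   summing to 1.
#' @export
color_proportions <- function(cloud, mode = c("intensity", "classify")) {
  stopifnot(inherits(cloud, "pointcloud"))
  mode <- match.arg(mode)
  r <- cloud$colors[, 1]
  g <- cloud$colors[, 2]
  if (mode == "intensity") {
    tot <- sum(r) + sum(g)
    if (tot == 0)
      stop("color proportions undefined: total red + green intensity is 0")
    c(green_prop = sum(g) / tot, red_prop = sum(r) / tot)
  } else {
    ng <- sum(g > r)
    nr <- sum(r > g)
    if (ng + nr == 0)
      stop("color proportions undefined: no red- or green-dominant points")
    c(green_prop = ng / (ng + nr), red_prop = nr / (ng + nr))
  }
}

#' Extract whole-panicle digital traits
#'
#' Bundles the digital traits of a segmented panicle cloud: PPA (the
#' mean of the rotational projected-area sweep, the quantity used to
#' normalize panicle gas exchange), the max/min and axis-perpendicular
#' projected areas, the voxel count VC (binned in the intrinsic PCA
#' frame), and the green/red color proportions.
#'
#' @inheritParams projection_sweep
#' @inheritParams fit_panicle_frame
#' @param voxel_size voxel resolution for VC; default `2 x` median
#'   nearest-neighbour spacing.
#' @param color_mode passed to [color_proportions()].
#' @return An object of class `panicle_traits`: list with `ppa`,
#'   `area_max`, `area_min`, `area_perp_x`, `area_perp_y`,
#'   `voxel_count`, `green_prop`, `red_prop`, plus the underlying
#'   `sweep`, `frame`, `voxel_size`, `n_points` and `units`.
#' @export
extract_traits <- function(cloud, voxel_size = NULL, step_deg = 5,
                           method = c("alpha_shape", "convex_hull",
                                      "raster"),
                           up_hint = c(0, 0, 1),
                           color_mode = c("intensity", "classify"),
                           alpha = NULL, cell = NULL) {
  stopifnot(inherits(cloud, "pointcloud"))
  method <- match.arg(method)
  color_mode <- match.arg(color_mode)
  frame <- fit_panicle_frame(cloud, up_hint = up_hint)
  sweep_ <- projection_sweep(cloud, frame, step_deg = step_deg,
                             method = method, alpha = alpha, cell = cell)
  vg <- voxelize(cloud, voxel_size = voxel_size, frame = frame)
  cp <- color_proportions(cloud, mode = color_mode)
  structure(list(ppa = sweep_$area_mean,
                 area_max = sweep_$area_max,
                 area_min = sweep_$area_min,
                 area_perp_x = sweep_$area_perp_x,
                 area_perp_y = sweep_$area_perp_y,
                 voxel_count = vg$voxel_count,
                 green_prop = unname(cp["green_prop"]),
                 red_prop = unname(cp["red_prop"]),
                 sweep = sweep_,
                 frame = frame,
                 voxel_size = vg$voxel_size,
                 n_points = nrow(cloud$coords),
                 units = sweep_$units,
                 color_mode = color_mode),
            class = "panicle_traits")
}

#' @export
print.panicle_traits <- function(x, ...) {
  cat("Panicle digital traits\n")
  cat(sprintf("  PPA (mean projected area): %.4g %s\n", x$ppa, x$units))
  cat(sprintf("  projected area min/max:    %.4g / %.4g %s\n",
              x$area_min, x$area_max, x$units))
  cat(sprintf("  voxel count (VC):          %d (voxel size %.4g)\n",
              x$voxel_count, x$voxel_size))
  cat(sprintf("  green / red proportion:    %.3f / %.3f (%s mode)\n",
              x$green_prop, x$red_prop, x$color_mode))
  cat(sprintf("  points: %d\n", x$n_points))
  invisible(x)
}

#' @export
summary.panicle_traits <- function(object, ...) {
  out <- as.data.frame(object[c("ppa", "area_max", "area_min",
                                "area_perp_x", "area_perp_y",
                                "voxel_count", "green_prop",
                                "red_prop", "n_points")])
  out
}

#' @export
plot.panicle_traits <- function(x, ...) {
  plot(x$sweep, ...)
  invisible(x)
}
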