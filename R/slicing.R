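#' Partition a panicle into equal sections along its axis
#'
#' Splits the Z-extent of the cloud (in the intrinsic PCA frame) into
#' `n_slices` equal intervals and computes per-slice traits: point
#' count, voxel count, summed red/green channel intensities and the
#' green/red proportions. Slice 1 is the top-most section (maximal Z,
#' the hook end of the panicle) and slice `n_slices` the bottom-most.
#' Interior interval boundaries are half-open with boundary points
#' assigned to the upper (lower-index) slice.
#'
#' @param cloud a segmented [point_cloud()].
#' @param frame optional [fit_panicle_frame()] result; fitted from the
#'   cloud when omitted. Passing an explicit frame allows slicing along
#'   an arbitrary axis (e.g. the world vertical).
#' @param n_slices number of sections (default 10).
#' @param voxel_size voxel resolution for per-slice voxel counts;
#'   default `2 x` the whole-cloud median nearest-neighbour spacing
#'   (shared by all slices so counts are comparable).
#' @param color_mode passed to [color_proportions()].
#' @return An object of class `slice_profile`: a data.frame with one
#'   row per slice (`slice`, `z_lo`, `z_hi`, `point_count`,
#'   `voxel_count`, `r_sum`, `g_sum`, `green_prop`, `red_prop`,
#'   `empty`), slice 1 first. Empty slices carry zero counts and `NA`
#'   proportions with `empty = TRUE`. The per-point slice assignment is
#'   kept in attribute `"slice_of"`.
#' @export
slice_cloud <- function(cloud, frame = NULL, n_slices = 10,
                        voxel_size = NULL,
                        color_mode = c("intensity", "classify")) {
  stopifnot(inherits(cloud, "pointcloud"))
  color_mode <- match.arg(color_mode)
  if (!is.numeric(n_slices) || length(n_slices) != 1L ||
      n_slices < 1 || n_slices != round(n_slices))
    stop("'n_slices' must be a positive integer")
  n_slices <- as.integer(n_slices)
  if (is.null(frame)) frame <- fit_panicle_frame(cloud)
  z <- .frame_coords(cloud$coords, frame)[, "z"]
  zmin <- min(z)
  zmax <- max(z)
  w <- (zmax - zmin) / n_slices
  if (w > 0) {
    i0 <- floor((z - zmin) / w)           # 0-based interval from bottom
    i0[i0 >= n_slices] <- n_slices - 1L   # close the top interval
    slice_of <- n_slices - as.integer(i0) # 1 = top
  } else {
    slice_of <- rep(1L, length(z))
  }
  if (is.null(voxel_size))
    voxel_size <- 2 * median_nn_spacing(cloud$coords)
  rows <- lapply(seq_len(n_slices), function(k) {
    in_k <- slice_of == k
    npts <- sum(in_k)
    z_hi <- zmax - (k - 1) * w
    z_lo <- zmax - k * w
    if (npts == 0L) {
      return(data.frame(slice = k, z_lo = z_lo, z_hi = z_hi,
                        point_count = 0L, voxel_count = 0L,
                        r_sum = 0, g_sum = 0,
                        green_prop = NA_real_, red_prop = NA_real_,
                        empty = TRUE))
    }
    sub <- subset_cloud(cloud, in_k)
    vc <- voxelize(sub, voxel_size = voxel_size, frame = frame)$voxel_count
    r_sum <- sum(sub$colors[, 1])
    g_sum <- sum(sub$colors[, 2])
    cp <- tryCatch(color_proportions(sub, mode = color_mode),
                   error = function(e) c(green_prop = NA_real_,
                                         red_prop = NA_real_))
    data.frame(slice = k, z_lo = z_lo, z_hi = z_hi,
               point_count = npts, voxel_count = vc,
               r_sum = r_sum, g_sum = g_sum,
               green_prop = unname(cp["green_prop"]),
               red_prop = unname(cp["red_prop"]),
               empty = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_slices") <- n_slices
  attr(out, "voxel_size") <- voxel_size
  attr(out, "color_mode") <- color_mode
  attr(out, "slice_of") <- slice_of  # per-point slice assignment
  class(out) <- c("slice_profile", "data.frame")
  out
}

#' @export
print.slice_profile <- function(x, ...) {
  cat(sprintf("Slice profile: %d slices (slice 1 = top), %d points total\n",
              attr(x, "n_slices"), sum(x$point_count)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.slice_profile <- function(x, trait = "green_prop", ...) {
  v <- x[[trait]]
  graphics::plot(v, x$slice, type = "b", pch = 16,
                 ylim = rev(range(x$slice)),
                 xlab = trait, ylab = "slice (1 = top)",
                 main = "Panicle slice profile", ...)
  invisible(x)
}

#' Replicate-averaged slice-profile matrix
#'
#' Assembles one trait from several slice profiles into a slice-by-
#' condition matrix, averaging replicate profiles within each group and
#' ignoring flagged empty slices — the layout behind the spatial
#' heat maps that compare genotypes and treatments.
#'
#' @param profiles list of [slice_cloud()] results with identical
#'   `n_slices`.
#' @param trait column to extract (e.g. `"green_prop"`,
#'   `"voxel_count"`, `"point_count"`).
#' @param groups optional factor/character of length `length(profiles)`
#'   assigning each profile to a condition column; default one column
#'   averaging all profiles.
#' @return Numeric matrix `n_slices x n_groups` with slice rows
#'   (1 = top) and group columns.
#' @export
profile_matrix <- function(profiles, trait = "green_prop",
                           groups = NULL) {
  if (inherits(profiles, "slice_profile")) profiles <- list(profiles)
  if (!length(profiles) || !all(vapply(profiles, inherits, logical(1),
                                       "slice_profile")))
    stop("'profiles' must be a list of slice_cloud() results")
  ns <- vapply(profiles, function(p) attr(p, "n_slices"), integer(1))
  if (length(unique(ns)) != 1L)
    stop("profiles disagree on n_slices (",
         paste(unique(ns), collapse = ", "), ")")
  n <- ns[1]
  if (is.null(groups)) groups <- rep("all", length(profiles))
  if (length(groups) != length(profiles))
    stop("'groups' must match the number of profiles")
  groups <- factor(groups, levels = unique(groups))
  if (!trait %in% names(profiles[[1]]))
    stop("unknown trait column: ", trait)
  out <- sapply(levels(groups), function(gr) {
    vals <- sapply(profiles[groups == gr], function(p) {
      v <- p[[trait]]
      v[p$empty] <- NA
      v
    })
    rowMeans(as.matrix(vals), na.rm = TRUE)
  })
  out <- matrix(out, nrow = n,
                dimnames = list(slice = seq_len(n),
                                group = levels(groups)))
  out
}
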