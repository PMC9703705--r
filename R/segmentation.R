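#' Visible Atmospherically Resistant Index per point
#'
#' VARI = (G - R) / (G + R - B), computed from each point's RGB
#' intensities. Green vegetation scores clearly positive while gray
#' backgrounds score near zero, which is what makes the index usable
#' for picking the panicle cluster out of reconstruction clutter.
#' Points with a zero denominator (G + R = B) are colorimetrically
#' degenerate: their value is set to 0 and flagged.
#'
#' @param cloud a [point_cloud()] object.
#' @return An object of class `vari_scores`: list with `values`
#'   (length-N numeric) and `undefined` (length-N logical flags).
#' @examples
#' cl <- point_cloud(matrix(0, 2, 3),
#'                   rbind(c(0, 255, 0), c(120, 120, 120)))
#' compute_vari(cl)$values  # 1 for pure green, 0 for gray
#' @export
compute_vari <- function(cloud) {
  stopifnot(inherits(cloud, "pointcloud"))
  r <- cloud$colors[, 1]
  g <- cloud$colors[, 2]
  b <- cloud$colors[, 3]
  den <- g + r - b
  undef <- den == 0
  vals <- numeric(length(den))
  vals[!undef] <- (g[!undef] - r[!undef]) / den[!undef]
  structure(list(values = vals, undefined = undef), class = "vari_scores")
}

#' @export
print.vari_scores <- function(x, ...) {
  cat(sprintf("VARI scores: %d points, %d degenerate; median %.3f, %d with VARI > 0.1\n",
              length(x$values), sum(x$undefined), median(x$values),
              sum(x$values > 0.1)))
  invisible(x)
}

.voxel_keys <- function(coords, voxel_size, origin = NULL) {
  if (is.null(origin)) origin <- apply(coords, 2, min)
  ix <- floor(sweep(coords, 2, origin) / voxel_size)
  storage.mode(ix) <- "integer"
  ix
}

.encode_keys <- function(ix) {
  lo <- apply(ix, 2, min)
  ix <- sweep(ix, 2, lo)
  k1 <- max(ix[, 1]) + 2
  k2 <- max(ix[, 2]) + 2
  as.numeric(ix[, 1]) + k1 * (as.numeric(ix[, 2]) + k2 * as.numeric(ix[, 3]))
}

#' Cluster a point cloud by voxel-grid connected components
#'
#' Bins points on a regular grid of side `voxel_size` and labels as one
#' cluster every set of points whose occupied voxels form a
#' 26-connected component (sharing a face, edge or corner). This is the
#' connected-component labeling step of panicle segmentation: the
#' panicle, the plant and background clutter end up in different
#' components whenever the spatial gap between them exceeds the grid
#' resolution.
#'
#' @param cloud a [point_cloud()] object.
#' @param voxel_size positive grid resolution in coordinate units;
#'   default `2 x` the cloud's median nearest-neighbour spacing.
#' @return An object of class `cluster_labels`: list with `labels`
#'   (length-N integers in `1..n_clusters`), `n_clusters`, and the
#'   `voxel_size` used.
#' @export
cluster_points <- function(cloud, voxel_size = NULL) {
  stopifnot(inherits(cloud, "pointcloud"))
  if (is.null(voxel_size))
    voxel_size <- 2 * median_nn_spacing(cloud$coords)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("'voxel_size' must be a positive number")
  n <- nrow(cloud$coords)
  ix <- .voxel_keys(cloud$coords, voxel_size)
  keys <- .encode_keys(ix)
  uk <- unique(keys)
  vox_of_point <- match(keys, uk)
  nv <- length(uk)
  if (nv == 1L) {
    return(structure(list(labels = rep(1L, n), n_clusters = 1L,
                          voxel_size = voxel_size),
                     class = "cluster_labels"))
  }
  uix <- ix[!duplicated(keys), , drop = FALSE]
  # half the 26-neighbourhood; the other half comes in as reverse edges
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs %*% c(1, 3, 9) > 0, , drop = FALSE]
  lo <- apply(ix, 2, min)
  uix0 <- sweep(uix, 2, lo)
  k1 <- max(ix[, 1] - lo[1]) + 2
  k2 <- max(ix[, 2] - lo[2]) + 2
  enc <- function(m) as.numeric(m[, 1]) + k1 * (as.numeric(m[, 2]) +
                                                k2 * as.numeric(m[, 3]))
  ukey0 <- enc(uix0)
  edges <- NULL
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(uix0, 2, -offs[o, ])
    hit <- match(enc(nb), ukey0)
    from <- which(!is.na(hit))
    if (length(from))
      edges <- rbind(edges, cbind(from, hit[from]))
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  labels <- comp$membership[vox_of_point]
  structure(list(labels = as.integer(labels),
                 n_clusters = as.integer(comp$no),
                 voxel_size = voxel_size),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  sz <- sort(tabulate(x$labels), decreasing = TRUE)
  cat(sprintf("Voxel-grid clustering: %d clusters (voxel size %.4g)\n",
              x$n_clusters, x$voxel_size))
  cat("  sizes:", paste(head(sz, 8), collapse = ", "),
      if (length(sz) > 8) "..." else "", "\n")
  invisible(x)
}

#' Select the panicle cluster by the VARI majority rule
#'
#' The cluster containing the maximum number of points with VARI
#' strictly greater than `vari_threshold` is taken to be the panicle.
#' Ties are broken by larger total point count, then by lowest label.
#'
#' @param cloud a [point_cloud()] object.
#' @param labels a [cluster_points()] result aligned with `cloud`.
#' @param vari a [compute_vari()] result aligned with `cloud`.
#' @param vari_threshold greenness cutoff (default 0.1).
#' @return The panicle sub-cloud, with the selected point indices in
#'   attribute `"indices"` and the winning label in attribute `"label"`.
#' @export
select_panicle_cluster <- function(cloud, labels, vari,
                                   vari_threshold = 0.1) {
  stopifnot(inherits(cloud, "pointcloud"),
            inherits(labels, "cluster_labels"),
            inherits(vari, "vari_scores"))
  n <- nrow(cloud$coords)
  if (length(labels$labels) != n || length(vari$values) != n)
    stop("'labels' and 'vari' must align with 'cloud'")
  qual <- tabulate(labels$labels[vari$values > vari_threshold],
                   nbins = labels$n_clusters)
  if (all(qual == 0))
    stop("no cluster contains any point with VARI > ", vari_threshold,
         " (no panicle found)")
  size <- tabulate(labels$labels, nbins = labels$n_clusters)
  ord <- order(-qual, -size, seq_along(qual))
  win <- ord[1]
  idx <- which(labels$labels == win)
  out <- subset_cloud(cloud, idx)
  attr(out, "indices") <- idx
  attr(out, "label") <- win
  out
}

#' Cluster report table
#'
#' One row per cluster: label, size and number of points passing the
#' VARI threshold. Written alongside segmented clouds for auditability.
#'
#' @inheritParams select_panicle_cluster
#' @return A data.frame with columns `label`, `size`, `n_qualifying`.
#' @export
cluster_report <- function(labels, vari, vari_threshold = 0.1) {
  stopifnot(inherits(labels, "cluster_labels"),
            inherits(vari, "vari_scores"))
  qual <- tabulate(labels$labels[vari$values > vari_threshold],
                   nbins = labels$n_clusters)
  data.frame(label = seq_len(labels$n_clusters),
             size = tabulate(labels$labels, nbins = labels$n_clusters),
             n_qualifying = qual)
}

#' Segment the panicle from a raw cloud
#'
#' Convenience pipeline: VARI scoring, voxel-grid connected-component
#' clustering, then selection of the cluster with the most points
#' scoring VARI above the threshold.
#'
#' @inheritParams cluster_points
#' @inheritParams select_panicle_cluster
#' @return A list of class `panicle_segmentation`: `cloud` (the panicle
#'   sub-cloud), `indices` (row indices into the input), `labels`,
#'   `vari`, and `report` (the [cluster_report()] table).
#' @export
segment_panicle <- function(cloud, voxel_size = NULL,
                            vari_threshold = 0.1) {
  vari <- compute_vari(cloud)
  labels <- cluster_points(cloud, voxel_size = voxel_size)
  sel <- select_panicle_cluster(cloud, labels, vari,
                                vari_threshold = vari_threshold)
  structure(list(cloud = sel,
                 indices = attr(sel, "indices"),
                 labels = labels,
                 vari = vari,
                 report = cluster_report(labels, vari, vari_threshold)),
            class = "panicle_segmentation")
}

#' @export
print.panicle_segmentation <- function(x, ...) {
  cat(sprintf("Panicle segmentation: %d of %d points selected (cluster %d of %d)\n",
              length(x$indices), length(x$labels$labels),
              attr(x$cloud, "label"), x$labels$n_clusters))
  invisible(x)
}
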