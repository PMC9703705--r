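# Shared fixtures and independent oracles for the test suite.

# brute-force O(N^2) connected components: points closer than
# `threshold` are linked; transitive closure by union-find
brute_components <- function(coords, threshold) {
  n <- nrow(coords)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d2 <- as.matrix(dist(coords))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (d2[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# TRUE iff every group of `a` lies inside a single group of `b`
refines <- function(a, b) {
  all(tapply(b, a, function(v) length(unique(v))) == 1L)
}

# polygon area by the shoelace formula (oracle for hull areas)
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# small deterministic cloud with the given colors recycled over rows
make_cloud <- function(coords, color = c(60, 180, 50)) {
  coords <- as.matrix(coords)
  point_cloud(coords,
              matrix(rep(color, length.out = 3 * nrow(coords)),
                     ncol = 3, byrow = TRUE))
}

# axis-aligned noisy segment along +Z, a minimal frame fixture
line_cloud <- function(n = 200, jitter = 0.01, seed = 1) {
  withr::with_seed(seed, {
    z <- seq(0, 10, length.out = n)
    make_cloud(cbind(rnorm(n, 0, jitter), rnorm(n, 0, jitter), z))
  })
}

# Jaccard index between two index sets
jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# default small panicle + one gray clutter blob, for segmentation tests
clutter_panicle_spec <- function(seed, ...) {
  panicle_spec(n_primary_branches = 6, spikelets_per_branch = 5,
               points_per_spikelet = 30,
               clutter = list(clutter_cluster(c(9, 9, -5),
                                              n = 1500, sd = 1)),
               seed = seed, ...)
}
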