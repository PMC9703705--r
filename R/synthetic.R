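## Synthetic panicle clouds, analytic primitives and gas-exchange
## cohorts with known ground truth. Every generator is a pure function
## of its parameters and seed.

.GREEN_MEAN <- c(60, 180, 50)   # red-channel, green-channel, blue-channel
.GREEN_SD   <- c(15, 20, 15)
.RED_MEAN   <- c(180, 60, 50)   # green-dominant palette with R/G swapped
.RED_SD     <- c(20, 15, 15)
.GRAY_MEAN  <- 120
.GRAY_SD    <- 10

.draw_colors <- function(class, n) {
  if (class == "gray") {
    # gray means equal channels: a per-point luminance with only small
    # independent channel jitter, so VARI stays near 0 as for a real
    # achromatic background
    L <- rnorm(n, .GRAY_MEAN, .GRAY_SD)
    m <- cbind(L, L, L) + matrix(rnorm(3 * n, 0, 2), n, 3)
  } else {
    mu <- switch(class, green = .GREEN_MEAN, red = .RED_MEAN)
    sdv <- switch(class, green = .GREEN_SD, red = .RED_SD)
    m <- cbind(rnorm(n, mu[1], sdv[1]), rnorm(n, mu[2], sdv[2]),
               rnorm(n, mu[3], sdv[3]))
  }
  m <- round(m)
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

#' Specification of a synthetic panicle cloud
#'
#' Parameters of the branched-panicle generator: a gently arced rachis
#' of length `rachis_length` (quadratic bend, so the principal axis and
#' the chord differ slightly), `n_primary_branches` branches bearing
#' Gaussian spikelet blobs, and an axial color gradient. Each point is
#' drawn green-dominant with probability interpolated linearly along
#' the panicle height between `green_gradient[2]` at the bottom and
#' `green_gradient[1]` at the top, red-dominant otherwise — emulating
#' the chlorophyll gradient of a ripening panicle. Optional clutter
#' clusters emulate reconstruction background (pot, labels).
#'
#' @param rachis_length rachis length in cm (default 17, a typical
#'   temperate japonica panicle).
#' @param n_primary_branches number of primary branches (default 10).
#' @param spikelets_per_branch spikelets per branch (default 8).
#' @param points_per_spikelet reconstruction points per spikelet blob
#'   (default 60).
#' @param green_gradient `(top, bottom)` green-dominant fractions in
#'   `[0, 1]` (default `c(0.95, 0.7)`).
#' @param noise_sd isotropic positional jitter sd in cm (default 0.05).
#' @param clutter list of [clutter_cluster()] descriptions.
#' @param seed integer seed; identical seeds give identical clouds.
#' @return An object of class `panicle_spec`.
#' @export
panicle_spec <- function(rachis_length = 17,
                         n_primary_branches = 10,
                         spikelets_per_branch = 8,
                         points_per_spikelet = 60,
                         green_gradient = c(0.95, 0.7),
                         noise_sd = 0.05,
                         clutter = list(),
                         seed = 1) {
  if (rachis_length <= 0) stop("'rachis_length' must be positive")
  counts <- c(n_primary_branches, spikelets_per_branch,
              points_per_spikelet)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("branch/spikelet/point counts must be integers >= 1")
  green_gradient <- as.numeric(green_gradient)
  if (length(green_gradient) != 2L || any(green_gradient < 0) ||
      any(green_gradient > 1))
    stop("'green_gradient' must be a (top, bottom) pair in [0, 1]")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(rachis_length = rachis_length,
                 n_primary_branches = as.integer(n_primary_branches),
                 spikelets_per_branch = as.integer(spikelets_per_branch),
                 points_per_spikelet = as.integer(points_per_spikelet),
                 green_gradient = green_gradient,
                 noise_sd = noise_sd,
                 clutter = clutter,
                 seed = as.integer(seed)),
            class = "panicle_spec")
}

#' Describe a background clutter cluster
#'
#' @param offset length-3 centre of the cluster, in cm, relative to the
#'   panicle base.
#' @param n number of points.
#' @param sd isotropic spread of the Gaussian blob in cm.
#' @param color `"gray"`, `"green"` or `"red"` palette.
#' @return A list consumed by [panicle_spec()]'s `clutter` argument.
#' @export
clutter_cluster <- function(offset, n = 1000, sd = 0.8,
                            color = c("gray", "green", "red")) {
  color <- match.arg(color)
  offset <- as.numeric(offset)
  if (length(offset) != 3L) stop("'offset' must be length 3")
  if (n < 1) stop("'n' must be >= 1")
  list(offset = offset, n = as.integer(n), sd = sd, color = color)
}

#' Generate a synthetic panicle point cloud with ground truth
#'
#' Builds a branched panicle: points along an arced rachis, along
#' primary branches attached to it, and Gaussian spikelet blobs on the
#' branches, colored by the axial green gradient of the spec; clutter
#' clusters are appended last. Deterministic per seed.
#'
#' @param spec a [panicle_spec()].
#' @return List with `cloud` (a [point_cloud()]) and `truth`, a list
#'   carrying `is_panicle` (per-point logical), `green_class`
#'   (per-point logical, `NA` for clutter), `p_green` (per-point
#'   programmed probability, `NA` for clutter) and the `spec`.
#' @export
generate_panicle <- function(spec) {
  stopifnot(inherits(spec, "panicle_spec"))
  withr::with_seed(spec$seed, .generate_panicle_impl(spec))
}

.generate_panicle_impl <- function(spec) {
  L <- spec$rachis_length
  bend <- 0.12 * L
  rachis_curve <- function(t) cbind(bend * t^2, 0, t * L)
  step <- 0.04
  # rachis spine
  tt <- seq(0, 1, by = step / L)
  pts <- rachis_curve(tt)
  # branches: attachment spread along the rachis, drooping outward
  nb <- spec$n_primary_branches
  t_att <- seq(0.15, 0.95, length.out = nb)
  az <- runif(nb, 0, 2 * pi)
  blen <- 0.30 * L * (1 - 0.35 * t_att)
  spike_pts <- NULL
  for (j in seq_len(nb)) {
    base <- rachis_curve(t_att[j])
    dir <- c(cos(az[j]) * 0.8, sin(az[j]) * 0.8, 0.6)
    dir <- dir / sqrt(sum(dir^2))
    s <- seq(0, blen[j], by = step)
    bpts <- sweep(outer(s, dir), 2, as.numeric(base), "+")
    pts <- rbind(pts, bpts)
    # spikelet blobs along the branch
    s_sp <- seq(0.25, 1, length.out = spec$spikelets_per_branch) * blen[j]
    for (sk in s_sp) {
      ctr <- as.numeric(base) + sk * dir
      blob <- cbind(rnorm(spec$points_per_spikelet, ctr[1], 0.12),
                    rnorm(spec$points_per_spikelet, ctr[2], 0.12),
                    rnorm(spec$points_per_spikelet, ctr[3], 0.12))
      spike_pts <- rbind(spike_pts, blob)
    }
  }
  pts <- rbind(pts, spike_pts)
  if (spec$noise_sd > 0)
    pts <- pts + matrix(rnorm(length(pts), 0, spec$noise_sd), nrow(pts))
  n_pan <- nrow(pts)
  # axial green gradient: top fraction at max height, bottom at min
  z <- pts[, 3]
  h <- (z - min(z)) / max(max(z) - min(z), .Machine$double.eps)
  p_green <- spec$green_gradient[2] +
    h * (spec$green_gradient[1] - spec$green_gradient[2])
  is_green <- runif(n_pan) < p_green
  colors <- matrix(0, n_pan, 3)
  if (any(is_green)) colors[is_green, ] <- .draw_colors("green",
                                                        sum(is_green))
  if (any(!is_green)) colors[!is_green, ] <- .draw_colors("red",
                                                          sum(!is_green))
  is_panicle <- rep(TRUE, n_pan)
  green_class <- is_green
  pg <- p_green
  for (cl in spec$clutter) {
    blob <- cbind(rnorm(cl$n, cl$offset[1], cl$sd),
                  rnorm(cl$n, cl$offset[2], cl$sd),
                  rnorm(cl$n, cl$offset[3], cl$sd))
    pts <- rbind(pts, blob)
    colors <- rbind(colors, .draw_colors(cl$color, cl$n))
    is_panicle <- c(is_panicle, rep(FALSE, cl$n))
    green_class <- c(green_class, rep(NA, cl$n))
    pg <- c(pg, rep(NA_real_, cl$n))
  }
  cloud <- point_cloud(pts, colors, units_per_cm = 1)
  list(cloud = cloud,
       truth = list(is_panicle = is_panicle,
                    green_class = green_class,
                    p_green = pg,
                    spec = spec))
}

#' Generate an analytic primitive point cloud
#'
#' Uniformly samples a named surface or solid with a constant green
#' color. These primitives have closed-form silhouettes (a sphere
#' shell of radius r projects to a disc of area pi r^2; a solid
#' cylinder side-on to a 2r x h rectangle; a box face to its known
#' area) and serve as independent oracles for the projected-area and
#' slicing code.
#'
#' @param shape `"sphere_shell"`, `"cylinder"` or `"box"`.
#' @param n_points number of points (>= 100).
#' @param r radius (sphere, cylinder).
#' @param h height (cylinder, along Z).
#' @param edges length-3 edge lengths (box).
#' @param seed integer seed.
#' @return A [point_cloud()].
#' @export
generate_primitive <- function(shape = c("sphere_shell", "cylinder",
                                         "box"),
                               n_points = 10000, r = 1, h = 10,
                               edges = c(1, 2, 3), seed = 1) {
  shape <- match.arg(shape)
  if (n_points < 100) stop("'n_points' must be at least 100")
  n <- as.integer(n_points)
  pts <- withr::with_seed(as.integer(seed), switch(shape,
    sphere_shell = {
      g <- matrix(rnorm(3 * n), n, 3)
      g / sqrt(rowSums(g^2)) * r
    },
    cylinder = {
      th <- runif(n, 0, 2 * pi)
      rad <- r * sqrt(runif(n))
      cbind(rad * cos(th), rad * sin(th), runif(n, 0, h))
    },
    box = {
      cbind(runif(n, 0, edges[1]), runif(n, 0, edges[2]),
            runif(n, 0, edges[3]))
    }))
  point_cloud(pts, matrix(rep(.GREEN_MEAN, each = n), n, 3))
}

#' Factorial design for a synthetic gas-exchange cohort
#'
#' One row per tissue x genotype x treatment x timepoint cell with the
#' programmed mean assimilation `mean_A`, mean transpiration `mean_E`
#' and replicate count `n`. The default design mirrors a two-genotype
#' heat-stress experiment measured at 4 and 10 days after
#' fertilization (n = 4 plants per cell): a heat-sensitive genotype
#' whose leaf and panicle assimilation drop under heat at 10 DAF (-56%
#' and -26%) and a tolerant genotype whose assimilation rises (+57%
#' leaf, +121% panicle), with transpiration responses to match.
#' Baselines are typical rice values (flag leaf A 22 µmol m^-2 s^-1,
#' E 5 mmol m^-2 s^-1; panicle A 6, E 2 — panicle assimilation roughly
#' 30% of the flag leaf).
#'
#' @return data.frame with columns `tissue`, `genotype`, `treatment`,
#'   `daf`, `mean_A`, `mean_E`, `n`.
#' @export
default_gas_design <- function() {
  base <- expand.grid(tissue = c("leaf", "panicle"),
                      genotype = c("sensitive", "tolerant"),
                      treatment = c("control", "heat"),
                      daf = c(4L, 10L),
                      KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  base$mean_A <- ifelse(base$tissue == "leaf", 22, 6)
  base$mean_E <- ifelse(base$tissue == "leaf", 5, 2)
  mult_A <- rep(1, nrow(base))
  mult_E <- rep(1, nrow(base))
  heat <- base$treatment == "heat"
  leaf <- base$tissue == "leaf"
  sens <- base$genotype == "sensitive"
  d10 <- base$daf == 10L
  # 10 DAF heat responses: the headline genotype contrast
  mult_A[heat & d10 & leaf & sens] <- 0.44
  mult_A[heat & d10 & leaf & !sens] <- 1.57
  mult_A[heat & d10 & !leaf & sens] <- 0.74
  mult_A[heat & d10 & !leaf & !sens] <- 2.21
  # transpiration: sensitive leaf closes stomata, tolerant keeps
  # transpiring; panicle E is elevated under heat at 4 DAF
  mult_E[heat & leaf & sens] <- 0.6
  mult_E[heat & leaf & !sens] <- 1.2
  mult_E[heat & !leaf & base$daf == 4L] <- 1.3
  mult_E[heat & !leaf & d10 & !sens] <- 1.3
  base$mean_A <- base$mean_A * mult_A
  base$mean_E <- base$mean_E * mult_E
  base$n <- 4L
  base
}

#' Generate a synthetic gas-exchange cohort
#'
#' Draws per-replicate assimilation and transpiration values from the
#' cell means of a factorial design with Gaussian noise proportional
#' to the mean (`noise_cv`), enabling end-to-end percent-change and
#' correlation tests against the programmed truth.
#'
#' @param design a design table as from [default_gas_design()].
#' @param noise_cv coefficient of variation of the replicate noise
#'   (default 0.08, consistent with modest between-plant scatter at
#'   n = 3-4); 0 gives noiseless cell means.
#' @param seed integer seed.
#' @return data.frame with one row per replicate: the design labels
#'   plus `replicate`, `A`, `E` and `wue`. The design is attached as
#'   attribute `"design"`.
#' @export
generate_gas_exchange_cohort <- function(design = default_gas_design(),
                                         noise_cv = 0.08, seed = 1) {
  design <- as.data.frame(design)
  need <- c("tissue", "genotype", "treatment", "daf", "mean_A",
            "mean_E", "n")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (noise_cv < 0) stop("'noise_cv' must be non-negative")
  out <- withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nrow(design)), function(i) {
      d <- design[i, ]
      A <- rnorm(d$n, d$mean_A, noise_cv * abs(d$mean_A))
      E <- rnorm(d$n, d$mean_E, noise_cv * abs(d$mean_E))
      E <- pmax(E, 0.05 * abs(d$mean_E))  # keep transpiration positive
      data.frame(tissue = d$tissue, genotype = d$genotype,
                 treatment = d$treatment, daf = d$daf,
                 replicate = seq_len(d$n), A = A, E = E)
    })
    do.call(rbind, rows)
  })
  out$wue <- wue(out$A, out$E)
  attr(out, "design") <- design
  out
}
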