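test_that("PCA frame recovers an axis-aligned elongated cloud", {
  cl <- line_cloud(n = 500, jitter = 0.05, seed = 2)
  fr <- fit_panicle_frame(cl)
  # dominant eigenvector of the sample covariance must be ~ world Z
  ang <- acos(min(1, abs(sum(fr$z_axis * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 1)
  expect_equal(crossprod(cbind(fr$x_axis, fr$y_axis, fr$z_axis)),
               diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  # origin is the cloud point with minimal projection on the axis
  expect_equal(fr$origin,
               unname(cl$coords[which.min(cl$coords %*% fr$z_axis), ]))
})

test_that("the frame is equivariant under rigid motion", {
  sim <- generate_panicle(panicle_spec(seed = 3,
                                       n_primary_branches = 5,
                                       spikelets_per_branch = 4,
                                       points_per_spikelet = 20))
  fr <- fit_panicle_frame(sim$cloud)
  for (s in 1:5) {
    Q <- random_rotation(seed = s)
    cl2 <- transform_cloud(sim$cloud, Q, c(3, -1, 7))
    fr2 <- fit_panicle_frame(cl2, up_hint = as.numeric(Q %*% c(0, 0, 1)))
    for (ax in c("z_axis", "x_axis", "y_axis")) {
      ang <- acos(min(1, abs(sum(fr2[[ax]] * (Q %*% fr[[ax]]))))) * 180 / pi
      expect_lt(ang, 1)
    }
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(fit_panicle_frame(make_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))),
               "at least 3")
  collinear <- make_cloud(cbind(0, 0, seq(0, 1, length.out = 10)))
  expect_error(fit_panicle_frame(collinear), "collinear")
})

test_that("voxelization bins points like the brute-force assignment", {
  corners <- as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10)))
  vg <- voxelize(make_cloud(corners), voxel_size = 1)
  expect_equal(vg$voxel_count, 8L)
  # all points coincident collapse to a single voxel
  same <- make_cloud(matrix(rep(c(1, 2, 3), 50), 50, 3, byrow = TRUE))
  expect_equal(voxelize(same, voxel_size = 0.5)$voxel_count, 1L)
  # pigeonhole and monotonicity in resolution
  withr::with_seed(51, pts <- matrix(runif(600, 0, 5), 200, 3))
  cl <- make_cloud(pts)
  counts <- sapply(c(4, 2, 1, 0.5, 0.1), function(v)
    voxelize(cl, voxel_size = v)$voxel_count)
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts <= 200))
  expect_error(voxelize(cl, voxel_size = 0), "positive")
})

test_that("alpha-shape area agrees with the convex hull on convex sets", {
  withr::with_seed(61, {
    th <- runif(4000) * 2 * pi
    r <- sqrt(runif(4000))
    xy <- cbind(r * cos(th), r * sin(th))
  })
  # with an unbounded alpha the triangulation fills the convex hull
  full <- panicle3d:::.alpha_area(xy, alpha = 1e6)
  hull <- shoelace_area(xy[chull(xy), ])
  expect_equal(full, hull, tolerance = 0.01)
})

test_that("projected areas match analytic silhouettes", {
  sp <- generate_primitive("sphere_shell", n_points = 20000, r = 1,
                           seed = 8)
  fr <- fit_panicle_frame(sp)
  for (ang in c(0, 35, 90, 140)) {
    expect_equal(projected_area(sp, fr, ang), pi, tolerance = 0.03)
    expect_equal(projected_area(sp, fr, ang, method = "convex_hull"),
                 pi, tolerance = 0.03)
    expect_equal(projected_area(sp, fr, ang, method = "raster"),
                 pi, tolerance = 0.10)
  }
})

test_that("alpha-shape areas never exceed the convex hull", {
  sim <- generate_panicle(panicle_spec(seed = 9,
                                       n_primary_branches = 6,
                                       spikelets_per_branch = 5,
                                       points_per_spikelet = 25))
  fr <- fit_panicle_frame(sim$cloud)
  for (ang in c(0, 45, 100)) {
    a <- projected_area(sim$cloud, fr, ang)
    h <- projected_area(sim$cloud, fr, ang, method = "convex_hull")
    expect_lte(a, h * (1 + 1e-8))
  }
})

test_that("degenerate projections give zero area with a warning", {
  fr <- fit_panicle_frame(line_cloud(seed = 3))
  two <- make_cloud(rbind(c(0, 0, 0), c(0, 0, 1)))
  expect_warning(a <- projected_area(two, fr, 0), "fewer than 3")
  expect_equal(a, 0)
})

test_that("the default sweep has 36 angles and coherent summaries", {
  sim <- generate_panicle(panicle_spec(seed = 10,
                                       n_primary_branches = 5,
                                       spikelets_per_branch = 4,
                                       points_per_spikelet = 15))
  sw <- projection_sweep(sim$cloud)
  expect_length(sw$areas, 36)
  expect_equal(sw$angles, seq(0, 175, by = 5))
  expect_lte(sw$area_min, sw$area_mean)
  expect_lte(sw$area_mean, sw$area_max)
  sw45 <- projection_sweep(sim$cloud, step_deg = 45)
  expect_length(sw45$areas, 4)
  expect_error(projection_sweep(sim$cloud, step_deg = 7), "divisor of 180")
})

test_that("the sweep is 180-degree periodic", {
  sim <- generate_panicle(panicle_spec(seed = 12,
                                       n_primary_branches = 5,
                                       spikelets_per_branch = 4,
                                       points_per_spikelet = 15))
  fr <- fit_panicle_frame(sim$cloud)
  for (ang in c(10, 75)) {
    expect_equal(projected_area(sim$cloud, fr, ang, method = "convex_hull"),
                 projected_area(sim$cloud, fr, ang + 180,
                                method = "convex_hull"))
    expect_equal(projected_area(sim$cloud, fr, ang),
                 projected_area(sim$cloud, fr, ang + 180),
                 tolerance = 0.01)
  }
})

test_that("a sphere sweep is rotationally flat", {
  sp <- generate_primitive("sphere_shell", n_points = 20000, r = 1,
                           seed = 13)
  sw <- projection_sweep(sp, fit_panicle_frame(sp))
  expect_lt(sw$area_max - sw$area_min, 0.03 * sw$area_mean)
})

test_that("color proportions match hand-computed ratios", {
  pure <- make_cloud(matrix(rnorm(30), 10, 3), c(0, 255, 0))
  expect_equal(color_proportions(pure),
               c(green_prop = 1, red_prop = 0))
  half <- point_cloud(matrix(rnorm(60), 20, 3),
                      rbind(matrix(rep(c(255, 0, 0), 10), ncol = 3,
                                   byrow = TRUE),
                            matrix(rep(c(0, 255, 0), 10), ncol = 3,
                                   byrow = TRUE)))
  expect_equal(unname(color_proportions(half)), c(0.5, 0.5))
  hand <- point_cloud(matrix(0, 3, 3),
                      cbind(r = c(50, 100, 200), g = c(200, 100, 50),
                            b = c(0, 0, 0)))
  expect_equal(unname(color_proportions(hand)[1]), 350 / 700)
  expect_equal(sum(color_proportions(hand)), 1)
  blue <- make_cloud(matrix(0, 5, 3), c(0, 0, 255))
  expect_error(color_proportions(blue), "undefined")
})

test_that("trait extraction bundles the sweep, VC and colors", {
  sim <- generate_panicle(panicle_spec(seed = 14, green_gradient = c(0.8, 0.8),
                                       n_primary_branches = 6,
                                       spikelets_per_branch = 5,
                                       points_per_spikelet = 30))
  tr <- extract_traits(sim$cloud, color_mode = "classify")
  expect_s3_class(tr, "panicle_traits")
  expect_equal(tr$ppa, tr$sweep$area_mean)
  # classification recovers the programmed green fraction
  expect_equal(tr$green_prop, mean(sim$truth$green_class), tolerance = 0.02)
  expect_equal(tr$green_prop + tr$red_prop, 1)
  expect_equal(summary(tr)$voxel_count, tr$voxel_count)
})

test_that("traits are invariant under rigid motion", {
  sim <- generate_panicle(panicle_spec(seed = 15,
                                       n_primary_branches = 6,
                                       spikelets_per_branch = 5,
                                       points_per_spikelet = 25))
  tr <- extract_traits(sim$cloud)
  for (s in 1:4) {
    Q <- random_rotation(seed = 100 + s)
    tr2 <- extract_traits(transform_cloud(sim$cloud, Q, c(-2, 4, 1)),
                          up_hint = as.numeric(Q %*% c(0, 0, 1)))
    for (f in c("ppa", "area_max", "area_min", "voxel_count",
                "green_prop", "red_prop"))
      expect_equal(tr2[[f]], tr[[f]], tolerance = 0.01)
  }
})

test_that("sphere traits match the analytic oracle", {
  sp <- generate_primitive("sphere_shell", n_points = 20000, r = 1,
                           seed = 16)
  tr <- extract_traits(sp)
  expect_equal(tr$ppa, pi, tolerance = 0.03)
})
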