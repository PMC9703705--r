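test_that("default slicing yields 10 ordered slices that conserve totals", {
  sim <- generate_panicle(panicle_spec(seed = 20,
                                       n_primary_branches = 6,
                                       spikelets_per_branch = 5,
                                       points_per_spikelet = 30))
  cl <- sim$cloud
  sl <- slice_cloud(cl)
  expect_equal(nrow(sl), 10L)
  expect_equal(sl$slice, 1:10)
  # slice 1 sits at maximal Z
  expect_true(all(diff(sl$z_hi) < 0))
  # conservation of points and channel sums
  expect_equal(sum(sl$point_count), n_points(cl))
  expect_equal(sum(sl$r_sum), sum(cl$colors[, 1]))
  expect_equal(sum(sl$g_sum), sum(cl$colors[, 2]))
  # whole-cloud green proportion recomposes exactly from slice sums
  expect_equal(sum(sl$g_sum) / sum(sl$g_sum + sl$r_sum),
               unname(color_proportions(cl)["green_prop"]))
  # equal-width partition of [z_min, z_max]
  widths <- sl$z_hi - sl$z_lo
  expect_equal(widths, rep(widths[1], 10))
})

test_that("a single slice reproduces the whole-cloud traits", {
  sim <- generate_panicle(panicle_spec(seed = 21,
                                       n_primary_branches = 5,
                                       spikelets_per_branch = 4,
                                       points_per_spikelet = 20))
  sl <- slice_cloud(sim$cloud, n_slices = 1)
  expect_equal(nrow(sl), 1L)
  expect_equal(sl$point_count, n_points(sim$cloud))
  cp <- color_proportions(sim$cloud)
  expect_equal(sl$green_prop, unname(cp["green_prop"]))
  expect_error(slice_cloud(sim$cloud, n_slices = 0), "positive integer")
})

test_that("a uniform cylinder fills slices evenly", {
  n <- 20000
  cy <- generate_primitive("cylinder", n_points = n, r = 0.5, h = 10,
                           seed = 22)
  sl <- slice_cloud(cy)
  expect_true(all(abs(sl$point_count - n / 10) <= 3 * sqrt(n / 10)))
})

test_that("reversing the up hint reverses the slice order exactly", {
  sim <- generate_panicle(panicle_spec(seed = 23,
                                       n_primary_branches = 6,
                                       spikelets_per_branch = 5,
                                       points_per_spikelet = 25))
  f1 <- fit_panicle_frame(sim$cloud, up_hint = c(0, 0, 1))
  f2 <- fit_panicle_frame(sim$cloud, up_hint = c(0, 0, -1))
  s1 <- slice_cloud(sim$cloud, f1)
  s2 <- slice_cloud(sim$cloud, f2)
  expect_equal(s1$point_count, rev(s2$point_count))
  expect_equal(s1$g_sum, rev(s2$g_sum))
})

test_that("empty slices are flagged, not fabricated", {
  # two dense blobs far apart along Z leave hollow middle slices
  withr::with_seed(24, {
    a <- matrix(rnorm(900, sd = 0.3), 300, 3)
    b <- matrix(rnorm(900, sd = 0.3), 300, 3)
    b[, 3] <- b[, 3] + 30
  })
  cl <- make_cloud(rbind(a, b))
  sl <- slice_cloud(cl, n_slices = 10)
  expect_true(any(sl$empty))
  expect_true(all(is.na(sl$green_prop[sl$empty])))
  expect_true(all(sl$point_count[sl$empty] == 0))
  expect_equal(sum(sl$point_count), 600)
})

test_that("profile matrices average replicates and respect shape", {
  sims <- lapply(1:3, function(s)
    generate_panicle(panicle_spec(seed = 30 + s,
                                  n_primary_branches = 5,
                                  spikelets_per_branch = 4,
                                  points_per_spikelet = 40)))
  profs <- lapply(sims, function(s) slice_cloud(s$cloud,
                                                color_mode = "classify"))
  # idempotent mean: identical profiles average to themselves
  m <- profile_matrix(list(profs[[1]], profs[[1]]))
  expect_equal(unname(m[, 1]), profs[[1]]$green_prop)
  # grouped averaging
  mg <- profile_matrix(profs, groups = c("a", "a", "b"))
  expect_equal(dim(mg), c(10L, 2L))
  expect_equal(unname(mg[, "b"]), profs[[3]]$green_prop)
  # mismatched slicing is a shape error
  bad <- slice_cloud(sims[[1]]$cloud, n_slices = 5)
  expect_error(profile_matrix(list(profs[[1]], bad)), "n_slices")
})

test_that("averaged profiles recover the programmed color gradient", {
  grad <- c(0.95, 0.55)
  sims <- lapply(1:3, function(s)
    generate_panicle(panicle_spec(seed = 40 + s,
                                  green_gradient = grad,
                                  n_primary_branches = 6,
                                  spikelets_per_branch = 5,
                                  points_per_spikelet = 40)))
  profs <- lapply(sims, function(s) slice_cloud(s$cloud,
                                                color_mode = "classify"))
  m <- profile_matrix(profs)
  # per-slice ground truth: mean of the drawn green classes per slice
  truth <- rowMeans(sapply(seq_along(sims), function(i) {
    so <- attr(profs[[i]], "slice_of")
    sapply(1:10, function(k)
      mean(sims[[i]]$truth$green_class[so == k]))
  }))
  est_slope <- stats::coef(stats::lm(m[, 1] ~ seq_len(10)))[2]
  true_slope <- stats::coef(stats::lm(truth ~ seq_len(10)))[2]
  expect_equal(unname(est_slope), unname(true_slope), tolerance = 0.1)
  # gradient runs downhill from slice 1 (top) to slice 10 (bottom)
  expect_lt(est_slope, 0)
})
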