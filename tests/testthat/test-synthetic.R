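test_that("generators are pure functions of spec and seed", {
  sp <- clutter_panicle_spec(seed = 71)
  a <- generate_panicle(sp)
  b <- generate_panicle(sp)
  expect_identical(a$cloud$coords, b$cloud$coords)
  expect_identical(a$cloud$colors, b$cloud$colors)
  expect_identical(a$truth$green_class, b$truth$green_class)
  c <- generate_panicle(clutter_panicle_spec(seed = 72))
  expect_false(identical(a$cloud$coords, c$cloud$coords))
  expect_identical(generate_primitive("cylinder", seed = 2)$coords,
                   generate_primitive("cylinder", seed = 2)$coords)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(panicle_spec(green_gradient = c(1.2, 0.5)), "\\[0, 1\\]")
  expect_error(panicle_spec(n_primary_branches = 0), ">= 1")
  expect_error(panicle_spec(noise_sd = -1), "non-negative")
  expect_error(generate_primitive("box", n_points = 10), "at least 100")
})

test_that("an all-green panicle is nearly all green-dominant", {
  sim <- generate_panicle(panicle_spec(seed = 73,
                                       green_gradient = c(1, 1),
                                       n_primary_branches = 6,
                                       spikelets_per_branch = 5,
                                       points_per_spikelet = 30))
  cp <- color_proportions(sim$cloud, mode = "classify")
  expect_gt(unname(cp["green_prop"]), 0.9)
  expect_true(all(sim$truth$green_class))
})

test_that("segmentation shrugs off a large gray clutter cluster", {
  sp <- panicle_spec(seed = 74, n_primary_branches = 6,
                     spikelets_per_branch = 5, points_per_spikelet = 30,
                     clutter = list(clutter_cluster(c(10, 10, -6),
                                                    n = 10000, sd = 1.5)))
  sim <- generate_panicle(sp)
  seg <- segment_panicle(sim$cloud)
  expect_gte(jaccard(seg$indices, which(sim$truth$is_panicle)), 0.99)
})

test_that("primitive silhouettes match their closed forms", {
  # box: hull area of the angle-0 projection is the known face area
  box <- generate_primitive("box", n_points = 30000, edges = c(1, 2, 3),
                            seed = 75)
  fr <- fit_panicle_frame(box)
  expect_equal(projected_area(box, fr, 0, method = "convex_hull"),
               2 * 3, tolerance = 0.02)
  # cylinder side-on: 2 r h rectangle
  cy <- generate_primitive("cylinder", n_points = 20000, r = 0.5, h = 8,
                           seed = 76)
  expect_equal(projected_area(cy, fit_panicle_frame(cy), 0,
                              method = "convex_hull"),
               2 * 0.5 * 8, tolerance = 0.03)
})

test_that("a noiseless cohort recovers programmed effects exactly", {
  coh <- generate_gas_exchange_cohort(noise_cv = 0, seed = 77)
  des <- attr(coh, "design")
  cell <- function(d, ...) {
    f <- list(...)
    rows <- d
    for (nm in names(f)) rows <- rows[rows[[nm]] == f[[nm]], ]
    rows
  }
  est <- function(tis, gen) {
    hs <- mean(cell(coh, tissue = tis, genotype = gen,
                    treatment = "heat", daf = 10)$A)
    ct <- mean(cell(coh, tissue = tis, genotype = gen,
                    treatment = "control", daf = 10)$A)
    percent_change(hs, ct)
  }
  expect_equal(est("panicle", "tolerant"), 121)
  expect_equal(est("leaf", "tolerant"), 57)
  expect_equal(est("leaf", "sensitive"), -56)
  expect_equal(est("panicle", "sensitive"), -26)
  expect_equal(nrow(coh), sum(des$n))
})

test_that("small-noise cohorts recover effects within sampling bounds", {
  for (s in 1:5) {
    coh <- generate_gas_exchange_cohort(noise_cv = 0.02, seed = 80 + s)
    hs <- coh[coh$tissue == "panicle" & coh$genotype == "tolerant" &
              coh$treatment == "heat" & coh$daf == 10, "A"]
    ct <- coh[coh$tissue == "panicle" & coh$genotype == "tolerant" &
              coh$treatment == "control" & coh$daf == 10, "A"]
    est <- percent_change(mean(hs), mean(ct))
    expect_equal(est, 121, tolerance = 0.15)
  }
})

test_that("correlated traits are recovered by the panel at n = 10", {
  # bivariate normal with r = 0.9 via Cholesky; Fisher-z sampling bound
  for (s in 1:5) {
    withr::with_seed(90 + s, {
      z1 <- rnorm(10)
      z2 <- 0.9 * z1 + sqrt(1 - 0.9^2) * rnorm(10)
    })
    pp <- pearson_panel(data.frame(x = z1, y = z2))
    expect_equal(pp$r["x", "y"], 0.9, tolerance = 0.15 / 0.9)
  }
})

test_that("panicle ground truth aligns with the cloud", {
  sim <- generate_panicle(clutter_panicle_spec(seed = 95))
  expect_length(sim$truth$is_panicle, n_points(sim$cloud))
  expect_length(sim$truth$green_class, n_points(sim$cloud))
  expect_true(all(is.na(sim$truth$green_class[!sim$truth$is_panicle])))
  # green classes were drawn from the programmed probabilities
  pan <- sim$truth$is_panicle
  expect_equal(mean(sim$truth$green_class[pan]),
               mean(sim$truth$p_green[pan]), tolerance = 0.05)
})
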