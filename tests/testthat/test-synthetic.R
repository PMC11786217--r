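test_that("cohort generation is deterministic and honors the empty case", {
  expect_length(generate_cohort(cohort_config(n_patients = 0))$lesions, 0)
  cfg <- cohort_config(n_patients = 2, seed = 33)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  # different seed, different cohort
  cfg2 <- cohort_config(n_patients = 2, seed = 34)
  expect_false(identical(generate_cohort(cfg)$table,
                         generate_cohort(cfg2)$table))
})

test_that("cohort structure: baseline plus follow-ups, paired contours", {
  env <- small_cohort_cache()
  co <- env$cohort
  expect_gt(length(co$lesions), 0)
  for (les in co$lesions) {
    expect_identical(les$times[1], 0)
    expect_gte(length(les$times), 2L)
    for (ob in les$observations) {
      expect_named(ob$masks, c("manual", "automatic"))
    }
  }
  # table bookkeeping matches the mask set
  expect_identical(nrow(co$table),
                   2L * sum(vapply(co$lesions,
                                   function(l) length(l$times), 0L)))
})

test_that("radio-necrosis labeling hits the configured fraction", {
  # label-level run over ~1000 lesions; masks not needed
  cfg <- cohort_config(n_patients = 110, render = FALSE, seed = 5,
                       man_diam_fraction = 1)
  co <- generate_cohort(cfg)
  rn <- vapply(co$lesions, `[[`, TRUE, "radionecrosis")
  n <- length(rn)
  expect_gt(n, 800)
  ci <- stats::qbinom(c(0.005, 0.995), n, 0.109) / n
  expect_gte(mean(rn), ci[1])
  expect_lte(mean(rn), ci[2])
})

test_that("trajectory kinds have their defining shapes", {
  times <- c(0, 60, 130, 200, 290)
  expect_equal(simulate_trajectory(1000, "stable", times, 0, 1),
               rep(1000, 5))
  shr <- simulate_trajectory(1000, "shrink", times, 0, 2)
  expect_true(all(diff(shr) < 0))
  s <- size_series("L", times, shr)
  expect_equal(temporal_monotonicity(s), 1)
  grw <- simulate_trajectory(1000, "grow", times, 0, 3)
  expect_true(all(diff(grw) >= 0))
  cr <- simulate_trajectory(1000, "cr", times, 0.1, 4)
  expect_true(any(cr == 0))
  z <- which(cr == 0)
  expect_identical(z, seq.int(min(z), 5L))  # a suffix of zeros
  expect_gt(cr[1], 0)
  ps <- simulate_trajectory(1000, "pseudo", times, 0, 5)
  d <- diff(ps)
  expect_true(any(d > 0) && any(d < 0))  # a rise and a fall
  expect_error(simulate_trajectory(1000, "shrink", c(0, 50, 50), 0, 1),
               class = "ranobm_invalid_value")
  expect_error(simulate_trajectory(1000, "shrink", c(10, 50), 0, 1),
               class = "ranobm_invalid_value")
})

test_that("rendered ellipsoids converge to the analytic volume", {
  st <- lesion_state(semi_axes = c(7, 5, 4))
  v_true <- 4 / 3 * pi * prod(c(7, 5, 4))
  err <- vapply(c(1, 0.5), function(sp) {
    abs(volume_mm3(render_lesion_mask(st, sp)) - v_true) / v_true
  }, 0)
  expect_lt(err[1], 0.02)
  expect_lt(err[2], err[1])  # finer grid, smaller error
  # sub-voxel lesion still covers its center voxel
  tiny <- render_lesion_mask(lesion_state(semi_axes = rep(0.6, 3)), 1)
  expect_gte(sum(tiny$occupancy), 1)
  # explicit extent must leave a margin
  expect_error(
    render_lesion_mask(lesion_state(semi_axes = c(10, 10, 10)), 1,
                       extent = list(origin = rep(-10, 3), dim = rep(21, 3)),
                       id = "L-big"),
    "L-big")
})

test_that("contour perturbation respects identity, envelope and style", {
  sph <- sphere_mask(8, 1)
  expect_identical(perturb_contour(sph, "manual", 0, 1), sph)
  expect_identical(perturb_contour(sph, "automatic", 0, 1), sph)
  expect_error(perturb_contour(sph, "manual", -1, 1),
               class = "ranobm_invalid_value")
  empty <- mask3d(array(0L, c(4, 4, 4)))
  expect_error(perturb_contour(empty, "manual", 1, 1),
               class = "ranobm_empty_mask")
})

test_that("changed voxels stay within the amplitude envelope", {
  sph <- sphere_mask(8, 1)
  orig <- which(sph$occupancy != 0L, arr.ind = TRUE)
  bg <- which(sph$occupancy == 0L, arr.ind = TRUE)
  for (s in 1:5) {
    p <- perturb_contour(sph, "manual", 1, s)
    added <- which(p$occupancy == 1L & sph$occupancy == 0L, arr.ind = TRUE)
    removed <- which(p$occupancy == 0L & sph$occupancy == 1L, arr.ind = TRUE)
    mindist <- function(pts, ref) {
      vapply(seq_len(nrow(pts)), function(i) {
        sqrt(min(colSums((t(ref) - pts[i, ])^2)))
      }, 0)
    }
    # voxel-center distance to the opposite set; boundary sits half a
    # voxel inside that distance
    if (nrow(added)) expect_lte(max(mindist(added, orig)) - 0.5, 1 + 1e-9)
    if (nrow(removed)) expect_lte(max(mindist(removed, bg)) - 0.5, 1 + 1e-9)
  }
})

test_that("manual sawtooth is rougher along z than the automatic style", {
  sph <- sphere_mask(8, 1)
  dev_var <- function(mk) {
    a <- apply(mk$occupancy, 3, sum)
    r <- apply(sph$occupancy, 3, sum)
    keep <- r > 9
    stats::var(sqrt(a[keep] / pi) - sqrt(r[keep] / pi))
  }
  vm <- vapply(1:20, function(s)
    dev_var(perturb_contour(sph, "manual", 1, s)), 0)
  va <- vapply(1:20, function(s)
    dev_var(perturb_contour(sph, "automatic", 1, s)), 0)
  expect_true(all(vm > va))
})

test_that("simulated manual diameters apply bias and noise around truth", {
  sph <- sphere_mask(8, 1)
  d <- longest_axial_diameter(sph)
  expect_equal(simulate_manual_diameter(sph, bias = 1, noise_sd = 0), d)
  # arithmetic: 0.75 x 10.64 = 7.98
  a <- array(0L, c(16, 5, 3)); a[2:13, 3, 2] <- 1L  # 12 voxels: 11 mm
  elong <- mask3d(a, spacing = 10.64 / 11)
  expect_equal(simulate_manual_diameter(elong, bias = 0.75, noise_sd = 0),
               7.98, tolerance = 1e-9)
  # CLT: mean of 1000 seeded draws within 3 sd-of-mean of 0.75 x truth
  draws <- vapply(1:1000, function(s)
    simulate_manual_diameter(sph, 0.75, 0.5, s), 0)
  expect_lt(abs(mean(draws) - 0.75 * d), 3 * 0.5 / sqrt(1000))
  expect_error(simulate_manual_diameter(mask3d(array(0L, c(4, 4, 4)))),
               class = "ranobm_empty_mask")
})

test_that("noise-free monotone cohorts are perfectly monotone in time", {
  cfg <- cohort_config(
    n_patients = 4, seed = 9, render = FALSE, trajectory_noise_sd = 0,
    trajectory_mix = c(shrink = 0.6, grow = 0.4, stable = 0, pseudo = 0,
                       cr = 0),
    n_followups = list(dist = "poisson", lambda = 3, min = 2))
  co <- generate_cohort(cfg)
  for (les in co$lesions) {
    s <- size_series(les$lesion_id, les$times, les$true_volumes, "true-vol")
    expect_equal(temporal_monotonicity(s), 1, info = les$lesion_id)
  }
})
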