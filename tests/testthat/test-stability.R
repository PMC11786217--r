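test_that("coefficient of variation conventions", {
  expect_equal(coef_variation(rep(3.7, 21)), 0)
  expect_equal(coef_variation(c(8, 10, 12)), 2 / 10)
  expect_error(coef_variation(c(-1, 1)), class = "ranobm_invalid_value")
})

test_that("sphere sizes are rotation-stable; elongated diameters are not", {
  sph <- sphere_mask(10, 1)
  # empirical characterization of the digitized sphere, pinned as a
  # regression bound
  expect_lt(rotation_cov(sph, "diameter"), 0.02)
  expect_lt(rotation_cov(sph, "volume"), 0.01)
  # in-plane elongation perpendicular to the rotation axis: axial sections
  # shrink with tilt while the volume is conserved
  el <- render_lesion_mask(lesion_state(semi_axes = c(5, 15, 5)), 1)
  expect_gt(rotation_cov(el, "diameter"), rotation_cov(el, "volume"))
  expect_error(rotation_cov(mask3d(array(0L, c(4, 4, 4))), "diameter"),
               class = "ranobm_empty_mask")
})

test_that("rotation flips the final category only near a threshold", {
  el <- render_lesion_mask(lesion_state(semi_axes = c(5, 15, 5)), 1)
  d0 <- longest_axial_diameter(el)
  # angle-0 value 20.1% above the nadir (PD); the rotation spread drops
  # below the +20% boundary -> at least one rotated assessment changes
  near <- size_series("L", c(0, 60), c(d0 / 1.201, d0))
  expect_true(rotation_response_change(near, el))
  # far inside the SD band for every rotation -> no change
  sph <- sphere_mask(10, 1)
  far <- size_series("L", c(0, 60), c(20, 19))
  expect_false(rotation_response_change(far, sph))
  # rotation-invariant sphere near nothing -> no change
  sphser <- size_series("L", c(0, 60), c(21, 20))
  expect_false(rotation_response_change(sphser, sph))
  expect_error(
    rotation_response_change(far, sph, rotation_spec(c(-2, 2), "x")),
    class = "ranobm_invalid_value")
})

test_that("temporal monotonicity is |Spearman| with declared conventions", {
  dec <- size_series("L", c(0, 30, 60, 90), c(9, 7, 4, 2))
  expect_equal(temporal_monotonicity(dec), 1)
  # explicit rank-arithmetic oracle
  times <- c(0, 30, 60, 90, 120)
  values <- c(5, 3, 4, 2, 3)
  rt <- rank(times); rv <- rank(values)  # average ranks for the tie
  rho_oracle <- sum((rt - mean(rt)) * (rv - mean(rv))) /
    sqrt(sum((rt - mean(rt))^2) * sum((rv - mean(rv))^2))
  s <- size_series("L", times, values)
  expect_equal(temporal_monotonicity(s), abs(rho_oracle))
  expect_warning(
    z <- temporal_monotonicity(size_series("L", c(0, 30, 60), c(5, 5, 5))),
    "constant")
  expect_equal(z, 0)
  expect_error(temporal_monotonicity(size_series("L", c(0, 30), c(5, 4))),
               class = "ranobm_invalid_series")
})

test_that("consecutive change counting matches the worked examples", {
  expect_equal(consecutive_change_count(c("PR", "CR", "CR")),
               c(changes = 1L, pairs = 2L))
  expect_equal(consecutive_change_count(c("PR", "PR", "PD", "PR")),
               c(changes = 2L, pairs = 3L))
  expect_equal(consecutive_change_count(c("SD", "SD")),
               c(changes = 0L, pairs = 1L))
  expect_error(consecutive_change_count("PR"),
               class = "ranobm_invalid_series")
  # invariant under relabeling: only the equality pattern matters
  set.seed(8)
  for (i in 1:10) {
    x <- sample(c("PD", "SD", "PR", "CR"), 6, replace = TRUE)
    perm <- setNames(sample(c("a", "b", "c", "d")), c("PD", "SD", "PR", "CR"))
    expect_identical(consecutive_change_count(x),
                     consecutive_change_count(unname(perm[x])))
  }
})

test_that("change rates pool counts, not per-lesion rates", {
  expect_equal(pooled_change_rate(list(c(changes = 1, pairs = 2))), 0.5)
  expect_equal(
    pooled_change_rate(list(c(changes = 1, pairs = 2),
                            c(changes = 2, pairs = 3))),
    3 / 5)
  expect_false(isTRUE(all.equal(3 / 5, mean(c(1 / 2, 2 / 3)))))
  expect_equal(
    pooled_change_rate(data.frame(changes = c(0, 0), pairs = c(2, 3))), 0)
  expect_error(pooled_change_rate(list()), class = "ranobm_invalid_value")
})

test_that("paired Wilcoxon matches exact enumeration on small samples", {
  expect_warning(p <- paired_difference_test(1:5, 1:5), "zero")
  expect_equal(p, 1)
  # n = 6, all differences positive and untied: 2 / 2^6
  a <- c(2, 4, 7, 11, 16, 22); b <- a - c(1, 2, 3, 4, 5, 6)
  expect_equal(paired_difference_test(a, b), 2 / 64)
  # sign-flip enumeration oracle for n <= 10
  signed_rank_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    mean(abs(w_all - n * (n + 1) / 4) >= abs(w_obs - n * (n + 1) / 4))
  }
  set.seed(15)
  for (i in 1:5) {
    d <- round(stats::rnorm(8, 0.5, 1), 3)
    d <- d[d != 0]
    while (any(duplicated(abs(d)))) d <- d + stats::rnorm(length(d), 0, 1e-4)
    expect_equal(paired_difference_test(d, rep(0, length(d))),
                 signed_rank_p(d), tolerance = 1e-10)
  }
})

test_that("paired Wilcoxon large-sample p agrees with a permutation oracle", {
  set.seed(4)
  a <- stats::rnorm(50, 0.15, 1); b <- stats::rnorm(50, 0, 1)
  p_pkg <- paired_difference_test(a, b)
  d <- a - b
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  w_perm <- replicate(40000, {
    s <- stats::runif(50) < 0.5
    sum(r[s])
  })
  p_perm <- mean(abs(w_perm - mu) >= abs(w_obs - mu) - 1e-9)
  expect_lt(abs(p_pkg - p_perm), 0.01)
})

test_that("McNemar on discordant pairs matches the binomial oracle", {
  expect_equal(paired_rate_test(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE)),
               1)
  # discordant (5, 0): 2 x 0.5^5
  a <- c(rep(TRUE, 5), rep(FALSE, 10)); b <- rep(FALSE, 15)
  expect_equal(paired_rate_test(a, b), 0.0625)
  # discordant (10, 10): symmetric, p = 1
  a2 <- c(rep(TRUE, 10), rep(FALSE, 10))
  b2 <- c(rep(FALSE, 10), rep(TRUE, 10))
  expect_equal(paired_rate_test(a2, b2), 1)
})
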