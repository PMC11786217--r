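# Fixtures and independent oracles shared across test files.

# Exhaustive O(n^2) oracle for the longest axial diameter: max pairwise
# center-to-center distance among occupied voxels, slice by slice, no
# convex hull. Deliberately independent of the production implementation.
diam_oracle <- function(mask) {
  occ <- mask$occupancy
  sp <- mask$spacing
  best <- 0
  for (k in seq_len(dim(occ)[3])) {
    idx <- which(occ[, , k] != 0L, arr.ind = TRUE)
    if (nrow(idx) < 2L) next
    for (i in seq_len(nrow(idx) - 1L)) {
      dx <- (idx[i, 1] - idx[(i + 1):nrow(idx), 1]) * sp[1]
      dy <- (idx[i, 2] - idx[(i + 1):nrow(idx), 2]) * sp[2]
      best <- max(best, sqrt(max(dx^2 + dy^2)))
    }
  }
  best
}

# Random small blob-like mask (connected-ish random occupancy).
random_small_mask <- function(seed, p = 0.5, maxdim = 12L) {
  set.seed(seed)
  d <- sample(4:maxdim, 3L, replace = TRUE)
  mask3d(array(as.integer(stats::runif(prod(d)) < p), d))
}

sphere_mask <- function(r = 10, spacing = 1) {
  render_lesion_mask(lesion_state(semi_axes = rep(r, 3)), spacing = spacing)
}

# Correlated 4-column Gaussian draws via Cholesky (no extra dependency).
rmvn4 <- function(n, Sig) {
  matrix(stats::rnorm(n * 4), n, 4) %*% chol(Sig)
}

pf_null_sigma <- function(r = 0.5) {
  Sig <- diag(4)
  Sig[1, 2] <- Sig[2, 1] <- r
  Sig[3, 4] <- Sig[4, 3] <- r
  Sig[1, 3] <- Sig[3, 1] <- 0.3
  Sig[2, 4] <- Sig[4, 2] <- 0.3
  Sig[1, 4] <- Sig[4, 1] <- 0.2
  Sig[2, 3] <- Sig[3, 2] <- 0.2
  Sig
}

# Study-scale synthetic cohort (~200 lesions) with cached measurements;
# built once per test run, shared by the stability/agreement/acceptance
# suites.
study_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$cohort)) {
      env$cohort <- generate_cohort(cohort_config(n_patients = 22, seed = 1))
      env$measurements <- measure_cohort(env$cohort)
    }
    env
  }
})

# Small rendered cohort for structural tests.
small_cohort_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$cohort)) {
      env$cohort <- generate_cohort(cohort_config(n_patients = 3, seed = 101))
      env$measurements <- measure_cohort(env$cohort)
    }
    env
  }
})
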