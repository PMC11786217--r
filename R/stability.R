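# Stability of size measurements and response assessments.
#
# Two stability notions are quantified: (1) robustness to rigid rotation of
# the contours, emulating variations in patient head positioning (a rotation
# leaves the lesion intrinsically unchanged, so any measured variation is
# method noise); (2) repeatability across time, under the working hypothesis
# that the true post-treatment size evolution is monotone, so non-monotone
# measured series reflect measurement error.

#' Coefficient of variation
#'
#' `sd(x)/mean(x)` with the sample (n-1) standard deviation; the
#' convention used for all rotation-stability summaries.
#'
#' @param x Numeric vector of repeated size measurements.
#' @return Dimensionless CoV.
#' @export
coef_variation <- function(x) {
  m <- mean(x)
  if (m == 0) {
    stop_ranobm("CoV undefined for mean-zero measurements",
                "ranobm_invalid_value")
  }
  stats::sd(x) / m
}

# Pad a mask so that any rotation about its centroid cannot clip occupied
# voxels (grid must contain the ball of radius max||p - c|| around c).
pad_for_rotation <- function(mask) {
  ctr <- mask_centroid(mask)
  xyz <- occupied_coords(mask)
  r <- sqrt(max(rowSums(sweep(xyz, 2L, ctr)^2)))
  d <- dim(mask$occupancy)
  lo <- mask$origin
  hi <- mask$origin + (d - 1) * mask$spacing
  deficit <- pmax(r - (ctr - lo), r - (hi - ctr), 0)
  pad <- as.integer(ceiling(deficit / mask$spacing)) + 1L
  if (all(pad <= 1L)) mask else pad_mask(mask, max(pad))
}

# Measure diameter and volume for every rotated version of a mask.
rotated_sizes <- function(mask, spec) {
  stopifnot(inherits(spec, "rotation_spec"))
  m <- pad_for_rotation(mask)
  diam <- vol <- numeric(length(spec$angles))
  for (i in seq_along(spec$angles)) {
    r <- rotate_mask(m, spec$angles[i], spec$axes, spec$center)
    diam[i] <- longest_axial_diameter(r)
    vol[i] <- volume_mm3(r)
  }
  list(angles = spec$angles, diameter = diam, volume = vol)
}

#' Rotation stability of one size measurement
#'
#' Rotates the mask through every angle of the specification, measures the
#' size, and returns the coefficient of variation across the rotated
#' versions. Volumes enter as cube roots so that volumetric and
#' unidimensional CoVs are compared on the same linear scale.
#'
#' @param mask A non-empty [mask3d].
#' @param method `"diameter"` or `"volume"`.
#' @param spec A [rotation_spec] (must include angle 0).
#' @return Dimensionless CoV.
#' @export
rotation_cov <- function(mask, method = c("diameter", "volume"),
                         spec = rotation_spec()) {
  method <- match.arg(method)
  if (is_empty_mask(mask)) {
    stop_ranobm("cannot assess rotation stability of an empty mask",
                "ranobm_empty_mask")
  }
  sz <- rotated_sizes(mask, spec)
  x <- if (method == "diameter") sz$diameter else cube_root_size(sz$volume)
  coef_variation(x)
}

#' Does rotating the last observation change the final RANO category?
#'
#' Only the last time point is rotated; baseline and nadir stay at their
#' unrotated measurements. Returns `TRUE` if any rotated re-measurement of
#' the final size flips the final response category relative to the
#' unrotated (angle 0) assessment.
#'
#' @param series The lesion's unrotated [size_series] (baseline through
#'   last follow-up), in the dimensionality of `thresholds`.
#' @param last_mask [mask3d] of the lesion at the last follow-up.
#' @param spec A [rotation_spec]; must include angle 0.
#' @param thresholds A [rano_thresholds]; its `dimension` selects whether
#'   the rotated re-measurement is a diameter or a volume.
#' @return Logical.
#' @export
rotation_response_change <- function(series, last_mask,
                                     spec = rotation_spec(),
                                     thresholds = rano_thresholds()) {
  stopifnot(inherits(series, "size_series"),
            inherits(thresholds, "rano_thresholds"))
  if (!any(spec$angles == 0)) {
    stop_ranobm("rotation spec must include angle 0 (reference category)",
                "ranobm_invalid_value")
  }
  sz <- rotated_sizes(last_mask, spec)
  vals <- if (thresholds$dimension == "diameter") sz$diameter else sz$volume
  nt <- length(series$values)
  final_cat <- function(last_value) {
    v <- series$values
    v[nt] <- last_value
    s <- size_series(series$lesion_id, series$times, v, series$method)
    cats <- classify_rano(s, thresholds)$categories
    as.character(cats[length(cats)])
  }
  ref <- final_cat(vals[spec$angles == 0][1])
  for (v in vals) {
    if (final_cat(v) != ref) return(TRUE)
  }
  FALSE
}

#' Monotonicity of a size series across time
#'
#' The absolute Spearman rank correlation between time since treatment and
#' measured size, over lesions with at least 3 annotated time points.
#' A value of 1 means perfectly monotone evolution; lower values indicate
#' alternating growth/shrinkage, read as measurement instability. Ties are
#' handled by average ranks; an exactly constant series carries no evidence
#' of a monotone trend and is defined as 0, with a warning.
#'
#' @param series A [size_series] with >= 3 time points.
#' @return Absolute Spearman correlation in `[0, 1]`.
#' @export
temporal_monotonicity <- function(series) {
  stopifnot(inherits(series, "size_series"))
  if (length(series$values) < 3L) {
    stop_ranobm("monotonicity needs at least 3 annotated time points",
                "ranobm_invalid_series")
  }
  if (stats::sd(series$values) == 0) {
    warning("constant size series: monotonicity defined as 0")
    return(0)
  }
  abs(stats::cor(series$times, series$values, method = "spearman"))
}

#' Count category changes between consecutive assessments
#'
#' For an assessed category sequence of length L there are L - 1
#' consecutive pairs; a change is an adjacent unequal pair. E.g.
#' `[PR, CR, CR]` (baseline plus two follow-ups) has 1 change out of 2
#' pairs, and `[PR, PR, PD, PR]` has 2 out of 3. Depends only on the
#' equality pattern, not on the labels.
#'
#' @param categories A [response_sequence], factor, or character vector of
#'   length >= 2.
#' @return Named integer vector `c(changes =, pairs =)`.
#' @export
consecutive_change_count <- function(categories) {
  if (inherits(categories, "response_sequence")) {
    categories <- categories$categories
  }
  categories <- as.character(categories)
  if (length(categories) < 2L) {
    stop_ranobm("need at least 2 assessed categories", "ranobm_invalid_series")
  }
  n <- length(categories)
  c(changes = sum(categories[-1] != categories[-n]), pairs = n - 1L)
}

#' Pooled rate of response change
#'
#' Accumulates change and pair counts across lesions before dividing
#' (pooled rate, not a mean of per-lesion rates): records (1, 2) and
#' (2, 3) pool to 3/5 = 0.6.
#'
#' @param records A list of `c(changes =, pairs =)` vectors (as returned by
#'   [consecutive_change_count]), or a matrix/data.frame with columns
#'   `changes` and `pairs`.
#' @return Fraction in `[0, 1]`.
#' @export
pooled_change_rate <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, records)
  }
  records <- as.data.frame(records)
  if (nrow(records) == 0L || sum(records$pairs) == 0) {
    stop_ranobm("no consecutive pairs to pool", "ranobm_invalid_value")
  }
  sum(records$changes) / sum(records$pairs)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares paired stability statistics (e.g. CoVs of two measurement
#' methods over the same lesions). Uses the exact signed-rank distribution
#' for up to 25 informative (non-zero, untied) pairs and the normal
#' approximation with continuity correction otherwise. If every difference
#' is zero the test carries no information and p = 1 is returned with a
#' warning.
#'
#' @param values_a,values_b Equal-length paired numeric vectors.
#' @param exact_max Largest number of informative pairs for which the
#'   exact distribution is used (default 25).
#' @return Two-sided p-value.
#' @export
paired_difference_test <- function(values_a, values_b, exact_max = 25L) {
  if (length(values_a) != length(values_b)) {
    stop_ranobm("paired vectors must have equal length", "ranobm_invalid_value")
  }
  d <- values_a - values_b
  d <- d[!is.na(d)]
  if (length(d) == 0L || all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  nz <- d[d != 0]
  exact <- length(nz) <= exact_max && !any(d == 0) &&
    !any(duplicated(abs(nz)))
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, paired = TRUE,
                       exact = exact, correct = TRUE)$p.value
  )
}

#' Paired two-sided McNemar test on change indicators
#'
#' Compares the response-change rates of two assessment methods over the
#' same lesions via the discordant pairs of a 2x2 contingency table. Exact
#' doubled-binomial p when the discordant total is below 25, chi-squared
#' with continuity correction otherwise; p = 1 when there are no
#' discordant pairs.
#'
#' @param flags_a,flags_b Equal-length paired logical vectors (e.g.
#'   "assessment changed under rotation").
#' @param exact_max Largest discordant total for the exact branch.
#' @return Two-sided p-value.
#' @export
paired_rate_test <- function(flags_a, flags_b, exact_max = 25L) {
  if (length(flags_a) != length(flags_b)) {
    stop_ranobm("paired vectors must have equal length", "ranobm_invalid_value")
  }
  keep <- !is.na(flags_a) & !is.na(flags_b)
  a <- as.logical(flags_a[keep]); b <- as.logical(flags_b[keep])
  n10 <- sum(a & !b)
  n01 <- sum(!a & b)
  nd <- n10 + n01
  if (nd == 0L) return(1)
  if (nd < exact_max) {
    min(1, 2 * stats::pbinom(min(n10, n01), nd, 0.5))
  } else {
    tab <- matrix(c(sum(a & b), n01, n10, sum(!a & !b)), 2L, 2L)
    stats::mcnemar.test(tab, correct = TRUE)$p.value
  }
}
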