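# Per-lesion response classification.
#
# Three assessment families are implemented:
#   * RANO on longest axial diameters (unidimensional): PR at >= 30%
#     decrease vs baseline, PD at >= 20% increase vs the nadir (smallest
#     size across all time points up to the assessed one, baseline
#     included), CR at disappearance, SD otherwise.
#   * RANO on volumes: the same logic with thresholds extrapolated to a
#     sphere (65.7% decrease / 72.8% increase).
#   * Clinician-style: previous time point as reference, with a
#     gadolinium-T1/T2 match flag distinguishing progression from
#     radio-necrosis.

RANO_LEVELS <- c("PD", "SD", "PR", "CR")

#' Extrapolate diameter response thresholds to volumes
#'
#' A sphere whose diameter shrinks by fraction `p` loses `1 - (1 - p)^3` of
#' its volume, and one whose diameter grows by `q` gains `(1 + q)^3 - 1`.
#' Applying this to the unidimensional criteria (30% decrease, 20%
#' increase) yields the volumetric thresholds: 65.7% decrease and 72.8%
#' increase.
#'
#' @param pr_decrease Diameter-decrease fraction defining PR (default 0.30).
#' @param pd_increase Diameter-increase fraction defining PD (default 0.20).
#' @return Named numeric: `pr_decrease` and `pd_increase` volume fractions.
#' @export
#' @examples
#' volumetric_thresholds_from_diameter(0.30, 0.20)  # 0.657, 0.728
volumetric_thresholds_from_diameter <- function(pr_decrease = 0.30,
                                                pd_increase = 0.20) {
  if (pr_decrease < 0 || pr_decrease >= 1 || pd_increase < 0) {
    stop_ranobm("thresholds out of range", "ranobm_invalid_value")
  }
  c(pr_decrease = 1 - (1 - pr_decrease)^3,
    pd_increase = (1 + pd_increase)^3 - 1)
}

#' Response thresholds for RANO classification
#'
#' @param pr_decrease Fractional decrease vs baseline defining PR.
#' @param pd_increase Fractional increase vs nadir defining PD.
#' @param dimension `"diameter"` or `"volume"`; bookkeeping so that a size
#'   series is classified with thresholds of matching dimensionality.
#' @return A `rano_thresholds` list.
#' @export
rano_thresholds <- function(pr_decrease = 0.30, pd_increase = 0.20,
                            dimension = c("diameter", "volume")) {
  dimension <- match.arg(dimension)
  if (pr_decrease <= 0 || pr_decrease >= 1 || pd_increase <= 0) {
    stop_ranobm("pr_decrease must be in (0,1) and pd_increase > 0",
                "ranobm_invalid_value")
  }
  structure(list(pr_decrease = pr_decrease, pd_increase = pd_increase,
                 dimension = dimension),
            class = "rano_thresholds")
}

#' @rdname rano_thresholds
#' @export
rano_thresholds_volume <- function() {
  th <- volumetric_thresholds_from_diameter()
  rano_thresholds(th[["pr_decrease"]], th[["pd_increase"]], "volume")
}

#' A per-lesion size series
#'
#' @param lesion_id Identifier.
#' @param times Days since treatment, strictly increasing, first element
#'   the baseline (day 0 scan at treatment).
#' @param values Sizes (mm or mm^3), non-negative; 0 encodes disappearance.
#'   The baseline value must be positive.
#' @param method Measurement-method label (e.g. `"diam-manseg"`,
#'   `"vol-autoseg"`, `"man-diam"`).
#' @return A `size_series` list.
#' @export
size_series <- function(lesion_id, times, values, method = "diam") {
  if (length(times) != length(values) || length(times) < 2L) {
    stop_ranobm("need aligned times/values with at least one follow-up",
                "ranobm_invalid_series")
  }
  if (any(diff(times) <= 0)) {
    stop_ranobm("times must be strictly increasing", "ranobm_invalid_series")
  }
  if (any(values < 0)) {
    stop_ranobm("sizes must be non-negative", "ranobm_invalid_series")
  }
  if (values[1] <= 0) {
    stop_ranobm("baseline size must be positive (lesion must exist at baseline)",
                "ranobm_invalid_series")
  }
  structure(list(lesion_id = lesion_id, times = as.numeric(times),
                 values = as.numeric(values), method = method),
            class = "size_series")
}

#' Classify a size series with RANO criteria
#'
#' For each follow-up `t` (the baseline itself is not assessed):
#' CR if the size is 0 (disappearance); else PD if the size has increased
#' by at least `pd_increase` relative to the nadir, the smallest size over
#' all time points up to and including `t` (baseline included); else PR if
#' the size has decreased by at least `pr_decrease` relative to baseline;
#' else SD. PD takes precedence over PR when both rules fire. Any positive
#' size after a disappearance (nadir 0) is classified PD.
#'
#' @param series A [size_series].
#' @param thresholds A [rano_thresholds]; pick the dimensionality matching
#'   the series ([rano_thresholds_volume] for volumes).
#' @return A `response_sequence`: list with `categories` (factor over
#'   PD/SD/PR/CR, one per follow-up), plus per-follow-up `reference_value`
#'   (baseline) and `nadir_value`.
#' @export
#' @examples
#' s <- size_series("L1", c(0, 60, 120), c(10, 9, 11))
#' classify_rano(s)$categories  # SD, PD (nadir 9 mm, +22%)
classify_rano <- function(series, thresholds = rano_thresholds()) {
  stopifnot(inherits(series, "size_series"),
            inherits(thresholds, "rano_thresholds"))
  v <- series$values
  baseline <- v[1]
  nt <- length(v)
  cats <- character(nt - 1L)
  nadirs <- numeric(nt - 1L)
  for (t in 2:nt) {
    nadir <- min(v[1:t])
    nadirs[t - 1L] <- nadir
    cats[t - 1L] <- if (v[t] == 0) {
      "CR"
    } else if (nadir == 0 || v[t] >= (1 + thresholds$pd_increase) * nadir) {
      "PD"
    } else if (v[t] <= (1 - thresholds$pr_decrease) * baseline) {
      "PR"
    } else {
      "SD"
    }
  }
  response_sequence(series$lesion_id, series$times[-1], cats,
                    method = paste0("RANO-", series$method),
                    reference_value = baseline, nadir_value = nadirs)
}

#' Clinician-style previous-reference assessment
#'
#' Emulates radiologist assessment: each follow-up is compared with the
#' previous time point's longest diameter. CR on disappearance; PR at a
#' >= 30% decrease; a >= 20% increase is PD when the gadolinium-T1/T2
#' signals match and the growth pattern is consulted against the mismatch
#' flag: any diameter increase with a T1/T2 mismatch is read as
#' radio-necrosis (RN). SD otherwise. Regrowth after disappearance is PD.
#'
#' @param series A [size_series] of diameters.
#' @param t1t2_match Logical per follow-up: does the lesion's
#'   gadolinium-T1 enhancement match the T2 signal? Required (non-NA)
#'   whenever the diameter increased.
#' @param pr_decrease,pd_increase Fractions (defaults 0.30 / 0.20).
#' @param rn_growth_threshold Minimum fractional increase at which a
#'   mismatch is read as RN; the default 0 (any increase) follows clinical
#'   reading practice.
#' @return A `response_sequence` whose categories may include `"RN"`.
#' @export
classify_clinician_style <- function(series, t1t2_match,
                                     pr_decrease = 0.30, pd_increase = 0.20,
                                     rn_growth_threshold = 0) {
  stopifnot(inherits(series, "size_series"))
  v <- series$values
  nt <- length(v)
  if (length(t1t2_match) != nt - 1L) {
    stop_ranobm("need one t1t2_match flag per follow-up",
                "ranobm_invalid_series")
  }
  cats <- character(nt - 1L)
  for (t in 2:nt) {
    prev <- v[t - 1]; cur <- v[t]; match_t <- t1t2_match[t - 1L]
    cats[t - 1L] <- if (cur == 0) {
      "CR"
    } else if (prev == 0) {
      "PD"
    } else {
      growth <- cur / prev - 1
      if (growth > rn_growth_threshold && is.na(match_t)) {
        stop_ranobm(
          sprintf("lesion %s grew at follow-up %d but t1t2_match is missing",
                  series$lesion_id, t - 1L),
          "ranobm_missing_flag"
        )
      }
      if (growth > rn_growth_threshold && !match_t) {
        "RN"
      } else if (growth >= pd_increase) {
        "PD"
      } else if (-growth >= pr_decrease) {
        "PR"
      } else {
        "SD"
      }
    }
  }
  response_sequence(series$lesion_id, series$times[-1], cats,
                    method = "cliAssess-u",
                    reference_value = v[-nt], nadir_value = NA_real_,
                    levels = c(RANO_LEVELS, "RN"))
}

#' Ordered response categories for one lesion and one method
#'
#' @param lesion_id Identifier.
#' @param times Follow-up days (baseline has no category).
#' @param categories Character vector over PD/SD/PR/CR (plus RN for the
#'   clinician-style method).
#' @param method Assessment-method label.
#' @param reference_value,nadir_value Per-follow-up reference sizes
#'   (recycled), for audit output.
#' @param levels Category levels.
#' @return A `response_sequence` list.
#' @export
response_sequence <- function(lesion_id, times, categories, method = "RANO",
                              reference_value = NA_real_,
                              nadir_value = NA_real_,
                              levels = RANO_LEVELS) {
  if (length(times) != length(categories)) {
    stop_ranobm("times and categories must align", "ranobm_invalid_series")
  }
  if (!all(categories %in% levels)) {
    stop_ranobm("unknown response category", "ranobm_invalid_series")
  }
  structure(list(lesion_id = lesion_id, times = as.numeric(times),
                 categories = factor(categories, levels = levels),
                 method = method,
                 reference_value = rep_len(reference_value, length(times)),
                 nadir_value = rep_len(nadir_value, length(times))),
            class = "response_sequence")
}

#' @export
print.response_sequence <- function(x, ...) {
  cat(sprintf("<response_sequence> %s [%s]: %s\n", x$lesion_id, x$method,
              paste(as.character(x$categories), collapse = " ")))
  invisible(x)
}

#' Exclude radio-necrotic lesions from cross-method comparisons
#'
#' Radio-necrosis is not a RANO category and cannot be compared with the
#' automated assessments, so lesions ever labeled radio-necrotic are
#' removed wholesale before method comparison.
#'
#' @param sequences Named (by lesion) list of objects (e.g.
#'   [response_sequence]s) to filter.
#' @param labels Logical vector (or character turned logical on `"RN"`),
#'   aligned with `sequences`, marking radio-necrotic lesions.
#' @return List with `sequences` (the kept elements), `n_excluded` and
#'   `fraction_excluded`.
#' @export
exclude_radionecrosis <- function(sequences, labels) {
  if (is.character(labels)) labels <- labels == "RN"
  if (length(labels) != length(sequences)) {
    stop_ranobm("labels must align with sequences", "ranobm_invalid_value")
  }
  labels[is.na(labels)] <- FALSE
  list(sequences = sequences[!labels],
       n_excluded = sum(labels),
       fraction_excluded = if (length(labels)) mean(labels) else 0)
}
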