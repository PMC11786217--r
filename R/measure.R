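# Cohort-level plumbing: from generated (or loaded) lesion trajectories to
# size measurements, size series, response sequences, and the pooled
# stability analyses.

SIZE_METHODS <- c("vol-manseg", "vol-autoseg", "diam-manseg", "diam-autoseg",
                  "man-diam")

method_for <- function(kind, source) {
  paste0(kind, "-", c(manual = "manseg", automatic = "autoseg")[source])
}

#' Measure every lesion of a cohort
#'
#' Applies the two contour-derived size measures (voxel-count volume and
#' longest axial diameter) to both contour sources at every time point,
#' and carries through the simulated manually measured diameters.
#'
#' @param cohort A `bm_cohort` from [generate_cohort] (rendered).
#' @return Long data.frame: `lesion_id`, `time_days`, `method`, `value`.
#' @export
measure_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "bm_cohort"))
  rows <- vector("list", 0L)
  for (les in cohort$lesions) {
    for (t in seq_along(les$times)) {
      ob <- les$observations[[t]]
      if (!is.null(ob$masks)) {
        for (src in c("manual", "automatic")) {
          m <- ob$masks[[src]]
          rows[[length(rows) + 1L]] <- data.frame(
            lesion_id = les$lesion_id, time_days = ob$time_days,
            method = method_for("vol", src), value = volume_mm3(m),
            stringsAsFactors = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            lesion_id = les$lesion_id, time_days = ob$time_days,
            method = method_for("diam", src),
            value = longest_axial_diameter(m), stringsAsFactors = FALSE)
        }
      }
      if (!is.na(ob$manual_diameter) || les$true_volumes[t] == 0) {
        if (les$has_manual_diam) {
          rows[[length(rows) + 1L]] <- data.frame(
            lesion_id = les$lesion_id, time_days = ob$time_days,
            method = "man-diam",
            value = if (les$true_volumes[t] == 0) 0 else ob$manual_diameter,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Build per-lesion size series for one measurement method
#'
#' @param measurements Data.frame from [measure_cohort].
#' @param method One of the size-measurement labels (see `SIZE_METHODS`).
#' @return Named list of [size_series] (lesions with a positive baseline
#'   and at least one follow-up).
#' @export
cohort_series <- function(measurements, method) {
  d <- measurements[measurements$method == method, , drop = FALSE]
  out <- list()
  for (lid in unique(d$lesion_id)) {
    di <- d[d$lesion_id == lid, , drop = FALSE]
    di <- di[order(di$time_days), , drop = FALSE]
    if (nrow(di) < 2L || di$value[1] <= 0) next
    out[[lid]] <- size_series(lid, di$time_days, di$value, method)
  }
  out
}

#' Classify every lesion of a cohort with every assessment method
#'
#' Diameter-based series are classified with the unidimensional thresholds
#' (30% / 20%) and volume-based series with the sphere-extrapolated
#' volumetric thresholds (65.7% / 72.8%).
#'
#' @param measurements Data.frame from [measure_cohort].
#' @param methods Measurement methods to assess.
#' @return Named list: `assessments[[method]]` is a named list of
#'   [response_sequence]s.
#' @export
assess_cohort <- function(measurements, methods = SIZE_METHODS) {
  out <- list()
  for (m in intersect(methods, unique(measurements$method))) {
    th <- if (startsWith(m, "vol")) rano_thresholds_volume() else
      rano_thresholds()
    out[[m]] <- lapply(cohort_series(measurements, m), classify_rano,
                       thresholds = th)
  }
  out
}

#' Rotation-stability analysis of a cohort
#'
#' For every lesion that is not in complete response at its last follow-up
#' (an empty mask cannot be rotated) and both contour sources, rotates the
#' last-time-point contour through the angle set, and computes the CoV of
#' the diameter and of the cube-root volume across rotations plus whether
#' any rotation changes the final RANO category (baseline and nadir kept
#' unrotated).
#'
#' @param cohort A rendered `bm_cohort`.
#' @param spec A [rotation_spec].
#' @param measurements Optional precomputed [measure_cohort] output.
#' @return Data.frame: lesion_id, source, cov_diam, cov_vol, change_diam,
#'   change_vol.
#' @export
rotation_stability <- function(cohort, spec = rotation_spec(),
                               measurements = NULL) {
  stopifnot(inherits(cohort, "bm_cohort"))
  if (is.null(measurements)) measurements <- measure_cohort(cohort)
  rows <- list()
  for (les in cohort$lesions) {
    nt <- length(les$times)
    if (nt < 2L || les$true_volumes[nt] == 0) next
    ob <- les$observations[[nt]]
    if (is.null(ob$masks)) next
    for (src in c("manual", "automatic")) {
      mask <- ob$masks[[src]]
      if (sum(mask$occupancy) == 0L) next
      if (longest_axial_diameter(mask) == 0) next  # sub-measurable lesion
      sz <- rotated_sizes(mask, spec)
      dm <- method_for("diam", src); vm <- method_for("vol", src)
      dser <- measurements[measurements$lesion_id == les$lesion_id &
                             measurements$method == dm, , drop = FALSE]
      vser <- measurements[measurements$lesion_id == les$lesion_id &
                             measurements$method == vm, , drop = FALSE]
      dser <- dser[order(dser$time_days), ]
      vser <- vser[order(vser$time_days), ]
      if (nrow(dser) < 2L || dser$value[1] <= 0) next
      change <- function(vals, times, base_values, th) {
        i0 <- which(sz$angles == 0)[1]
        v <- base_values
        n <- length(v)
        ref <- NULL
        changed <- FALSE
        for (x in c(vals[i0], vals)) {
          v[n] <- x
          s <- size_series(les$lesion_id, times, v, "tmp")
          cc <- classify_rano(s, th)$categories
          fin <- as.character(cc[length(cc)])
          if (is.null(ref)) ref <- fin
          else if (fin != ref) { changed <- TRUE; break }
        }
        changed
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_id = les$lesion_id, source = src,
        cov_diam = coef_variation(sz$diameter),
        cov_vol = coef_variation(cube_root_size(sz$volume)),
        change_diam = change(sz$diameter, dser$time_days, dser$value,
                             rano_thresholds()),
        change_vol = change(sz$volume, vser$time_days, vser$value,
                            rano_thresholds_volume()),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    stop_ranobm("no rotatable lesion in cohort", "ranobm_invalid_value")
  }
  do.call(rbind, rows)
}

#' Temporal-stability analysis of a cohort
#'
#' Restricted to lesions with at least 3 annotated time points. Computes
#' per lesion and measurement method the absolute Spearman correlation
#' between time and size, and per assessment method the consecutive
#' response-change counts.
#'
#' @param cohort A `bm_cohort`.
#' @param measurements Optional precomputed [measure_cohort] output.
#' @param methods Measurement methods to include.
#' @return List with `monotonicity` (data.frame lesion_id, method,
#'   abs_spearman) and `changes` (data.frame lesion_id, method, changes,
#'   pairs).
#' @export
temporal_stability <- function(cohort, measurements = NULL,
                               methods = c("vol-manseg", "vol-autoseg",
                                           "diam-manseg", "diam-autoseg")) {
  stopifnot(inherits(cohort, "bm_cohort"))
  if (is.null(measurements)) measurements <- measure_cohort(cohort)
  mono <- list(); chg <- list()
  assessments <- assess_cohort(measurements, methods)
  for (m in intersect(methods, unique(measurements$method))) {
    for (s in cohort_series(measurements, m)) {
      if (length(s$values) >= 3L) {
        rho <- suppressWarnings(temporal_monotonicity(s))
        mono[[length(mono) + 1L]] <- data.frame(
          lesion_id = s$lesion_id, method = m, abs_spearman = rho,
          stringsAsFactors = FALSE)
      }
    }
    for (rs in assessments[[m]]) {
      if (length(rs$categories) >= 2L) {
        cc <- consecutive_change_count(rs)
        chg[[length(chg) + 1L]] <- data.frame(
          lesion_id = rs$lesion_id, method = m,
          changes = cc[["changes"]], pairs = cc[["pairs"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  list(monotonicity = do.call(rbind, mono), changes = do.call(rbind, chg))
}
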