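# Staged analysis pipeline.
#
# CSV is the inter-stage contract (inspectable and diffable); NIfTI appears
# only at the geometry boundary. Every stage writes its outputs atomically
# and appends to a manifest carrying the seed and a config hash, so a rerun
# with the same configuration and seed is byte-identical (modulo the
# manifest timestamp).

PIPELINE_STAGES <- c("simulate", "measure", "assess", "stability",
                     "agreement", "outcome")

# Polynomial rolling hash over the JSON serialization; cheap content hash
# for the manifest.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_atomic_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  path
}

write_atomic_json <- function(x, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  path
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop_ranobm(sprintf(
      "stage '%s' needs missing upstream artifact '%s'; run earlier stages",
      stage, path), "ranobm_missing_artifact")
  }
  path
}

#' Run one stage (or all stages) of the analysis pipeline
#'
#' Stages, in order: `simulate` (generate the synthetic cohort, write the
#' cohort table and one NIfTI mask per lesion/time/contour source),
#' `measure` (size measurements CSV), `assess` (RANO response CSV),
#' `stability` (rotation + temporal stability CSVs and summary JSON),
#' `agreement` (pairwise method agreement JSON and correlation CSV),
#' `outcome` (1-year outcome CSV and summary JSON). `all` runs everything.
#'
#' @param stage One of `"all"`, `"simulate"`, `"measure"`, `"assess"`,
#'   `"stability"`, `"agreement"`, `"outcome"`.
#' @param config A [cohort_config] (its `seed` drives all randomness).
#' @param outdir Output directory (created if needed).
#' @param rotation A [rotation_spec] for the stability stage.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(stage = "all", config = cohort_config(),
                         outdir, rotation = rotation_spec()) {
  stage <- match.arg(stage, c("all", PIPELINE_STAGES))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") PIPELINE_STAGES else stage
  manifest_path <- file.path(outdir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list(seed = config$seed, config_hash = config_hash(config),
         stages = list())
  }
  for (s in stages) {
    out <- switch(s,
      simulate = stage_simulate(config, outdir),
      measure = stage_measure(config, outdir),
      assess = stage_assess(outdir),
      stability = stage_stability(config, outdir, rotation),
      agreement = stage_agreement(outdir),
      outcome = stage_outcome(outdir)
    )
    manifest$stages[[s]] <- out
  }
  manifest$written <- format(Sys.time(), tz = "UTC")
  write_atomic_json(manifest, manifest_path)
  invisible(manifest)
}

stage_simulate <- function(config, outdir) {
  cohort <- generate_cohort(config)
  maskdir <- file.path(outdir, "masks")
  dir.create(maskdir, showWarnings = FALSE)
  tab <- cohort$table
  if (config$render && nrow(tab) > 0) {
    for (les in cohort$lesions) {
      for (t in seq_along(les$times)) {
        for (src in c("manual", "automatic")) {
          fn <- sprintf("%s_t%03d_%s.nii.gz", les$lesion_id,
                        as.integer(les$times[t]), src)
          write_mask(les$observations[[t]]$masks[[src]],
                     file.path(maskdir, fn))
          sel <- tab$lesion_id == les$lesion_id &
            tab$time_days == les$times[t] & tab$contour_source == src
          tab$mask_path[sel] <- file.path("masks", fn)
        }
      }
    }
  }
  cohort_csv <- write_atomic_csv(tab, file.path(outdir, "cohort.csv"))
  cfg_json <- write_atomic_json(unclass(config),
                                file.path(outdir, "config.json"))
  list(inputs = character(0),
       outputs = c("cohort.csv", "config.json", "masks/"),
       n_lesions = length(cohort$lesions))
}

# Rebuild an in-memory cohort from the simulate artifacts.
load_cohort <- function(outdir, stage = "measure") {
  cohort_csv <- require_artifact(file.path(outdir, "cohort.csv"), stage)
  tab <- utils::read.csv(cohort_csv, stringsAsFactors = FALSE)
  cfg_path <- file.path(outdir, "config.json")
  config <- if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cfg
  } else {
    NULL
  }
  lesions <- list()
  for (lid in unique(tab$lesion_id)) {
    d <- tab[tab$lesion_id == lid, , drop = FALSE]
    times <- sort(unique(d$time_days))
    obs <- vector("list", length(times))
    vols <- numeric(length(times))
    labels <- rep(NA_character_, length(times))
    for (t in seq_along(times)) {
      dt <- d[d$time_days == times[t], , drop = FALSE]
      masks <- list()
      for (src in c("manual", "automatic")) {
        mp <- dt$mask_path[dt$contour_source == src]
        if (length(mp) == 1L && !is.na(mp)) {
          masks[[src]] <- read_mask(file.path(outdir, mp))
        }
      }
      if (length(masks) == 0L) masks <- NULL
      vols[t] <- if (!is.null(masks)) volume_mm3(masks$manual) else NA_real_
      md <- dt$manual_diameter_mm[1]
      obs[[t]] <- list(time_days = times[t], true_volume = vols[t],
                       masks = masks, manual_diameter = md)
      labels[t] <- dt$radiologist_label[1]
    }
    lesions[[length(lesions) + 1L]] <- structure(
      list(patient_id = d$patient_id[1], lesion_id = lid, kind = NA,
           times = times, true_volumes = vols,
           radionecrosis = isTRUE(d$excluded_radionecrosis[1]),
           has_manual_diam = any(!is.na(d$manual_diameter_mm)),
           labels = labels, observations = obs),
      class = "lesion_trajectory")
  }
  structure(list(lesions = lesions, table = tab,
                 config = config),
            class = "bm_cohort")
}

stage_measure <- function(config, outdir) {
  cohort <- load_cohort(outdir, "measure")
  meas <- measure_cohort(cohort)
  write_atomic_csv(meas, file.path(outdir, "measurements.csv"))
  list(inputs = "cohort.csv", outputs = "measurements.csv",
       n_rows = nrow(meas))
}

read_measurements <- function(outdir, stage) {
  p <- require_artifact(file.path(outdir, "measurements.csv"), stage)
  m <- utils::read.csv(p, stringsAsFactors = FALSE)
  need <- c("lesion_id", "time_days", "method", "value")
  miss <- setdiff(need, names(m))
  if (length(miss)) {
    stop_ranobm(sprintf("measurements.csv lacks columns: %s",
                        paste(miss, collapse = ", ")),
                "ranobm_invalid_artifact")
  }
  bad <- which(!is.finite(m$value) | m$value < 0)
  if (length(bad)) {
    stop_ranobm(sprintf("measurements.csv row %d: invalid size value",
                        bad[1] + 1L), "ranobm_invalid_artifact")
  }
  m
}

stage_assess <- function(outdir) {
  meas <- read_measurements(outdir, "assess")
  assessments <- assess_cohort(meas)
  rows <- list()
  for (m in names(assessments)) {
    for (rs in assessments[[m]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_id = rs$lesion_id, time_days = rs$times, method = m,
        category = as.character(rs$categories),
        reference_value = rs$reference_value,
        nadir_value = rs$nadir_value, stringsAsFactors = FALSE)
    }
  }
  resp <- do.call(rbind, rows)
  write_atomic_csv(resp, file.path(outdir, "responses.csv"))
  list(inputs = "measurements.csv", outputs = "responses.csv",
       n_rows = nrow(resp))
}

stage_stability <- function(config, outdir, rotation) {
  meas <- read_measurements(outdir, "stability")
  cohort <- load_cohort(outdir, "stability")
  rot <- rotation_stability(cohort, rotation, meas)
  tmp <- temporal_stability(cohort, meas)
  write_atomic_csv(rot, file.path(outdir, "stability_rotation.csv"))
  write_atomic_csv(tmp$monotonicity,
                   file.path(outdir, "stability_monotonicity.csv"))
  write_atomic_csv(tmp$changes, file.path(outdir, "stability_changes.csv"))
  summ <- list(
    cov = list(
      note = "CoV uses the sample (n-1) sd; volumes enter as cube roots",
      mean_cov_diam = mean(rot$cov_diam),
      mean_cov_vol = mean(rot$cov_vol),
      wilcoxon_p_diam_vs_vol =
        paired_difference_test(rot$cov_diam, rot$cov_vol)
    ),
    rotation_change = list(
      rate_diam = mean(rot$change_diam),
      rate_vol = mean(rot$change_vol),
      mcnemar_p = paired_rate_test(rot$change_diam, rot$change_vol)
    ),
    temporal = lapply(split(tmp$monotonicity, tmp$monotonicity$method),
                      function(d) mean(d$abs_spearman)),
    change_rates = lapply(split(tmp$changes, tmp$changes$method),
                          pooled_change_rate)
  )
  write_atomic_json(summ, file.path(outdir, "stability_summary.json"))
  list(inputs = c("cohort.csv", "measurements.csv"),
       outputs = c("stability_rotation.csv", "stability_monotonicity.csv",
                   "stability_changes.csv", "stability_summary.json"))
}

stage_agreement <- function(outdir) {
  meas <- read_measurements(outdir, "agreement")
  resp_p <- require_artifact(file.path(outdir, "responses.csv"), "agreement")
  resp <- utils::read.csv(resp_p, stringsAsFactors = FALSE)
  methods <- unique(resp$method)
  pairs <- list()
  for (i in seq_along(methods)) {
    for (j in seq_along(methods)) {
      if (i >= j) next
      a <- resp[resp$method == methods[i], ]
      b <- resp[resp$method == methods[j], ]
      m <- merge(a, b, by = c("lesion_id", "time_days"))
      if (nrow(m) == 0L) next
      cm <- confusion_matrix(factor(m$category.x, RANO_LEVELS),
                             factor(m$category.y, RANO_LEVELS))
      pairs[[paste(methods[i], methods[j], sep = "|")]] <- list(
        n = attr(cm, "n"),
        counts = as.integer(cm),
        percent_agreement = percent_agreement(cm),
        kappa = cohen_kappa(cm),
        pabak = pabak(cm))
    }
  }
  # correlation matrix of size measurements over complete cases
  wide <- stats::reshape(meas, idvar = c("lesion_id", "time_days"),
                         timevar = "method", direction = "wide")
  vals <- wide[, grep("^value\\.", names(wide)), drop = FALSE]
  names(vals) <- sub("^value\\.", "", names(vals))
  cc <- stats::cor(as.matrix(vals), use = "pairwise.complete.obs")
  corr_df <- data.frame(method = rownames(cc), cc, check.names = FALSE)
  write_atomic_csv(corr_df, file.path(outdir, "correlations.csv"))
  write_atomic_json(list(note = "raw two-sided p-values, no multiplicity correction",
                         pairs = pairs),
                    file.path(outdir, "agreement.json"))
  list(inputs = c("measurements.csv", "responses.csv"),
       outputs = c("agreement.json", "correlations.csv"))
}

stage_outcome <- function(outdir) {
  resp_p <- require_artifact(file.path(outdir, "responses.csv"), "outcome")
  resp <- utils::read.csv(resp_p, stringsAsFactors = FALSE)
  seqs <- list()
  for (m in unique(resp$method)) {
    d <- resp[resp$method == m, ]
    seqs[[m]] <- lapply(split(d, d$lesion_id), function(di) {
      di <- di[order(di$time_days), ]
      response_sequence(di$lesion_id[1], di$time_days, di$category,
                        method = m)
    })
  }
  out <- tryCatch(cohort_outcome_summary(seqs),
                  ranobm_invalid_value = function(e) NULL)
  if (is.null(out)) {
    write_atomic_json(list(note = "no lesion with follow-up beyond 1 year"),
                      file.path(outdir, "outcome_summary.json"))
    return(list(inputs = "responses.csv",
                outputs = "outcome_summary.json", n_eligible = 0))
  }
  write_atomic_csv(out$records, file.path(outdir, "outcome.csv"))
  write_atomic_json(list(summary = out$summary,
                         pairwise_p = as.data.frame(out$pairwise_p)),
                    file.path(outdir, "outcome_summary.json"))
  list(inputs = "responses.csv",
       outputs = c("outcome.csv", "outcome_summary.json"),
       n_eligible = length(unique(out$records$lesion_id)))
}
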