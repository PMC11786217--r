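# Inter-method agreement statistics.
#
# Continuous agreement: Pearson correlation and Lin's concordance
# correlation coefficient (CCC) between size-measurement methods, and the
# Pearson-Filon test for comparing two dependent non-overlapping
# correlations (e.g. diameter-vs-cube-root-volume correlation under manual
# vs automatic contours, measured on the same lesions).
# Categorical agreement: confusion matrices over the RANO categories with
# percent agreement, Cohen's kappa, and the prevalence- and bias-adjusted
# kappa (PABAK).

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of common length >= 3 with non-zero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_ranobm("need aligned vectors of length >= 3", "ranobm_invalid_value")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ranobm("correlation undefined for zero-variance input",
                "ranobm_invalid_value")
  }
  stats::cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' `2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, Lin's original definition. Unlike Pearson's
#' r, the CCC penalizes location and scale shift: it measures agreement
#' with the identity line, not just linear association.
#'
#' @param x,y Numeric vectors of common length >= 3.
#' @param sample_moments Use n-1 moments instead (default `FALSE`).
#' @return CCC in `[-1, 1]`.
#' @export
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 4, 6))  # 8/22: perfectly correlated, poor agreement
lin_ccc <- function(x, y, sample_moments = FALSE) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_ranobm("need aligned vectors of length >= 3", "ranobm_invalid_value")
  }
  n <- length(x)
  f <- if (sample_moments) 1 else (n - 1) / n
  vx <- stats::var(x) * f
  vy <- stats::var(y) * f
  cxy <- stats::cov(x, y) * f
  denom <- vx + vy + (mean(x) - mean(y))^2
  if (denom == 0) {
    stop_ranobm("CCC undefined: both variances zero and equal means",
                "ranobm_invalid_value")
  }
  2 * cxy / denom
}

#' Confusion matrix between two aligned response-sequence sets
#'
#' Cross-tabulates the assessments of two methods over the intersection of
#' their (lesion, time) keys, mirroring paired-subset handling: only
#' follow-ups assessed by both methods enter.
#'
#' @param seq_a,seq_b Lists of [response_sequence]s (one per lesion), or a
#'   pair of aligned factors.
#' @param levels Category levels of the table (default PD, SD, PR, CR).
#' @return A `confusion_matrix`: square table with attributes `n`.
#' @export
confusion_matrix <- function(seq_a, seq_b, levels = RANO_LEVELS) {
  if (is.list(seq_a) && !is.data.frame(seq_a)) {
    key <- function(seqs) {
      do.call(rbind, lapply(seqs, function(s) {
        data.frame(lesion_id = s$lesion_id, time = s$times,
                   cat = as.character(s$categories),
                   stringsAsFactors = FALSE)
      }))
    }
    a <- key(seq_a); b <- key(seq_b)
    m <- merge(a, b, by = c("lesion_id", "time"))
    if (nrow(m) == 0L) {
      stop_ranobm("no (lesion, time) keys shared by the two methods",
                  "ranobm_invalid_value")
    }
    fa <- factor(m$cat.x, levels = levels)
    fb <- factor(m$cat.y, levels = levels)
  } else {
    fa <- factor(seq_a, levels = levels)
    fb <- factor(seq_b, levels = levels)
    if (length(fa) == 0L) {
      stop_ranobm("empty assessments", "ranobm_invalid_value")
    }
  }
  tab <- table(fa, fb, dnn = c("method_a", "method_b"))
  structure(unclass(tab), class = c("confusion_matrix", "matrix"),
            n = sum(tab))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
    stop_ranobm("confusion matrix must be square", "ranobm_invalid_value")
  }
  n <- sum(cm)
  if (n == 0) stop_ranobm("empty confusion matrix", "ranobm_invalid_value")
  n
}

#' Percent agreement of a confusion matrix
#' @param cm Square count matrix.
#' @return Fraction `trace/n`.
#' @export
percent_agreement <- function(cm) {
  n <- check_cm(cm)
  sum(diag(as.matrix(cm))) / n
}

#' Cohen's kappa
#'
#' `(p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' marginal products.
#'
#' @param cm Square count matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  n <- check_cm(cm)
  cm <- as.matrix(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) {
    stop_ranobm("kappa undefined: expected agreement is 1",
                "ranobm_invalid_value")
  }
  (po - pe) / (1 - pe)
}

#' Prevalence- and bias-adjusted kappa (PABAK)
#'
#' `(k p_o - 1) / (k - 1)` for `k` categories: the kappa obtained when
#' marginals are forced uniform, removing prevalence and rater-bias
#' effects. Equals Cohen's kappa when the observed marginals are uniform.
#'
#' @param cm Square count matrix with k >= 2 categories.
#' @return PABAK in `[-1, 1]`.
#' @export
pabak <- function(cm) {
  n <- check_cm(cm)
  cm <- as.matrix(cm)
  k <- nrow(cm)
  if (k < 2L) stop_ranobm("need >= 2 categories", "ranobm_invalid_value")
  po <- sum(diag(cm)) / n
  (k * po - 1) / (k - 1)
}

#' Pearson-Filon test for two dependent non-overlapping correlations
#'
#' Tests `H0: rho(x1, x2) = rho(x3, x4)` where all four variables are
#' measured on the same n subjects and the two correlations share no
#' variable. The statistic is
#' `z = sqrt(n) (r12 - r34) / sqrt((1 - r12^2)^2 + (1 - r34^2)^2 - 2k)`
#' with the classical Pearson-Filon asymptotic covariance term
#' `k = 1/2 r12 r34 (r13^2 + r14^2 + r23^2 + r24^2) + r13 r24 + r14 r23
#'  - (r12 r13 r14 + r12 r23 r24 + r13 r23 r34 + r14 r24 r34)`
#' assembled from the six pairwise correlations; p is two-sided from the
#' standard normal.
#'
#' @param x1,x2,x3,x4 Aligned numeric vectors of common length n >= 10;
#'   the compared correlations are r12 = cor(x1, x2) and r34 = cor(x3, x4).
#' @return List with `z`, `p_value`, `r12`, `r34`, `n`.
#' @export
pearson_filon_test <- function(x1, x2, x3, x4) {
  n <- length(x1)
  if (length(x2) != n || length(x3) != n || length(x4) != n) {
    stop_ranobm("all four vectors must be aligned", "ranobm_invalid_value")
  }
  if (n < 10L) {
    stop_ranobm("Pearson-Filon test needs n >= 10", "ranobm_invalid_value")
  }
  r12 <- stats::cor(x1, x2); r34 <- stats::cor(x3, x4)
  r13 <- stats::cor(x1, x3); r14 <- stats::cor(x1, x4)
  r23 <- stats::cor(x2, x3); r24 <- stats::cor(x2, x4)
  rs <- c(r12, r34, r13, r14, r23, r24)
  if (any(!is.finite(rs)) || abs(r12) >= 1 || abs(r34) >= 1) {
    stop_ranobm("degenerate correlations (|r| = 1 or undefined)",
                "ranobm_invalid_value")
  }
  k <- 0.5 * r12 * r34 * (r13^2 + r14^2 + r23^2 + r24^2) +
    r13 * r24 + r14 * r23 -
    (r12 * r13 * r14 + r12 * r23 * r24 + r13 * r23 * r34 + r14 * r24 * r34)
  denom <- (1 - r12^2)^2 + (1 - r34^2)^2 - 2 * k
  z <- if (r12 == r34) 0 else sqrt(n) * (r12 - r34) / sqrt(denom)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), r12 = r12, r34 = r34,
       n = n)
}

#' Agreement summary for a pair of assessment methods
#'
#' @param seq_a,seq_b As in [confusion_matrix].
#' @param levels Category levels.
#' @return List with the confusion matrix, `percent_agreement`, `kappa`,
#'   and `pabak`.
#' @export
agreement_summary <- function(seq_a, seq_b, levels = RANO_LEVELS) {
  cm <- confusion_matrix(seq_a, seq_b, levels)
  list(confusion = cm,
       n = attr(cm, "n"),
       percent_agreement = percent_agreement(cm),
       kappa = cohen_kappa(cm),
       pabak = pabak(cm))
}
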