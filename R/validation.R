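# Step 3 — validation against a clinically severe pain cohort.
#
# Candidate probesets are checked for a stepwise change in expression across
# three groups: Low Pain visits and non-severe High Pain visits from the
# discovery cohort, and the independent Clinically Severe Pain cohort.
# Expression (linear intensities for DE, numerically encoded detection calls
# for AP) is z-scored within gender-by-diagnosis strata before testing, with
# zero-variance strata excluded rather than zero-filled. Stepwise-changed
# probesets are tested by one-way ANOVA with an attempted Bonferroni
# correction, mapping onto 0/2/4/6 validation points.

#' De-log a log2 expression value
#'
#' `2^x`; the inverse of the log2 transform, used to return RMA-style log
#' expression to the linear scale before stratified z-scoring.
#'
#' @param log2_value Numeric vector.
#' @return `2 ^ log2_value`.
#' @export
delog <- function(log2_value) 2^log2_value

#' Z-score values within gender-by-diagnosis strata
#'
#' Within each stratum, `(x - mean) / sd` with the sample standard deviation
#' (n - 1 denominator). A stratum whose values have zero variance — where the
#' z-score would be 0/0 — is excluded: its entries become `NA`, never zeros.
#' Strata of size 1 are likewise excluded, with a warning.
#'
#' @param x Numeric vector, one value per sample.
#' @param stratum Factor (or character) of stratum labels, same length.
#' @return Numeric vector of z values with `NA` for excluded strata.
#' @export
zscore_by_stratum <- function(x, stratum) {
  if (length(x) != length(stratum)) abort("x and stratum lengths differ")
  z <- rep(NA_real_, length(x))
  for (idx in split(seq_along(x), as.character(stratum))) {
    if (length(idx) < 2) {
      warning("stratum of size 1 excluded from z-scoring", call. = FALSE)
      next
    }
    s <- stats::sd(x[idx])
    if (!is.finite(s) || s == 0) next
    z[idx] <- (x[idx] - mean(x[idx])) / s
  }
  z
}

# Row-wise stratified z-scoring of a probesets x samples matrix. Each row is
# z-scored within each stratum independently; rows with zero variance in a
# stratum get NA there (the exclusion rule), as do strata of size < 2.
zscore_matrix_by_stratum <- function(mat, stratum) {
  z <- matrix(NA_real_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (idx in split(seq_len(ncol(mat)), as.character(stratum))) {
    if (length(idx) < 2) next
    sub <- mat[, idx, drop = FALSE]
    m <- rowMeans(sub)
    s <- sqrt(rowSums((sub - m)^2) / (length(idx) - 1))
    keep <- is.finite(s) & s > 0
    z[keep, idx] <- (sub[keep, , drop = FALSE] - m[keep]) / s[keep]
  }
  z
}

#' Clinically severe pain criterion
#'
#' A visit is clinically severe when pain VAS is 6 or above AND the sum of
#' SF-36 items 21 (pain intensity) and 22 (interference of pain with daily
#' activities) is 10 or above. Visits with missing SF-36 items are treated as
#' not severe.
#'
#' @param visits Visit table with pain_vas, sf36_21, sf36_22.
#' @return Logical vector.
#' @export
clinically_severe <- function(visits) {
  s <- visits$sf36_21 + visits$sf36_22
  out <- visits$pain_vas >= 6 & !is.na(s) & s >= 10
  out[is.na(out)] <- FALSE
  out
}

#' Stepwise-change test with one-way ANOVA
#'
#' Tests whether stratified z-scored expression progresses monotonically
#' (strict ordering of group means) from Low Pain to High Pain to Clinically
#' Severe in the probeset's discovery direction, and how significant the
#' three-group difference is by one-way ANOVA. Points: 6 when stepwise and
#' Bonferroni-significant (`p < alpha / n_tests`), 4 when stepwise and
#' nominally significant (`p < alpha`), 2 when stepwise only, 0 otherwise.
#'
#' @param z Numeric z-scored values (NAs from excluded strata are dropped).
#' @param group Factor/character of "Low"/"High"/"Severe" per value.
#' @param direction Discovery direction "I" (expect Low < High < Severe) or
#'   "D" (expect Low > High > Severe).
#' @param n_tests Bonferroni denominator: the number of probesets entering
#'   validation.
#' @param alpha Significance level (default 0.05).
#' @return One-row data.frame: mean_low, mean_high, mean_severe, stepwise,
#'   anova_p, bonferroni_sig, points, untestable.
#' @export
stepwise_anova <- function(z, group, direction, n_tests = 1, alpha = 0.05) {
  keep <- is.finite(z)
  z <- z[keep]
  group <- factor(as.character(group)[keep], levels = c("Low", "High", "Severe"))
  untestable <- any(table(group) == 0) || is.na(direction)
  if (untestable) {
    return(data.frame(mean_low = NA_real_, mean_high = NA_real_,
                      mean_severe = NA_real_, stepwise = FALSE,
                      anova_p = NA_real_, bonferroni_sig = FALSE,
                      points = 0L, untestable = TRUE))
  }
  m <- tapply(z, group, mean)
  stepwise <- if (direction == "I") {
    m[["Low"]] < m[["High"]] && m[["High"]] < m[["Severe"]]
  } else {
    m[["Low"]] > m[["High"]] && m[["High"]] > m[["Severe"]]
  }
  p <- stats::anova(stats::aov(z ~ group))[["Pr(>F)"]][1]
  bonf <- is.finite(p) && p < alpha / n_tests
  points <- if (stepwise && bonf) 6L else if (stepwise && p < alpha) 4L else
    if (stepwise) 2L else 0L
  data.frame(mean_low = unname(m[["Low"]]), mean_high = unname(m[["High"]]),
             mean_severe = unname(m[["Severe"]]), stepwise = stepwise,
             anova_p = p, bonferroni_sig = bonf, points = points,
             untestable = FALSE)
}

#' Validate carried-forward candidates against the severe-pain cohort
#'
#' Assembles the three validation groups — Low Pain visits and non-severe
#' High Pain visits from the discovery cohort, plus all visits of the
#' clinically severe validation cohort — z-scores each candidate probeset
#' within gender-by-diagnosis strata (linear intensities for DE, 0/0.5/1
#' encoded calls for AP), and runs the stepwise ANOVA test for every
#' candidate in its discovery direction. The Bonferroni denominator is the
#' number of candidates tested.
#'
#' @param candidates data.frame with probeset_id, direction, and optionally
#'   method ("DE"/"AP", default DE) columns.
#' @param disc_bundle,disc_visits Discovery cohort expression and visits.
#' @param val_bundle,val_visits Validation (severe) cohort expression and
#'   visits.
#' @param alpha Significance level (default 0.05).
#' @return data.frame, one row per candidate: probeset_id, direction, method,
#'   group means, stepwise, anova_p, bonferroni_sig, points, untestable.
#' @export
validation_table <- function(candidates, disc_bundle, disc_visits,
                             val_bundle, val_visits, alpha = 0.05) {
  if (!all(c("probeset_id", "direction") %in% names(candidates))) {
    abort("candidates needs probeset_id and direction columns")
  }
  method <- if ("method" %in% names(candidates)) candidates$method else
    rep("DE", nrow(candidates))

  d_state <- label_pain_state(disc_visits$pain_vas)
  d_sev <- clinically_severe(disc_visits)
  lo <- d_state == "Low"
  hi <- d_state == "High" & !d_sev
  group <- c(rep("Low", sum(lo)), rep("High", sum(hi)),
             rep("Severe", nrow(val_visits)))
  pheno <- rbind(disc_visits[lo, c("sample_id", "gender", "diagnosis")],
                 disc_visits[hi, c("sample_id", "gender", "diagnosis")],
                 val_visits[, c("sample_id", "gender", "diagnosis")])
  stratum <- paste(pheno$gender, pheno$diagnosis, sep = ".")

  pull <- function(bundle, ids, mode) {
    i <- match(ids, bundle$probeset_ids)
    if (anyNA(i)) abort("candidate probeset(s) missing from bundle")
    if (mode == "AP") encode_ap(bundle$calls[i, , drop = FALSE]) else
      bundle$intensity[i, , drop = FALSE]
  }

  n_tests <- nrow(candidates)
  out <- vector("list", n_tests)
  for (mode in unique(method)) {
    sel <- which(method == mode)
    ids <- candidates$probeset_id[sel]
    vals <- cbind(pull(disc_bundle, ids, mode)[, disc_visits$sample_id[lo], drop = FALSE],
                  pull(disc_bundle, ids, mode)[, disc_visits$sample_id[hi], drop = FALSE],
                  pull(val_bundle, ids, mode)[, val_visits$sample_id, drop = FALSE])
    z <- zscore_matrix_by_stratum(vals, stratum)
    for (k in seq_along(sel)) {
      res <- stepwise_anova(z[k, ], group, candidates$direction[sel[k]],
                            n_tests = n_tests, alpha = alpha)
      out[[sel[k]]] <- cbind(
        data.frame(probeset_id = ids[k], direction = candidates$direction[sel[k]],
                   method = mode, stringsAsFactors = FALSE),
        res)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
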