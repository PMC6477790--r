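# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles are deliberately naive loop implementations, sharing no
# code with the package paths they check.

# AUC by exhaustive case-control pair counting: wins count 1, ties 0.5.
brute_force_auc <- function(scores, cases) {
  cs <- scores[cases]
  ct <- scores[!cases]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Discovery concordance scoring of one probeset by an explicit loop over
# comparisons.
oracle_discovery <- function(low_vals, high_vals, method, fold = 1.2) {
  inc <- dec <- 0
  for (i in seq_along(low_vals)) {
    if (method == "DE") {
      r <- high_vals[i] / low_vals[i]
      if (!is.nan(r) && r >= fold) inc <- inc + 1
      else if (!is.nan(r) && r <= 1 / fold) dec <- dec + 1
    } else {
      if (low_vals[i] == "A" && high_vals[i] == "P") inc <- inc + 1
      if (low_vals[i] == "P" && high_vals[i] == "A") dec <- dec + 1
    }
  }
  n <- length(low_vals)
  fi <- inc / n
  fd <- dec / n
  if (fi == fd) {
    return(list(direction = NA_character_, fraction = fi, points = 0L))
  }
  f <- max(fi, fd)
  pts <- if (f >= 0.8) 6L else if (f >= 0.5) 4L else if (f >= 0.33) 2L else 0L
  list(direction = if (fi > fd) "I" else "D", fraction = f, points = pts)
}

# One-way ANOVA p by permutation of group labels (F-statistic null).
permutation_anova_p <- function(z, group, n_perm = 2000) {
  fstat <- function(g) {
    m <- tapply(z, g, mean)
    n <- tapply(z, g, length)
    gm <- mean(z)
    msb <- sum(n * (m - gm)^2) / (length(m) - 1)
    msw <- sum((z - m[g])^2) / (length(z) - length(m))
    msb / msw
  }
  f0 <- fstat(group)
  hits <- 0
  for (i in seq_len(n_perm)) {
    if (fstat(sample(group)) >= f0) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# A paired-visit cohort: every subject has one Low Pain (VAS 1) and one High
# Pain (VAS 8) visit, so each subject contributes exactly one comparison.
# Matrices are probesets x subjects.
paired_cohort <- function(low_int, high_int, low_calls = NULL, high_calls = NULL) {
  low_int <- as.matrix(low_int)
  high_int <- as.matrix(high_int)
  n <- ncol(low_int)
  p <- nrow(low_int)
  visits <- data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(n)), each = 2),
    visit_id = rep(c("V1", "V2"), n),
    day = rep(c(0, 100), n),
    gender = "M", diagnosis = "MDD",
    pain_vas = rep(c(1L, 8L), n),
    sf36_21 = rep(c(1L, 4L), n), sf36_22 = rep(c(1L, 4L), n),
    stringsAsFactors = FALSE)
  visits$sample_id <- paste(visits$subject_id, visits$visit_id, sep = "_")
  inten <- matrix(8, p, 2 * n)
  calls <- matrix("M", p, 2 * n)
  inten[, seq(1, 2 * n, 2)] <- low_int
  inten[, seq(2, 2 * n, 2)] <- high_int
  if (!is.null(low_calls)) {
    calls[, seq(1, 2 * n, 2)] <- as.matrix(low_calls)
    calls[, seq(2, 2 * n, 2)] <- as.matrix(high_calls)
  }
  bundle <- expression_bundle(inten, calls, sprintf("P%03d", seq_len(p)),
                              visits$sample_id)
  list(visits = visits, bundle = bundle)
}

# Prediction-result rows with given stratum levels / significance, shaped
# like stratified_run() output rows.
prediction_rows <- function(stratum_level, significant,
                            outcome = "state", mode = "cross_sectional") {
  data.frame(marker = "m", outcome = outcome, stratum_level = stratum_level,
             stratum = stratum_level, mode = mode,
             significant = significant, stringsAsFactors = FALSE)
}
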