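# Step 4 — prediction of state and trait in an independent test cohort.
#
# Markers are z-scored by gender and diagnosis, oriented so that higher
# always means higher risk (increased-risk markers keep their sign, decreased
# ones are negated), and evaluated cross-sectionally (one visit's level) and
# longitudinally (levels and slopes over the subject's visit history) against
# three outcomes: High Pain state at the visit, ED visits for pain within the
# first year of follow-up, and ED visits for pain over all follow-up.
# Metrics: Mann-Whitney ROC AUC with one-sided p, one-tailed Welch t-test,
# one-tailed Pearson correlation, Cox proportional-hazards ratios, and
# logistic odds ratios per z unit. Everything is repeated in all subjects and
# within gender and gender-by-diagnosis strata.

#' Risk-oriented composite score
#'
#' Simple summation of increased-risk markers minus decreased-risk markers:
#' `sum(z[I]) - sum(z[D])` per sample. For a single marker this is `z` when
#' increased and `-z` when decreased, which orients every downstream hazard
#' and odds ratio so that values above 1 mean increased risk. Samples missing
#' any member's value get `NA` (dropped from panel analyses).
#'
#' @param z Numeric matrix, markers x samples (a vector is treated as one
#'   marker).
#' @param directions "I"/"D" per marker.
#' @return Numeric vector, one composite score per sample.
#' @export
risk_oriented_score <- function(z, directions) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (nrow(z) != length(directions)) abort("one direction per marker required")
  if (!all(directions %in% c("I", "D"))) abort("directions must be 'I' or 'D'")
  sign_dir <- ifelse(directions == "I", 1, -1)
  colSums(z * sign_dir)
}

#' Longitudinal features of a marker series
#'
#' The four longitudinal features of a subject's z-scored marker series:
#' level at the most recent visit, maximum level, slope into the most recent
#' visit, and maximum slope between consecutive visits (slopes in z units per
#' day). Single-visit series get zero slopes.
#'
#' @param z Numeric vector of z-scored marker values, one per visit in day
#'   order.
#' @param days Strictly increasing numeric vector of visit days.
#' @return Named list: last_level, max_level, last_slope, max_slope.
#' @export
longitudinal_features <- function(z, days) {
  if (length(z) != length(days) || length(z) < 1) {
    abort("z and days must be non-empty and the same length")
  }
  if (length(days) > 1 && any(diff(days) <= 0)) {
    abort("visit days must be strictly increasing")
  }
  slopes <- if (length(z) > 1) diff(z) / diff(days) else numeric(0)
  list(last_level = z[length(z)],
       max_level = max(z),
       last_slope = if (length(slopes)) slopes[length(slopes)] else 0,
       max_slope = if (length(slopes)) max(slopes) else 0)
}

# Equal-weight composite of the four longitudinal features: each feature is
# z-scored across the cohort's longitudinal rows, then averaged.
longitudinal_composite <- function(features) {
  zs <- lapply(features[c("last_level", "max_level", "last_slope", "max_slope")],
               function(x) {
                 s <- stats::sd(x)
                 if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
               })
  rowMeans(do.call(cbind, zs))
}

#' Mann-Whitney ROC AUC with a one-sided p value
#'
#' The area under the ROC curve computed as the Mann-Whitney U statistic
#' scaled by `n_cases * n_controls`, with tied score pairs counted one half.
#' The one-sided p (alternative: scores are higher in cases) uses the normal
#' approximation to U with the tie correction and a continuity correction.
#'
#' @param scores Numeric scores.
#' @param cases Logical case labels, same length.
#' @return List: auc, p, n_cases, n_controls. With a single class present,
#'   auc and p are `NA` (untestable).
#' @export
roc_auc <- function(scores, cases) {
  keep <- is.finite(scores) & !is.na(cases)
  scores <- scores[keep]
  cases <- as.logical(cases[keep])
  n1 <- sum(cases)
  n0 <- sum(!cases)
  if (n1 == 0 || n0 == 0) {
    return(list(auc = NA_real_, p = NA_real_, n_cases = n1, n_controls = n0))
  }
  r <- rank(scores)
  u <- sum(r[cases]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  n <- n1 + n0
  ties <- table(scores)
  sigma2 <- n1 * n0 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (sigma2 <= 0) 1 else
    stats::pnorm((u - n1 * n0 / 2 - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  list(auc = auc, p = min(max(p, .Machine$double.xmin), 1),
       n_cases = n1, n_controls = n0)
}

one_sided_t <- function(scores, cases) {
  tryCatch(
    stats::t.test(scores[cases], scores[!cases], alternative = "greater",
                  var.equal = FALSE)$p.value,
    error = function(e) NA_real_)
}

one_sided_pearson <- function(scores, y) {
  tryCatch({
    # constant inputs have no defined correlation; report NA quietly
    ct <- suppressWarnings(
      stats::cor.test(scores, y, alternative = "greater", method = "pearson"))
    c(r = unname(ct$estimate), p = ct$p.value)
  }, error = function(e) c(r = NA_real_, p = NA_real_))
}

#' State prediction metrics for one marker and cohort
#'
#' ROC AUC with one-sided p against the High Pain label, a one-tailed Welch
#' t-test of High Pain visits versus the rest, and a one-tailed Pearson
#' correlation of scores with the VAS pain rating.
#'
#' @param scores Risk-oriented marker scores per visit.
#' @param cases Logical: High Pain visit (VAS >= 6).
#' @param pain_vas VAS ratings per visit.
#' @return One-row data.frame: auc, auc_p, t_p, r, r_p, n_cases, n_total.
#' @export
state_tests <- function(scores, cases, pain_vas) {
  roc <- roc_auc(scores, cases)
  pe <- one_sided_pearson(scores, pain_vas)
  data.frame(auc = roc$auc, auc_p = roc$p,
             t_p = one_sided_t(scores, cases),
             r = pe[["r"]], r_p = pe[["p"]],
             n_cases = roc$n_cases, n_total = roc$n_cases + roc$n_controls)
}

#' Cox proportional-hazards ratio per z unit of a marker score
#'
#' @param time Follow-up times in days.
#' @param event Logical event indicator.
#' @param scores Risk-oriented marker scores.
#' @return List: hr, log_hr, se, p (one-sided, alternative hazard increases
#'   with score).
#' @export
cox_hr <- function(time, event, scores) {
  fit <- tryCatch(
    suppressWarnings(survival::coxph(survival::Surv(time, event) ~ scores)),
    error = function(e) NULL)
  if (is.null(fit) || is.na(stats::coef(fit))) {
    return(list(hr = NA_real_, log_hr = NA_real_, se = NA_real_, p = NA_real_))
  }
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit)))[1])
  list(hr = exp(beta), log_hr = beta, se = se,
       p = stats::pnorm(beta / se, lower.tail = FALSE))
}

#' Logistic odds ratio per z unit of a marker score
#'
#' Odds ratio for a binary outcome from a logistic regression of the outcome
#' on the risk-oriented score, with a one-sided p (alternative: odds increase
#' with the score). Degenerate outcomes (all cases or none) are untestable.
#'
#' @param scores Risk-oriented marker scores.
#' @param cases Logical outcome.
#' @return List: or, log_or, se, p, n_cases, n_total.
#' @export
or_test <- function(scores, cases) {
  keep <- is.finite(scores) & !is.na(cases)
  scores <- scores[keep]
  cases <- as.logical(cases[keep])
  n1 <- sum(cases)
  n <- length(cases)
  if (n1 == 0 || n1 == n) {
    return(list(or = NA_real_, log_or = NA_real_, se = NA_real_, p = NA_real_,
                n_cases = n1, n_total = n))
  }
  fit <- suppressWarnings(stats::glm(cases ~ scores, family = stats::binomial()))
  beta <- stats::coef(fit)[["scores"]]
  se <- sqrt(diag(stats::vcov(fit)))[["scores"]]
  list(or = exp(beta), log_or = beta, se = se,
       p = stats::pnorm(beta / se, lower.tail = FALSE),
       n_cases = n1, n_total = n)
}

#' First-year trait prediction metrics
#'
#' Predicts an ED visit for pain within 365 days of the testing visit: ROC
#' AUC with one-sided p, one-tailed Welch t-test, one-tailed Pearson
#' correlation with ED-visit frequency (events per year of follow-up), and a
#' Cox regression on time to first ED visit censored at 365 days.
#'
#' @param scores Risk-oriented marker scores per visit.
#' @param days_to_first Days from the visit to the first subsequent ED pain
#'   visit (`Inf` when none occurred).
#' @param followup_days Possible follow-up after the visit, days (visits with
#'   fewer than 365 are excluded).
#' @param n_events Total ED pain visits over the subject's follow-up.
#' @return One-row data.frame: auc, auc_p, t_p, r, r_p, hr, hr_p, n_cases,
#'   n_total.
#' @export
trait_year1_tests <- function(scores, days_to_first, followup_days, n_events) {
  eligible <- followup_days >= 365
  scores <- scores[eligible]
  days_to_first <- days_to_first[eligible]
  followup_days <- followup_days[eligible]
  n_events <- n_events[eligible]
  cases <- days_to_first <= 365
  roc <- roc_auc(scores, cases)
  freq <- n_events / (followup_days / 365)
  pe <- one_sided_pearson(scores, freq)
  cox <- cox_hr(pmin(days_to_first, 365), cases, scores)
  data.frame(auc = roc$auc, auc_p = roc$p, t_p = one_sided_t(scores, cases),
             r = pe[["r"]], r_p = pe[["p"]], hr = cox$hr, hr_p = cox$p,
             n_cases = roc$n_cases, n_total = roc$n_cases + roc$n_controls)
}

#' All-years trait prediction metrics
#'
#' Predicts any future ED visit for pain over the full (variable-length)
#' follow-up: a logistic odds ratio per z unit with one-sided p — the
#' primary metric, since unlike ROC it accounts for follow-up length — and a
#' Cox regression on time to first ED visit censored at the last
#' medical-record note.
#'
#' @param scores Risk-oriented marker scores per visit.
#' @param days_to_first Days to first subsequent ED pain visit (`Inf` if
#'   none).
#' @param followup_days Days from the visit to the last medical-record note.
#' @return One-row data.frame: or, or_p, hr, hr_p, n_cases, n_total.
#' @export
trait_all_tests <- function(scores, days_to_first, followup_days) {
  eligible <- followup_days > 0
  scores <- scores[eligible]
  days_to_first <- days_to_first[eligible]
  followup_days <- followup_days[eligible]
  cases <- is.finite(days_to_first)
  or <- or_test(scores, cases)
  cox <- cox_hr(ifelse(cases, days_to_first, followup_days), cases, scores)
  data.frame(or = or$or, or_p = or$p, hr = cox$hr, hr_p = cox$p,
             n_cases = or$n_cases, n_total = or$n_total)
}

#' Stratified z-scored marker matrix for a test cohort
#'
#' log2 intensities of the requested markers z-scored within
#' gender-by-diagnosis strata (zero-variance and singleton strata excluded).
#'
#' @param bundle An [expression_bundle()].
#' @param visits Visit table matching the bundle's samples.
#' @param probeset_ids Markers to extract.
#' @return Numeric matrix, markers x samples.
#' @export
marker_z_matrix <- function(bundle, visits, probeset_ids) {
  i <- match(probeset_ids, bundle$probeset_ids)
  if (anyNA(i)) abort("marker probeset(s) missing from bundle")
  j <- match(visits$sample_id, bundle$sample_ids)
  if (anyNA(j)) abort("visit sample(s) missing from bundle")
  mat <- log2(pmax(bundle$intensity[i, j, drop = FALSE], .Machine$double.eps))
  stratum <- paste(visits$gender, visits$diagnosis, sep = ".")
  zscore_matrix_by_stratum(mat, stratum)
}

# Per-visit follow-up quantities relative to each testing visit.
visit_followup <- function(visits, followup) {
  k <- match(visits$subject_id, followup$subject_id)
  if (anyNA(k)) abort("follow-up record missing for %d subject(s)",
                      sum(is.na(unique(k))))
  idx_day <- followup$index_visit_day[k]
  last_note <- followup$last_note_day[k]
  fdays <- idx_day - visits$day + last_note
  first_ev <- vapply(seq_len(nrow(visits)), function(r) {
    ev <- followup$ed_pain_event_days[[k[r]]]
    if (!length(ev)) Inf else min(ev) + idx_day[r] - visits$day[r]
  }, numeric(1))
  n_ev <- vapply(k, function(kk) length(followup$ed_pain_event_days[[kk]]),
                 numeric(1))
  data.frame(followup_days = fdays, days_to_first = first_ev, n_events = n_ev)
}

# Strata plan over a visit table: all subjects, by gender, and by
# gender-by-diagnosis including the pooled PSYCHOSIS (SZ + SZA) stratum.
strata_plan <- function(visits) {
  plan <- list(list(level = "all", label = "all", sel = rep(TRUE, nrow(visits))))
  for (g in sort(unique(visits$gender))) {
    plan[[length(plan) + 1]] <- list(level = "gender", label = g,
                                     sel = visits$gender == g)
  }
  dx_groups <- c(as.list(sort(unique(visits$diagnosis))),
                 list(PSYCHOSIS = c("SZ", "SZA")))
  names(dx_groups) <- c(sort(unique(visits$diagnosis)), "PSYCHOSIS")
  for (g in sort(unique(visits$gender))) {
    for (dx in names(dx_groups)) {
      sel <- visits$gender == g & visits$diagnosis %in% dx_groups[[dx]]
      if (!any(sel)) next
      plan[[length(plan) + 1]] <- list(level = "gender_dx",
                                       label = paste(g, dx, sep = "-"),
                                       sel = sel)
    }
  }
  plan
}

#' Run stratified state and trait predictions for a marker set
#'
#' Evaluates every marker (and optional panels) against the requested
#' outcomes in all subjects, by gender, and by gender-by-diagnosis (with
#' psychosis = SZ + SZA pooled), cross-sectionally and longitudinally.
#' Cross-sectional rows use the risk-oriented z at each visit; longitudinal
#' rows use the equal-weight composite of last level, maximum level, last
#' slope, and maximum slope over the subject's visit history up to each
#' visit (from the second visit on). Strata with fewer than `min_cases`
#' cases or controls are reported as skipped. Significance is one-sided
#' `p < alpha` on the outcome's primary metric (AUC for state and first-year
#' trait, odds ratio for all-years trait).
#'
#' @param markers data.frame: probeset_id, direction ("I"/"D").
#' @param bundle,visits,followup Test-cohort expression, visits, follow-up.
#' @param outcomes Subset of c("state", "trait_year1", "trait_all").
#' @param modes Subset of c("cross_sectional", "longitudinal").
#' @param panels Optional named list of probeset-id vectors evaluated as
#'   risk-oriented summation panels.
#' @param alpha One-sided significance level (default 0.05).
#' @param min_cases Minimum cases and controls per stratum (default 2).
#' @return data.frame of prediction results, one row per marker x outcome x
#'   stratum x mode, with columns marker, outcome, stratum_level, stratum,
#'   mode, n_cases, n_total, auc, auc_p, t_p, r, r_p, or, or_p, hr, hr_p, p
#'   (primary), significant, skipped, reason.
#' @export
stratified_run <- function(markers, bundle, visits, followup = NULL,
                           outcomes = c("state", "trait_year1", "trait_all"),
                           modes = c("cross_sectional", "longitudinal"),
                           panels = NULL, alpha = 0.05, min_cases = 2) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(followup) && any(outcomes != "state")) {
    abort("trait outcomes need a follow-up table")
  }
  markers <- markers[, c("probeset_id", "direction")]
  if (any(is.na(markers$direction))) abort("every marker needs a direction")

  zmat <- marker_z_matrix(bundle, visits, markers$probeset_id)
  oriented <- zmat * ifelse(markers$direction == "I", 1, -1)
  score_list <- stats::setNames(
    lapply(seq_len(nrow(markers)), function(i) oriented[i, ]),
    markers$probeset_id)
  for (pn in names(panels)) {
    sel <- match(panels[[pn]], markers$probeset_id)
    if (anyNA(sel)) abort("panel %s references unknown markers", pn)
    score_list[[pn]] <- colSums(oriented[sel, , drop = FALSE])
  }

  ord <- order(visits$subject_id, visits$day)
  fu <- if (is.null(followup)) NULL else visit_followup(visits, followup)
  plan <- strata_plan(visits)

  long_rows_for <- function(scores) {
    # expanding-window longitudinal composite, visits 2..n per subject
    rows <- integer(0)
    feats <- list(last_level = numeric(0), max_level = numeric(0),
                  last_slope = numeric(0), max_slope = numeric(0))
    for (idx in split(ord, visits$subject_id[ord])) {
      if (length(idx) < 2) next
      for (k in 2:length(idx)) {
        w <- idx[1:k]
        if (any(!is.finite(scores[w]))) next
        f <- longitudinal_features(scores[w], visits$day[w])
        rows <- c(rows, idx[k])
        for (nm in names(feats)) feats[[nm]] <- c(feats[[nm]], f[[nm]])
      }
    }
    list(rows = rows,
         scores = if (length(rows)) longitudinal_composite(feats) else numeric(0))
  }

  out <- list()
  emit <- function(marker, outcome, st, mode, stats_row, skipped, reason) {
    base <- data.frame(marker = marker, outcome = outcome,
                       stratum_level = st$level, stratum = st$label,
                       mode = mode, n_cases = NA_integer_, n_total = NA_integer_,
                       auc = NA_real_, auc_p = NA_real_, t_p = NA_real_,
                       r = NA_real_, r_p = NA_real_, or = NA_real_,
                       or_p = NA_real_, hr = NA_real_, hr_p = NA_real_,
                       p = NA_real_, significant = FALSE, skipped = skipped,
                       reason = reason, stringsAsFactors = FALSE)
    if (!is.null(stats_row)) for (nm in names(stats_row)) base[[nm]] <- stats_row[[nm]]
    out[[length(out) + 1]] <<- base
  }

  for (mk in names(score_list)) {
    sc_cs <- score_list[[mk]]
    lng <- if ("longitudinal" %in% modes) long_rows_for(sc_cs) else NULL
    for (mode in modes) {
      if (mode == "cross_sectional") {
        rows <- which(is.finite(sc_cs)); sc <- sc_cs[rows]
      } else {
        rows <- lng$rows; sc <- lng$scores
      }
      if (!length(rows)) next
      v <- visits[rows, ]
      f <- if (is.null(fu)) NULL else fu[rows, ]
      for (st in plan) {
        sel <- st$sel[rows]
        for (outcome in outcomes) {
          cases <- switch(outcome,
            state = v$pain_vas >= 6,
            trait_year1 = f$followup_days >= 365 & f$days_to_first <= 365,
            trait_all = f$followup_days > 0 & is.finite(f$days_to_first))
          eligible <- switch(outcome,
            state = rep(TRUE, nrow(v)),
            trait_year1 = f$followup_days >= 365,
            trait_all = f$followup_days > 0)
          use <- sel & eligible
          n1 <- sum(cases[use]); n0 <- sum(use) - n1
          if (n1 < min_cases || n0 < min_cases) {
            emit(mk, outcome, st, mode, NULL, TRUE,
                 sprintf("%d cases / %d controls below minimum %d",
                         n1, n0, min_cases))
            next
          }
          res <- switch(outcome,
            state = state_tests(sc[use], cases[use], v$pain_vas[use]),
            trait_year1 = trait_year1_tests(sc[use], f$days_to_first[use],
                                            f$followup_days[use],
                                            f$n_events[use]),
            trait_all = trait_all_tests(sc[use], f$days_to_first[use],
                                        f$followup_days[use]))
          res$p <- if (outcome == "trait_all") res$or_p else res$auc_p
          res$significant <- is.finite(res$p) & res$p < alpha
          emit(mk, outcome, st, mode, res, FALSE, "")
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
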