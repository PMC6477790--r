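# Step 1 — within-subject longitudinal discovery scoring.
#
# Each subject contributes every (Low Pain visit, High Pain visit) pair; a
# probeset is scored by the fraction of those pairs in which it changes
# concordantly, either by detection-call switching (AP) or by fold change
# (DE), and the fraction maps onto 0/2/4/6 internal points.

#' Label the pain state of a visit
#'
#' Visual-analog-scale pain (0-10) is trichotomised: Low Pain at VAS 2 and
#' below, High Pain at VAS 6 and above, Intermediate between.
#'
#' @param pain_vas Integer vector of VAS scores in 0..10.
#' @return Character vector of "Low"/"Intermediate"/"High".
#' @export
label_pain_state <- function(pain_vas) {
  if (any(!is.finite(pain_vas) | pain_vas < 0 | pain_vas > 10)) {
    abort("pain_vas values must lie in [0, 10]")
  }
  ifelse(pain_vas <= 2, "Low", ifelse(pain_vas >= 6, "High", "Intermediate"))
}

#' Enumerate within-subject Low/High visit comparisons
#'
#' All (Low Pain, High Pain) visit pairs within each subject, in both temporal
#' orders; this is the within-subject comparison unit that the across-subject
#' concordance fraction is computed over. Subjects lacking either state
#' contribute no comparisons.
#'
#' @param visits Visit table with subject_id, visit_id, sample_id, pain_vas.
#' @return data.frame with columns subject_id, low_sample, high_sample
#'   (possibly zero rows).
#' @export
enumerate_comparisons <- function(visits) {
  state <- label_pain_state(visits$pain_vas)
  rows <- lapply(split(seq_len(nrow(visits)), visits$subject_id), function(idx) {
    lo <- idx[state[idx] == "Low"]
    hi <- idx[state[idx] == "High"]
    if (!length(lo) || !length(hi)) return(NULL)
    grid <- expand.grid(low = lo, high = hi)
    data.frame(subject_id = visits$subject_id[grid$low],
               low_sample = visits$sample_id[grid$low],
               high_sample = visits$sample_id[grid$high],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), low_sample = character(),
                      high_sample = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Numeric encoding of Absent/Marginal/Present detection calls
#'
#' A -> 0, M -> 0.5, P -> 1. Used when call data stand in for intensities in
#' AP-mode validation and testing.
#'
#' @param call Character vector of "A"/"M"/"P" (matrices allowed).
#' @return Numeric vector (or matrix) of 0 / 0.5 / 1.
#' @export
encode_ap <- function(call) {
  num <- unname(c(A = 0, M = 0.5, P = 1)[as.vector(call)])
  if (anyNA(num) && !anyNA(call)) {
    bad <- unique(setdiff(as.vector(call), names(c(A = 0, M = 0.5, P = 1))))
    abort("unknown detection call(s): %s", paste(bad, collapse = ", "))
  }
  if (is.matrix(call)) {
    num <- matrix(num, nrow(call), ncol(call), dimnames = dimnames(call))
  }
  num
}

#' Map a concordance fraction onto internal discovery points
#'
#' At least 33% of comparisons concordant earns 2 points, at least 50% earns
#' 4, and at least 80% earns 6.
#'
#' @param fraction Numeric vector of concordance fractions in [0, 1].
#' @return Integer vector of 0/2/4/6.
#' @export
discovery_points <- function(fraction) {
  ifelse(fraction >= 0.80, 6L,
         ifelse(fraction >= 0.50, 4L, ifelse(fraction >= 0.33, 2L, 0L)))
}

# Concordance indicator matrices (probesets x comparisons) for one method.
# DE: increased iff intensity(High)/intensity(Low) >= fold_threshold,
#     decreased iff ratio <= 1/fold_threshold. A zero Low intensity with a
#     nonzero High one gives ratio Inf (counted increased); 0/0 counts
#     neither way.
# AP: increased iff call switches A -> P from the Low to the High visit,
#     decreased iff P -> A; Marginal calls never count as a switch.
concordance_matrices <- function(bundle, comparisons, method, fold_threshold) {
  li <- match(comparisons$low_sample, bundle$sample_ids)
  hi <- match(comparisons$high_sample, bundle$sample_ids)
  if (anyNA(li) || anyNA(hi)) abort("comparison samples missing from bundle")
  if (method == "DE") {
    ratio <- bundle$intensity[, hi, drop = FALSE] /
      bundle$intensity[, li, drop = FALSE]
    inc <- ratio >= fold_threshold
    dec <- ratio <= 1 / fold_threshold
    inc[!is.finite(ratio) & is.nan(ratio)] <- FALSE
    dec[!is.finite(ratio) & is.nan(ratio)] <- FALSE
  } else {
    lo <- bundle$calls[, li, drop = FALSE]
    hiM <- bundle$calls[, hi, drop = FALSE]
    inc <- lo == "A" & hiM == "P"
    dec <- lo == "P" & hiM == "A"
  }
  list(inc = inc, dec = dec)
}

score_method <- function(bundle, comparisons, method, fold_threshold) {
  n <- nrow(comparisons)
  if (n < 1) abort("at least one Low/High comparison is required")
  cm <- concordance_matrices(bundle, comparisons, method, fold_threshold)
  fi <- rowSums(cm$inc) / n
  fd <- rowSums(cm$dec) / n
  # the direction with the larger concordant fraction wins; exact ties are
  # un-directed and score 0
  tie <- fi == fd
  direction <- ifelse(tie, NA_character_, ifelse(fi > fd, "I", "D"))
  fraction <- pmax(fi, fd)
  points <- discovery_points(fraction)
  points[tie] <- 0L
  data.frame(probeset_id = bundle$probeset_ids, method = method,
             direction = direction, fraction = fraction, points = points,
             stringsAsFactors = FALSE)
}

#' Discovery-score one probeset
#'
#' Scores a single probeset over a set of within-subject Low/High comparisons
#' with one method. See [discovery_table()] for the whole-array version.
#'
#' @param probeset_id Probeset to score.
#' @param comparisons Comparison table from [enumerate_comparisons()].
#' @param bundle An [expression_bundle()].
#' @param method "AP" (call switching) or "DE" (fold change).
#' @param fold_threshold Linear-scale fold threshold for DE concordance
#'   (default 1.2).
#' @return One-row data.frame: probeset_id, method, direction ("I"/"D", NA on
#'   a tie), fraction, points.
#' @export
score_probeset <- function(probeset_id, comparisons, bundle,
                           method = c("DE", "AP"), fold_threshold = 1.2) {
  method <- match.arg(method)
  i <- match(probeset_id, bundle$probeset_ids)
  if (is.na(i)) abort("probeset %s not in bundle", probeset_id)
  sub <- expression_bundle(bundle$intensity[i, , drop = FALSE],
                           bundle$calls[i, , drop = FALSE],
                           probeset_id, bundle$sample_ids)
  score_method(sub, comparisons, method, fold_threshold)
}

#' Discovery table: score every probeset with both methods
#'
#' Runs the within-subject concordance scoring for the AP and DE methods over
#' all probesets and flags the top discovery set (concordance fraction >=
#' `top_fraction`, default 90%).
#'
#' @param bundle An [expression_bundle()].
#' @param visits Visit table of the discovery cohort.
#' @param fold_threshold Linear fold threshold for DE (default 1.2).
#' @param top_fraction Concordance fraction for the top-set flag
#'   (default 0.90, inclusive).
#' @return data.frame with one row per probeset per method: probeset_id,
#'   method, direction, fraction, points, top_flag.
#' @export
discovery_table <- function(bundle, visits, fold_threshold = 1.2,
                            top_fraction = 0.90) {
  comparisons <- enumerate_comparisons(visits)
  if (nrow(comparisons) == 0) {
    abort("no within-subject Low/High comparisons in this cohort")
  }
  out <- rbind(score_method(bundle, comparisons, "AP", fold_threshold),
               score_method(bundle, comparisons, "DE", fold_threshold))
  out$top_flag <- out$fraction >= top_fraction
  rownames(out) <- NULL
  out
}

#' Best internal discovery score per probeset
#'
#' Collapses the two-method discovery table to one row per probeset, keeping
#' the method with the larger concordance fraction; this is the internal
#' score (0-6) that feeds prioritization and the final evidence tabulation.
#'
#' @param disc A [discovery_table()] result.
#' @return data.frame: probeset_id, method, direction, fraction, points,
#'   top_flag.
#' @export
best_discovery <- function(disc) {
  ord <- order(disc$probeset_id, -disc$points, -disc$fraction)
  d <- disc[ord, ]
  d <- d[!duplicated(d$probeset_id), ]
  rownames(d) <- NULL
  d
}
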