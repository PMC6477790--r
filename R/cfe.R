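# Convergent Functional Evidence (CFE) tabulation and ranking.
#
# Every biomarker's evidence across the pipeline is folded into one score:
# discovery (0-6), prioritization/CFG (0-12), validation (0-6), and three
# testing outcomes (state, first-year trait, all-years trait) worth up to 8
# points each — 8 when the marker significantly predicts in all subjects, 6
# when only within a gender, 4 when only within a gender-by-diagnosis
# stratum. Maximum 48: 36 points from the study's own data and 12 from the
# literature, a deliberate 3:1 weighting of internal over external evidence.

#' Testing points for one marker and outcome
#'
#' The best significant stratum level determines the points: any significant
#' all-subjects result gives 8; otherwise any significant gender-stratum
#' result gives 6; otherwise any significant gender-by-diagnosis result gives
#' 4; otherwise 0. Cross-sectional and longitudinal results both qualify.
#'
#' @param results Prediction rows for one marker and one outcome (columns
#'   stratum_level, significant), as produced by [stratified_run()].
#' @return Integer 0, 4, 6, or 8.
#' @export
testing_points <- function(results) {
  sig <- results$stratum_level[results$significant %in% TRUE]
  if ("all" %in% sig) 8L
  else if ("gender" %in% sig) 6L
  else if ("gender_dx" %in% sig) 4L
  else 0L
}

#' Per-step score bundle for one biomarker
#'
#' Validates the six step scores that feed the CFE tabulation.
#'
#' @param probeset_id Biomarker identifier.
#' @param discovery Internal discovery points (0/2/4/6).
#' @param cfg External CFG points (0-12).
#' @param validation Validation points (0/2/4/6).
#' @param state,trait_year1,trait_all Testing points (0/4/6/8).
#' @return A validated one-row data.frame of class `step_scores`.
#' @export
step_scores <- function(probeset_id, discovery, cfg, validation,
                        state, trait_year1, trait_all) {
  if (!discovery %in% c(0, 2, 4, 6)) abort("discovery points must be 0/2/4/6")
  if (cfg < 0 || cfg > 12) abort("cfg points must lie in [0, 12]")
  if (!validation %in% c(0, 2, 4, 6)) abort("validation points must be 0/2/4/6")
  for (f in list(state = state, trait_year1 = trait_year1,
                 trait_all = trait_all)) {
    if (!f %in% c(0, 4, 6, 8)) abort("testing points must be 0/4/6/8")
  }
  out <- data.frame(probeset_id = probeset_id, discovery = discovery,
                    cfg = cfg, validation = validation, state = state,
                    trait_year1 = trait_year1, trait_all = trait_all,
                    stringsAsFactors = FALSE)
  class(out) <- c("step_scores", class(out))
  out
}

#' Tabulate the CFE score from per-step scores
#'
#' Total = discovery + CFG + validation + three testing outcomes (maximum
#' 48). The internal subtotal (everything except CFG, maximum 36) and the
#' literature subtotal (CFG, maximum 12) are reported separately.
#'
#' @param steps A [step_scores()] row (or a data.frame of them).
#' @return data.frame: probeset_id, the six step fields, total,
#'   internal_subtotal, literature_subtotal.
#' @export
cfe_total <- function(steps) {
  total <- steps$discovery + steps$cfg + steps$validation + steps$state +
    steps$trait_year1 + steps$trait_all
  out <- data.frame(steps, total = total,
                    internal_subtotal = total - steps$cfg,
                    literature_subtotal = steps$cfg)
  class(out) <- "data.frame"
  out
}

#' Rank biomarkers by CFE score
#'
#' Descending by total; ties broken by the internal (own-data) subtotal,
#' then by probeset_id for a stable order.
#'
#' @param reports A [cfe_total()] table.
#' @return The table sorted, with a `rank` column (1 = best).
#' @export
rank_biomarkers <- function(reports) {
  if (nrow(reports) < 1) abort("at least one report required")
  ord <- order(-reports$total, -reports$internal_subtotal, reports$probeset_id)
  out <- reports[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full CFE report from the pipeline's stage tables
#'
#' Joins the best discovery score, the external CFG score, the validation
#' points, and the per-outcome testing points of every long-list marker into
#' a ranked CFE table.
#'
#' @param long_list Character vector of probesets carried into testing.
#' @param disc A [discovery_table()] result.
#' @param cfg_tab A [cfg_table()] result.
#' @param val_tab A [validation_table()] result.
#' @param predictions A [stratified_run()] result.
#' @return Ranked CFE table (see [cfe_total()], [rank_biomarkers()]).
#' @export
cfe_table <- function(long_list, disc, cfg_tab, val_tab, predictions) {
  best <- best_discovery(disc)
  rows <- lapply(long_list, function(ps) {
    d <- best$points[match(ps, best$probeset_id)]
    cf <- cfg_tab$external[match(ps, cfg_tab$probeset_id)]
    v <- val_tab$points[match(ps, val_tab$probeset_id)]
    pred <- predictions[predictions$marker == ps, ]
    step_scores(
      ps,
      discovery = if (is.na(d)) 0 else d,
      cfg = if (is.na(cf)) 0 else cf,
      validation = if (length(v) == 0 || is.na(v)) 0 else v,
      state = testing_points(pred[pred$outcome == "state", ]),
      trait_year1 = testing_points(pred[pred$outcome == "trait_year1", ]),
      trait_all = testing_points(pred[pred$outcome == "trait_all", ])
    )
  })
  rank_biomarkers(cfe_total(do.call(rbind, rows)))
}
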