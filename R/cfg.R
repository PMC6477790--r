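# Step 2 — prioritization by Convergent Functional Genomics (CFG).
#
# Prior literature evidence for a gene's involvement in pain is summarised
# into an external score: each of six evidence categories (human / non-human
# x genetic / nervous tissue / peripheral tissue-fluids) with at least one
# citation contributes points, capped at 12. Added to the internal discovery
# score (0-6) it gives a combined score out of 18; candidates at 6 and above
# (one third of the maximum) are carried into validation, which deliberately
# keeps novel genes that have a maximal internal score but no literature
# trail.

validate_evidence <- function(evidence) {
  need <- c("gene_symbol", "category", "citation_tag")
  if (!all(need %in% names(evidence))) {
    abort("evidence table needs columns %s", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(evidence$category), evidence_categories())
  if (length(bad)) abort("unknown evidence categor(y/ies): %s",
                         paste(bad, collapse = ", "))
  if (any(!nzchar(evidence$citation_tag))) abort("citation_tag must be non-empty")
  invisible(evidence)
}

#' External CFG evidence score
#'
#' Scores genes by the number of distinct literature-evidence categories in
#' which they have at least one citation. Each category carries a
#' configurable weight (default 2 points each over the six categories) and
#' the total is capped at `cap` (default 12). Multiple citations within one
#' category add nothing; a gene absent from the table scores 0.
#'
#' @param gene_symbols Character vector of genes to score.
#' @param evidence Evidence table (gene_symbol, category, citation_tag).
#' @param weights Named per-category weights over [evidence_categories()].
#' @param cap Maximum external score (default 12).
#' @return Named numeric vector of external points, one per input gene.
#' @export
cfg_external_score <- function(gene_symbols, evidence,
                               weights = stats::setNames(rep(2, 6), evidence_categories()),
                               cap = 12) {
  validate_evidence(evidence)
  if (!all(names(weights) %in% evidence_categories())) {
    abort("weights must be named by evidence_categories()")
  }
  has <- unique(evidence[, c("gene_symbol", "category")])
  pts <- tapply(weights[has$category], has$gene_symbol, sum)
  out <- stats::setNames(as.numeric(pts[gene_symbols]), gene_symbols)
  out[is.na(out)] <- 0
  pmin(out, cap)
}

#' Combine internal discovery and external CFG scores
#'
#' The combined score is the plain sum (maximum 6 + 12 = 18); candidates with
#' a combined score of at least `cutoff` (default 6, one third of the
#' maximum) carry forward into validation.
#'
#' @param internal Internal discovery points in [0, 6].
#' @param external External CFG points in [0, 12].
#' @param cutoff Carry-forward threshold on the combined score (default 6).
#' @return data.frame with columns internal, external, combined,
#'   carry_forward.
#' @export
cfg_combine <- function(internal, external, cutoff = 6) {
  if (any(internal < 0 | internal > 6)) abort("internal points must lie in [0, 6]")
  if (any(external < 0 | external > 12)) abort("external points must lie in [0, 12]")
  combined <- internal + external
  data.frame(internal = internal, external = external, combined = combined,
             carry_forward = combined >= cutoff)
}

#' CFG score table for a discovery run
#'
#' Propagates gene-level external CFG scores to probesets via a
#' probeset-to-gene map and combines them with each probeset's best internal
#' discovery score.
#'
#' @param disc A [discovery_table()] result.
#' @param evidence Evidence table.
#' @param probe2gene data.frame with columns probeset_id, gene_symbol.
#' @param weights,cap,cutoff Passed to [cfg_external_score()] /
#'   [cfg_combine()].
#' @return data.frame: probeset_id, gene_symbol, method, direction, fraction,
#'   internal, external, combined, carry_forward.
#' @export
cfg_table <- function(disc, evidence, probe2gene,
                      weights = stats::setNames(rep(2, 6), evidence_categories()),
                      cap = 12, cutoff = 6) {
  best <- best_discovery(disc)
  gene <- probe2gene$gene_symbol[match(best$probeset_id, probe2gene$probeset_id)]
  if (anyNA(gene)) abort("probe2gene map misses %d probeset(s)", sum(is.na(gene)))
  ext <- cfg_external_score(unique(gene), evidence, weights, cap)
  comb <- cfg_combine(best$points, as.numeric(ext[gene]), cutoff)
  data.frame(probeset_id = best$probeset_id, gene_symbol = gene,
             method = best$method, direction = best$direction,
             fraction = best$fraction, comb, stringsAsFactors = FALSE)
}

#' Assemble the long candidate list carried into testing
#'
#' Union of the top discovery probesets (concordance at or above the top-set
#' cutoff), the top prioritization probesets (external CFG score at or above
#' 8), and the nominally significant probesets from validation —
#' deduplicated, in that stable order.
#'
#' @param discovery_top Character vector of top discovery probesets.
#' @param cfg_top Character vector of top-CFG probesets (external >= 8).
#' @param validated_nominal Character vector of nominally significant
#'   validation probesets.
#' @return Character vector: ordered, deduplicated union.
#' @export
assemble_long_list <- function(discovery_top, cfg_top, validated_nominal) {
  unique(c(discovery_top, cfg_top, validated_nominal))
}
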