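#!/usr/bin/env Rscript
# Stage 5: state and trait prediction in the independent test cohort.
#
# The long candidate list (discovery top set + external CFG >= 8 + nominally
# validated) is tested for predicting High Pain state and future ED pain
# visits (first year; all years), cross-sectionally and longitudinally, in
# all subjects and within gender and gender-by-diagnosis strata. The full
# long-list panel and the validated short-list panel are evaluated as
# risk-oriented summation composites. Writes results/predictions.tsv and
# results/long_list.tsv.

suppressPackageStartupMessages(library(painmarkers))

test <- read_cohort("results/data/test")
disc_tab <- utils::read.delim("results/discovery.tsv")
cfg_tab <- utils::read.delim("results/cfg.tsv")
val <- utils::read.delim("results/validation.tsv")

best <- best_discovery(disc_tab)
discovery_top <- best$probeset_id[best$top_flag & !is.na(best$direction)]
cfg_top <- cfg_tab$probeset_id[cfg_tab$external >= 8 & !is.na(cfg_tab$direction)]
validated_nominal <- val$probeset_id[val$points >= 4]
long_list <- assemble_long_list(discovery_top, cfg_top, validated_nominal)
message(sprintf("long list: %d probesets (%d discovery + %d CFG + %d validated)",
                length(long_list), length(discovery_top), length(cfg_top),
                length(validated_nominal)))

markers <- data.frame(probeset_id = long_list,
                      direction = best$direction[match(long_list,
                                                       best$probeset_id)])
markers <- markers[!is.na(markers$direction), ]
utils::write.table(markers, "results/long_list.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

panels <- list(panel_long = markers$probeset_id)
short <- intersect(validated_nominal, markers$probeset_id)
if (length(short) > 1) panels$panel_short <- short

pred <- stratified_run(markers, test$bundle, test$visits, test$followup,
                       panels = panels)
utils::write.table(pred, "results/predictions.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

ok <- pred[!pred$skipped, ]
message(sprintf("%d evaluations (%d skipped small strata); %d significant at p < 0.05",
                nrow(pred), sum(pred$skipped), sum(ok$significant)))
for (oc in unique(ok$outcome)) {
  sub <- ok[ok$outcome == oc & ok$stratum_level == "all" & ok$significant, ]
  if (!nrow(sub)) next
  b <- sub[order(sub$p), ][1, ]
  metric <- if (oc == "trait_all") sprintf("OR %.2f", b$or) else
    sprintf("AUC %.2f", b$auc)
  message(sprintf("best all-subjects %s predictor: %s (%s, %s, p=%.2e)",
                  oc, b$marker, metric, b$mode, b$p))
}
message("wrote results/predictions.tsv")
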