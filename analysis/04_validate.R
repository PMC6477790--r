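#!/usr/bin/env Rscript
# Stage 4: validation against the clinically severe cohort.
#
# Carried-forward candidates are z-scored within gender-by-diagnosis strata
# over three groups (discovery Low Pain, discovery non-severe High Pain,
# clinically severe validation cohort) and tested for a stepwise change in
# their discovery direction with one-way ANOVA and Bonferroni correction.
# Writes results/validation.tsv.

suppressPackageStartupMessages(library(painmarkers))

disc <- read_cohort("results/data/discovery")
sev <- read_cohort("results/data/validation")
cfg_tab <- utils::read.delim("results/cfg.tsv")

cand <- cfg_tab[cfg_tab$carry_forward & !is.na(cfg_tab$direction),
                c("probeset_id", "direction", "method")]
message(sprintf("%d candidates entering validation (Bonferroni denominator)",
                nrow(cand)))

val <- validation_table(cand, disc$bundle, disc$visits, sev$bundle, sev$visits)
utils::write.table(val, "results/validation.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

message(sprintf("stepwise changed: %d; nominally significant: %d; Bonferroni: %d",
                sum(val$stepwise), sum(val$points >= 4), sum(val$points == 6)))
top <- val[order(val$anova_p), ][1:5, c("probeset_id", "anova_p", "points")]
message("most significant candidates:")
for (i in seq_len(nrow(top))) {
  message(sprintf("  %s  p=%.2e  points=%d", top$probeset_id[i],
                  top$anova_p[i], top$points[i]))
}
message("wrote results/validation.tsv")
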