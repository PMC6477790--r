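#!/usr/bin/env Rscript
# Stage 6: convergent functional evidence tabulation.
#
# Folds discovery, prioritization, validation, and the three testing
# outcomes into the 0-48 CFE score per long-list marker and ranks the
# biomarkers. Writes results/cfe.tsv and reports how well the final ranking
# recovers the planted ground truth.

suppressPackageStartupMessages(library(painmarkers))

disc_tab <- utils::read.delim("results/discovery.tsv")
cfg_tab <- utils::read.delim("results/cfg.tsv")
val <- utils::read.delim("results/validation.tsv")
pred <- utils::read.delim("results/predictions.tsv")
markers <- utils::read.delim("results/long_list.tsv")
truth <- utils::read.delim("results/data/discovery/truth.tsv")

cfe <- cfe_table(markers$probeset_id, disc_tab, cfg_tab, val, pred)
utils::write.table(cfe, "results/cfe.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

message("top 10 biomarkers by CFE score:")
for (i in seq_len(min(10, nrow(cfe)))) {
  r <- cfe[i, ]
  message(sprintf(
    "  %2d. %-8s total=%2d (discovery %d + CFG %g + validation %d + testing %d/%d/%d)",
    r$rank, r$probeset_id, r$total, r$discovery, r$cfg, r$validation,
    r$state, r$trait_year1, r$trait_all))
}
n_top <- min(20, nrow(cfe))
planted_top <- sum(truth$role[match(cfe$probeset_id[1:n_top],
                                    truth$probeset_id)] != "null")
message(sprintf("planted markers among the top %d: %d", n_top, planted_top))
message("wrote results/cfe.tsv")
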