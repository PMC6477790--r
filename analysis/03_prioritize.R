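#!/usr/bin/env Rscript
# Stage 3: prioritization by convergent functional genomics.
#
# Gene-level literature evidence across six categories is scored (2 points
# each, cap 12), combined with each probeset's best internal discovery score
# (max 6; combined max 18), and candidates at combined score >= 6 are
# carried into validation. Writes results/cfg.tsv.

suppressPackageStartupMessages(library(painmarkers))

tab <- utils::read.delim("results/discovery.tsv")
evidence <- read_evidence("results/data/evidence.tsv")
p2g <- utils::read.delim("results/data/probe2gene.tsv")

cfg_tab <- cfg_table(tab, evidence, p2g)
utils::write.table(cfg_tab, "results/cfg.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

message(sprintf("external CFG points: %d genes scored > 0, max %g",
                sum(cfg_tab$external > 0), max(cfg_tab$external)))
message(sprintf("combined score >= 6: %d candidates carried to validation",
                sum(cfg_tab$carry_forward)))
message(sprintf("  of which novel (internal 6, no external evidence): %d",
                sum(cfg_tab$carry_forward & cfg_tab$internal == 6 &
                      cfg_tab$external == 0)))
message(sprintf("external >= 8 (prioritization top set): %d probesets",
                sum(cfg_tab$external >= 8)))
message("wrote results/cfg.tsv")
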