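#!/usr/bin/env Rscript
# Stage 1 of the analysis: simulate the three study cohorts.
#
# The discovery cohort uses the fixed published design (28 subjects, 79
# visits, every subject with a diametric Low->High pain change); the
# validation cohort is 23 uniformly clinically severe subjects; the test
# cohort is an independent 170-subject cohort spanning the full pain range
# with ED follow-up. A shared array design (1000 probesets, 30 planted
# algogenes + 30 pain suppressors, effect size 2 z units) is used throughout,
# together with a literature-evidence table aligned with the planted truth.
#
# Writes results/data/{discovery,validation,test}/ plus evidence.tsv and
# probe2gene.tsv. Run from the repository root; --seed (default 1) controls
# every random draw.

suppressPackageStartupMessages(library(painmarkers))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

array_cfg <- function(n_subjects) {
  sim_config(n_subjects = n_subjects, n_probesets = 1000, n_algogenes = 30,
             n_suppressors = 30, effect_size = 2, seed = seed)
}

disc <- fixture_cohort(array_cfg(28))
sev <- generate_cohort(array_cfg(23), "validation")
test <- generate_cohort(array_cfg(170), "test")
evidence <- generate_evidence(disc$truth, seed = seed)

root <- "results/data"
write_cohort(disc, file.path(root, "discovery"))
write_cohort(sev, file.path(root, "validation"))
write_cohort(test, file.path(root, "test"))
utils::write.table(evidence, file.path(root, "evidence.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(disc$truth[, c("probeset_id", "gene_symbol")],
                   file.path(root, "probe2gene.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf("discovery: %d subjects / %d visits (fixed design)",
                length(unique(disc$visits$subject_id)), nrow(disc$visits)))
message(sprintf("validation: %d subjects / %d visits, all clinically severe",
                length(unique(sev$visits$subject_id)), nrow(sev$visits)))
message(sprintf("test: %d subjects / %d visits, %d with >= 1 ED pain visit",
                length(unique(test$visits$subject_id)), nrow(test$visits),
                sum(vapply(test$followup$ed_pain_event_days, length, 1L) > 0)))
message(sprintf("evidence: %d citations over %d genes", nrow(evidence),
                length(unique(evidence$gene_symbol))))
message("wrote ", root)
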