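# Readers, writers, and the end-to-end pipeline driver.
#
# All artifacts are plain tab-separated tables with header rows; expression
# and call matrices carry probesets in rows with a probeset_id first column
# and one column per visit sample (keyed subjectID_visitID). ED event days
# are serialised as a comma-joined list.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a cohort's tables to a directory
#'
#' Writes visits.tsv, expression.tsv, calls.tsv, followup.tsv, and truth.tsv
#' (when a truth table is present) under `dir`.
#'
#' @param cohort A [generate_cohort()] result (or a list with the same
#'   members).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cohort$visits, file.path(dir, "visits.tsv"))
  b <- cohort$bundle
  write_tsv(data.frame(probeset_id = b$probeset_ids, b$intensity,
                       check.names = FALSE),
            file.path(dir, "expression.tsv"))
  write_tsv(data.frame(probeset_id = b$probeset_ids, b$calls,
                       check.names = FALSE),
            file.path(dir, "calls.tsv"))
  if (!is.null(cohort$followup)) {
    fu <- cohort$followup
    flat <- data.frame(
      subject_id = fu$subject_id, index_visit_day = fu$index_visit_day,
      ed_pain_event_days = vapply(fu$ed_pain_event_days, paste,
                                  character(1), collapse = ","),
      last_note_day = fu$last_note_day, stringsAsFactors = FALSE)
    write_tsv(flat, file.path(dir, "followup.tsv"))
  }
  if (!is.null(cohort$truth)) write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' Read and validate a visit table
#'
#' @param path visits.tsv path.
#' @return Validated visit data.frame.
#' @export
read_visits <- function(path) {
  v <- read_tsv(path)
  need <- c("subject_id", "visit_id", "day", "gender", "diagnosis",
            "pain_vas", "sf36_21", "sf36_22", "sample_id")
  miss <- setdiff(need, names(v))
  if (length(miss)) abort("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  if (anyDuplicated(v[, c("subject_id", "visit_id")])) {
    abort("%s: duplicated (subject_id, visit_id)", path)
  }
  if (any(v$pain_vas < 0 | v$pain_vas > 10)) {
    abort("%s: pain_vas outside [0, 10] at row %d", path,
          which(v$pain_vas < 0 | v$pain_vas > 10)[1])
  }
  if (!all(v$gender %in% c("M", "F"))) abort("%s: gender must be M or F", path)
  bad <- setdiff(unique(v$diagnosis), diagnosis_codes())
  if (length(bad)) abort("%s: unknown diagnosis %s", path,
                         paste(bad, collapse = ", "))
  day_ok <- vapply(split(v$day, v$subject_id),
                   function(d) !is.unsorted(d), logical(1))
  if (!all(day_ok)) abort("%s: days must be non-decreasing within subject", path)
  v
}

#' Read paired expression and detection-call matrices
#'
#' @param expr_path,calls_path expression.tsv / calls.tsv paths (probeset_id
#'   first column, one column per sample).
#' @param visits Optional visit table: every sample column must match
#'   exactly one visit row.
#' @return An [expression_bundle()].
#' @export
read_expression_bundle <- function(expr_path, calls_path, visits = NULL) {
  e <- read_tsv(expr_path)
  k <- read_tsv(calls_path)
  if (names(e)[1] != "probeset_id") abort("%s: first column must be probeset_id", expr_path)
  if (names(k)[1] != "probeset_id") abort("%s: first column must be probeset_id", calls_path)
  if (!identical(dim(e), dim(k)) || !identical(names(e), names(k)) ||
      !identical(e$probeset_id, k$probeset_id)) {
    abort("%s and %s must share probesets and samples", expr_path, calls_path)
  }
  cm <- as.matrix(k[, -1, drop = FALSE])
  bad <- which(!cm %in% c("A", "M", "P"))
  if (length(bad)) {
    r <- (bad[1] - 1) %% nrow(cm) + 1
    cc <- (bad[1] - 1) %/% nrow(cm) + 1
    abort("%s: invalid call '%s' at probeset %s, sample %s", calls_path,
          cm[bad[1]], k$probeset_id[r], colnames(cm)[cc])
  }
  if (!is.null(visits)) {
    orphan <- setdiff(colnames(e)[-1], visits$sample_id)
    if (length(orphan)) abort("%s: sample(s) with no visit row: %s", expr_path,
                              paste(utils::head(orphan, 3), collapse = ", "))
  }
  expression_bundle(as.matrix(e[, -1, drop = FALSE]), cm,
                    e$probeset_id, names(e)[-1])
}

#' Read a follow-up table
#'
#' @param path followup.tsv path (ed_pain_event_days comma-joined).
#' @return data.frame with ed_pain_event_days as a list column of sorted
#'   non-negative day offsets.
#' @export
read_followup <- function(path) {
  f <- read_tsv(path)
  need <- c("subject_id", "index_visit_day", "ed_pain_event_days", "last_note_day")
  miss <- setdiff(need, names(f))
  if (length(miss)) abort("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  ev <- lapply(strsplit(as.character(f$ed_pain_event_days), ","), function(x) {
    x <- suppressWarnings(as.numeric(x[nzchar(x)]))
    if (anyNA(x)) abort("%s: non-numeric ED event day", path)
    x
  })
  if (any(vapply(ev, function(x) length(x) && (is.unsorted(x) || any(x < 0)),
                 logical(1)))) {
    abort("%s: event days must be sorted, non-negative offsets", path)
  }
  if (any(f$last_note_day < 0)) abort("%s: last_note_day must be >= 0", path)
  f$ed_pain_event_days <- I(ev)
  f
}

#' Read and validate an evidence table
#'
#' @param path evidence.tsv path.
#' @return Validated evidence data.frame.
#' @export
read_evidence <- function(path) {
  validate_evidence(read_tsv(path))
}

#' Read every input table of a pipeline run
#'
#' Schema-checks each file and cross-references expression samples against
#' visit rows.
#'
#' @param dir Directory holding visits.tsv, expression.tsv, calls.tsv, and
#'   optionally followup.tsv and truth.tsv.
#' @return List: visits, bundle, followup (or NULL), truth (or NULL).
#' @export
read_cohort <- function(dir) {
  visits <- read_visits(file.path(dir, "visits.tsv"))
  bundle <- read_expression_bundle(file.path(dir, "expression.tsv"),
                                   file.path(dir, "calls.tsv"), visits)
  fu_path <- file.path(dir, "followup.tsv")
  tr_path <- file.path(dir, "truth.tsv")
  list(visits = visits, bundle = bundle,
       followup = if (file.exists(fu_path)) read_followup(fu_path) else NULL,
       truth = if (file.exists(tr_path)) read_tsv(tr_path) else NULL)
}

#' Run the full biomarker pipeline
#'
#' Discovery scoring on the discovery cohort, CFG prioritization, validation
#' against the clinically severe cohort, long-list assembly, stratified
#' state/trait testing in the independent test cohort, and CFE tabulation.
#' All intermediate tables are written under `out_dir` together with a run
#' report; re-running with identical inputs produces byte-identical files.
#'
#' @param discovery,validation,testing Cohort lists (visits, bundle, and for
#'   testing also followup), e.g. from [generate_cohort()] or
#'   [read_cohort()].
#' @param evidence Evidence table.
#' @param probe2gene data.frame probeset_id -> gene_symbol.
#' @param out_dir Output directory (NULL to skip writing).
#' @param fold_threshold DE fold threshold (default 1.2).
#' @param top_fraction Discovery top-set cutoff (default 0.90).
#' @param cfg_cutoff Combined-score carry-forward cutoff (default 6).
#' @param cfg_top_external Long-list external-CFG cutoff (default 8).
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param min_cases Minimum stratum cases/controls (default 2).
#' @return List: discovery, cfg, validation, long_list, predictions, cfe,
#'   report.
#' @export
run_pipeline <- function(discovery, validation, testing, evidence, probe2gene,
                         out_dir = NULL, fold_threshold = 1.2,
                         top_fraction = 0.90, cfg_cutoff = 6,
                         cfg_top_external = 8, alpha = 0.05, min_cases = 2) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie strictly between 0 and 1")
  }
  report <- list()
  note <- function(fmt, ...) {
    report[[length(report) + 1]] <<- sprintf(fmt, ...)
    message(sprintf(fmt, ...))
  }

  note("discovery: %d subjects, %d samples, %d probesets",
       length(unique(discovery$visits$subject_id)), nrow(discovery$visits),
       length(discovery$bundle$probeset_ids))
  disc <- discovery_table(discovery$bundle, discovery$visits,
                          fold_threshold, top_fraction)
  best <- best_discovery(disc)
  note("discovery: %d probesets with internal points > 0, %d in top set",
       sum(best$points > 0), sum(best$top_flag))

  cfg_tab <- cfg_table(disc, evidence, probe2gene, cutoff = cfg_cutoff)
  note("prioritization: %d candidates at combined score >= %d",
       sum(cfg_tab$carry_forward), cfg_cutoff)

  cand <- cfg_tab[cfg_tab$carry_forward & !is.na(cfg_tab$direction),
                  c("probeset_id", "direction", "method")]
  dropped <- sum(cfg_tab$carry_forward) - nrow(cand)
  if (dropped > 0) note("validation: %d un-directed candidate(s) dropped", dropped)
  val_tab <- validation_table(cand, discovery$bundle, discovery$visits,
                              validation$bundle, validation$visits,
                              alpha = alpha)
  note("validation: %d candidates tested; %d stepwise, %d nominal, %d Bonferroni",
       nrow(val_tab), sum(val_tab$stepwise), sum(val_tab$points >= 4),
       sum(val_tab$points == 6))

  discovery_top <- best$probeset_id[best$top_flag & !is.na(best$direction)]
  cfg_top <- cfg_tab$probeset_id[cfg_tab$external >= cfg_top_external &
                                   !is.na(cfg_tab$direction)]
  validated_nominal <- val_tab$probeset_id[val_tab$points >= 4]
  long_list <- assemble_long_list(discovery_top, cfg_top, validated_nominal)
  note("long list: %d probesets (%d discovery top + %d CFG top + %d validated)",
       length(long_list), length(discovery_top), length(cfg_top),
       length(validated_nominal))

  markers <- data.frame(probeset_id = long_list,
                        direction = best$direction[match(long_list,
                                                         best$probeset_id)],
                        stringsAsFactors = FALSE)
  markers <- markers[!is.na(markers$direction), ]
  panels <- list(panel_long = markers$probeset_id)
  short <- intersect(validated_nominal, markers$probeset_id)
  if (length(short) > 1) panels$panel_short <- short
  note("testing: %d markers, %d panel(s), %d test samples",
       nrow(markers), length(panels), nrow(testing$visits))
  predictions <- stratified_run(markers, testing$bundle, testing$visits,
                                testing$followup, panels = panels,
                                alpha = alpha, min_cases = min_cases)
  note("testing: %d result rows (%d significant, %d skipped strata)",
       nrow(predictions), sum(predictions$significant), sum(predictions$skipped))

  cfe <- cfe_table(markers$probeset_id, disc, cfg_tab, val_tab, predictions)
  note("CFE: top marker %s with %d points", cfe$probeset_id[1], cfe$total[1])

  out <- list(discovery = disc, cfg = cfg_tab, validation = val_tab,
              long_list = long_list, predictions = predictions, cfe = cfe,
              report = unlist(report))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(disc, file.path(out_dir, "discovery.tsv"))
    write_tsv(cfg_tab, file.path(out_dir, "cfg.tsv"))
    write_tsv(val_tab, file.path(out_dir, "validation.tsv"))
    write_tsv(predictions, file.path(out_dir, "predictions.tsv"))
    write_tsv(cfe, file.path(out_dir, "cfe.tsv"))
    writeLines(out$report, file.path(out_dir, "run_report.txt"))
  }
  out
}
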