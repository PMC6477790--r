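# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# whatever state the caller had. Keeps every generator reproducible without
# clobbering the user's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stop() with sprintf-style formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x > 0 && x == round(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x <= 1

#' Diagnosis codes used throughout the pipeline
#'
#' The seven psychiatric diagnosis codes carried on visit records: bipolar
#' (BP), depression (MDD), schizophrenia (SZ), schizoaffective (SZA),
#' post-traumatic stress disorder (PTSD), psychosis not otherwise specified
#' (PSYCH), and mood disorder not otherwise specified (MOOD). The derived
#' PSYCHOSIS stratum used in testing pools SZ and SZA.
#'
#' @return Character vector of diagnosis codes.
#' @export
diagnosis_codes <- function() c("BP", "MDD", "SZ", "SZA", "PTSD", "PSYCH", "MOOD")

# Sample key convention: one column of the expression matrices per testing
# visit, keyed subjectID_visitID.
sample_key <- function(subject_id, visit_id) paste(subject_id, visit_id, sep = "_")
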