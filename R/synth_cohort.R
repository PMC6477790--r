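# Synthetic cohort generator: visit phenotypes, expression bundle with planted
# markers, emergency-department follow-up, and literature-evidence fixtures.
# Stands in for the microarray cohorts the pipeline was designed around, so
# every downstream step can be exercised and its operating characteristics
# measured against known ground truth.

#' Simulation configuration for synthetic pain cohorts
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate the
#' study design the pipeline targets: a longitudinal psychiatric cohort with
#' 2-5 testing visits per subject roughly 3-6 months apart, about one third
#' female, a diagnosis mix dominated by bipolar disorder and the psychosis
#' spectrum, and pain self-reported on a 0-10 visual analog scale (VAS) that
#' swings within subject between Low Pain (VAS 0-2) and High Pain (VAS 6-10)
#' blocks.
#'
#' Expression is simulated on the log2 scale as
#' `N(baseline_log2 + shift, noise_sd)` and exponentiated to the linear scale
#' microarray intensities are reported on. Planted "algogenes" are
#' `effect_size * noise_sd` log2 units higher in High Pain visits than in Low
#' Pain visits (the shift applied symmetrically around baseline) and planted
#' "pain suppressor" genes are the same amount lower; all other probesets are
#' null.
#' Detection calls are derived from the log2 intensity by two thresholds
#' (Absent below `baseline_log2 - 1`, Present above `baseline_log2`, Marginal
#' between).
#'
#' A per-subject trait liability `t ~ N(0,1)` multiplies the
#' emergency-department (ED) pain-visit rate by `exp(trait_hazard_beta * t)`
#' and is carried into planted-marker expression with oriented loading
#' `trait_load * noise_sd`, so planted markers predict future ED visits as
#' well as pain state.
#'
#' @param n_subjects Number of subjects.
#' @param visits_per_subject Integer vector of admissible visit counts,
#'   sampled uniformly per subject (1-6; discovery cohorts require >= 2).
#' @param p_female Probability a subject is female.
#' @param diagnosis_weights Named non-negative weights over
#'   [diagnosis_codes()]; normalised to sum to 1.
#' @param n_probesets Total probesets on the synthetic array.
#' @param n_algogenes,n_suppressors Planted increased / decreased probesets.
#' @param effect_size Standardised log2 mean shift (in units of `noise_sd`)
#'   between Low and High Pain states for planted markers. Must be >= 0.
#' @param severe_shift_mult Multiplier on the planted shift for clinically
#'   severe visits (>= 1), planting the Low < High < Severe gradient the
#'   validation step looks for.
#' @param noise_sd Residual log2-intensity standard deviation.
#' @param baseline_log2 Location of null log2 intensities.
#' @param trait_load Subject-level trait loading of planted markers, in units
#'   of `noise_sd`.
#' @param trait_hazard_beta Log hazard ratio of ED pain visits per unit of
#'   subject trait liability.
#' @param base_ed_rate Baseline ED pain-visit rate per day at trait liability
#'   0 (default ~0.22 probability of an event within a year).
#' @param followup_days Nominal electronic-record follow-up window (days);
#'   individual subjects get 0.8-1.2 times this.
#' @param p_severe_high Probability that a High Pain visit also meets the
#'   clinically severe criterion (SF-36 item 21 + item 22 >= 10).
#' @param seed Integer seed; identical configs and seeds give identical
#'   cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(n_subjects = 50,
                       visits_per_subject = 2:5,
                       p_female = 9 / 28,
                       diagnosis_weights = c(BP = 9, MDD = 3, SZ = 3, SZA = 6,
                                             PTSD = 5, PSYCH = 2, MOOD = 0) / 28,
                       n_probesets = 1000,
                       n_algogenes = 25,
                       n_suppressors = 25,
                       effect_size = 2,
                       severe_shift_mult = 1.5,
                       noise_sd = 0.5,
                       baseline_log2 = 7,
                       trait_load = 1,
                       trait_hazard_beta = 0.5,
                       base_ed_rate = 6.8e-4,
                       followup_days = 2030,
                       p_severe_high = 0.3,
                       seed = 1) {
  cfg <- list(
    n_subjects = n_subjects, visits_per_subject = as.integer(visits_per_subject),
    p_female = p_female, diagnosis_weights = diagnosis_weights,
    n_probesets = n_probesets, n_algogenes = n_algogenes,
    n_suppressors = n_suppressors, effect_size = effect_size,
    severe_shift_mult = severe_shift_mult,
    noise_sd = noise_sd, baseline_log2 = baseline_log2,
    trait_load = trait_load, trait_hazard_beta = trait_hazard_beta,
    base_ed_rate = base_ed_rate, followup_days = followup_days,
    p_severe_high = p_severe_high, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  for (f in c("n_subjects", "n_probesets")) {
    if (!is_count(cfg[[f]])) abort("sim_config$%s must be a positive count", f)
  }
  v <- cfg$visits_per_subject
  if (length(v) < 1 || any(v < 1 | v > 6 | v != round(v))) {
    abort("visits_per_subject must be integers in 1..6")
  }
  if (!is_prob(cfg$p_female)) abort("p_female must be a probability")
  if (!is_prob(cfg$p_severe_high)) abort("p_severe_high must be a probability")
  dw <- cfg$diagnosis_weights
  if (is.null(names(dw)) || !all(names(dw) %in% diagnosis_codes()) ||
      any(dw < 0) || sum(dw) <= 0) {
    abort("diagnosis_weights must be named non-negative weights over diagnosis_codes()")
  }
  if (abs(sum(dw) - 1) > 1e-8) {
    abort("diagnosis_weights must sum to 1")
  }
  for (f in c("n_algogenes", "n_suppressors")) {
    x <- cfg[[f]]
    if (!is.numeric(x) || length(x) != 1 || x < 0 || x != round(x)) {
      abort("sim_config$%s must be a non-negative integer", f)
    }
  }
  if (cfg$n_algogenes + cfg$n_suppressors > cfg$n_probesets) {
    abort("n_algogenes + n_suppressors must not exceed n_probesets")
  }
  if (!is.numeric(cfg$effect_size) || cfg$effect_size < 0) {
    abort("effect_size must be >= 0")
  }
  if (!is.numeric(cfg$severe_shift_mult) || cfg$severe_shift_mult < 1) {
    abort("severe_shift_mult must be >= 1")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be positive")
  if (cfg$base_ed_rate < 0) abort("base_ed_rate must be >= 0")
  if (cfg$followup_days < 1) abort("followup_days must be >= 1 day")
  invisible(cfg)
}

# Deterministic per-role seed offsets so discovery/validation/test cohorts
# generated from one config are independent but individually reproducible.
role_seed <- function(cfg, role) {
  cfg$seed + c(discovery = 0L, validation = 100003L, test = 200003L)[[role]]
}

# SF-36 pain items (21: intensity 1-6, 22: interference 1-5). "Severe" rows
# are drawn so item21 + item22 >= 10; all other combinations stay below 10.
draw_sf36 <- function(band) {
  switch(band,
    low = c(sample(1:2, 1), sample(1:2, 1)),
    mid = c(sample(2:4, 1), sample(2:4, 1)),
    severe = {
      i21 <- sample(5:6, 1)
      i22 <- if (i21 == 5L) 5L else sample(4:5, 1)
      c(i21, i22)
    }
  )
}

generate_visits <- function(cfg, role = c("discovery", "validation", "test")) {
  role <- match.arg(role)
  if (role == "discovery" && min(cfg$visits_per_subject) < 2) {
    abort("discovery cohorts need >= 2 visits per subject so a diametric Low/High change can exist")
  }
  n <- cfg$n_subjects
  subject_id <- sprintf("S%03d", seq_len(n))
  gender <- sample(c("F", "M"), n, replace = TRUE,
                   prob = c(cfg$p_female, 1 - cfg$p_female))
  dw <- cfg$diagnosis_weights
  diagnosis <- sample(names(dw), n, replace = TRUE, prob = dw)
  n_visits <- if (length(cfg$visits_per_subject) == 1) {
    rep(cfg$visits_per_subject, n)
  } else {
    sample(cfg$visits_per_subject, n, replace = TRUE)
  }

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- n_visits[i]
    day <- cumsum(c(0, sample(90:180, v - 1, replace = TRUE)))
    vas <- switch(role,
      discovery = {
        # alternating Low/High blocks guarantee >= 1 diametric change
        states <- rep(if (runif(1) < 0.5) c("Low", "High") else c("High", "Low"),
                      length.out = v)
        ifelse(states == "Low", sample(0:2, v, replace = TRUE),
               sample(6:10, v, replace = TRUE))
      },
      validation = sample(6:10, v, replace = TRUE),
      # test visits span the full scale, ~27% High Pain
      test = sample(0:10, v, replace = TRUE,
                    prob = c(2, 2, 2, 1.5, 1.5, 1.5, 1, 1, 1, 1, 1))
    )
    band <- ifelse(vas <= 2, "low", ifelse(vas >= 6, "high", "mid"))
    sf <- t(vapply(seq_len(v), function(k) {
      if (band[k] == "high") {
        severe <- role == "validation" || runif(1) < cfg$p_severe_high
        draw_sf36(if (severe) "severe" else "mid")
      } else draw_sf36(band[k])
    }, integer(2)))
    rows[[i]] <- data.frame(
      subject_id = subject_id[i],
      visit_id = sprintf("V%d", seq_len(v)),
      day = day,
      gender = gender[i],
      diagnosis = diagnosis[i],
      pain_vas = as.integer(vas),
      sf36_21 = sf[, 1],
      sf36_22 = sf[, 2],
      stringsAsFactors = FALSE
    )
  }
  visits <- do.call(rbind, rows)
  visits$sample_id <- sample_key(visits$subject_id, visits$visit_id)
  rownames(visits) <- NULL
  visits
}

#' Probeset truth table for a simulated array
#'
#' The planted-marker key: probeset identifiers, their 1:1 synthetic gene
#' symbols, the planted role (`algogene`, increased in High Pain;
#' `suppressor`, decreased; or `null`), and whether the probeset carries the
#' subject-level trait (ED-visit risk) component. Planted markers occupy the
#' first rows of the array.
#'
#' @param cfg A [sim_config()].
#' @return data.frame with columns probeset_id, gene_symbol, role, trait,
#'   direction (`I`/`D` for planted probesets, `NA` for nulls).
#' @export
probe_truth <- function(cfg) {
  p <- cfg$n_probesets
  role <- rep("null", p)
  if (cfg$n_algogenes > 0) role[seq_len(cfg$n_algogenes)] <- "algogene"
  if (cfg$n_suppressors > 0) {
    role[cfg$n_algogenes + seq_len(cfg$n_suppressors)] <- "suppressor"
  }
  data.frame(
    probeset_id = sprintf("PS%05d", seq_len(p)),
    gene_symbol = sprintf("GENE%05d", seq_len(p)),
    role = role,
    trait = role != "null",
    direction = ifelse(role == "algogene", "I",
                       ifelse(role == "suppressor", "D", NA_character_)),
    stringsAsFactors = FALSE
  )
}

generate_expression <- function(visits, cfg, trait_liability) {
  truth <- probe_truth(cfg)
  p <- cfg$n_probesets
  s <- nrow(visits)
  log2mat <- matrix(stats::rnorm(p * s, cfg$baseline_log2, cfg$noise_sd), p, s)

  sign_dir <- ifelse(truth$role == "algogene", 1,
                     ifelse(truth$role == "suppressor", -1, 0))
  planted <- sign_dir != 0
  if (any(planted)) {
    # The planted state shift is applied symmetrically around baseline
    # (-shift/2 in Low Pain, +shift/2 in High Pain), so the High - Low
    # difference is exactly effect_size * noise_sd while large effects can
    # cross both detection-call thresholds (turning genes "off" in Low and
    # "on" in High). Clinically severe visits sit (severe_shift_mult - 1) *
    # shift above plain High Pain, planting the Low < High < Severe gradient
    # the validation step tests for.
    shift <- cfg$effect_size * cfg$noise_sd
    col_shift <- ifelse(visits$pain_vas <= 2, -shift / 2,
                        ifelse(visits$pain_vas >= 6,
                               shift / 2 + (cfg$severe_shift_mult - 1) * shift *
                                 clinically_severe(visits), 0))
    if (any(col_shift != 0)) {
      log2mat[planted, ] <- log2mat[planted, ] +
        outer(sign_dir[planted], col_shift)
    }
    tl <- trait_liability[visits$subject_id]
    log2mat[planted, ] <- log2mat[planted, ] +
      outer(sign_dir[planted] * cfg$trait_load * cfg$noise_sd, tl)
  }

  calls <- matrix("M", p, s)
  calls[log2mat < cfg$baseline_log2 - 1] <- "A"
  calls[log2mat > cfg$baseline_log2] <- "P"

  bundle <- expression_bundle(
    intensity = 2^log2mat, calls = calls,
    probeset_ids = truth$probeset_id, sample_ids = visits$sample_id
  )
  list(bundle = bundle, truth = truth)
}

#' Construct a paired intensity / detection-call expression bundle
#'
#' Container for the two matrices the pipeline consumes: linear-scale
#' intensities and Absent/Marginal/Present detection calls, probesets in rows
#' and visit samples in columns.
#'
#' @param intensity Non-negative numeric matrix, probesets x samples.
#' @param calls Character matrix of "A"/"M"/"P", same shape.
#' @param probeset_ids,sample_ids Row / column identifiers.
#' @return An `expression_bundle` list with named, dimension-checked members.
#' @export
expression_bundle <- function(intensity, calls, probeset_ids, sample_ids) {
  intensity <- as.matrix(intensity)
  calls <- as.matrix(calls)
  if (!identical(dim(intensity), dim(calls))) {
    abort("intensity and calls matrices must share dimensions")
  }
  if (length(probeset_ids) != nrow(intensity)) abort("probeset_ids length mismatch")
  if (length(sample_ids) != ncol(intensity)) abort("sample_ids length mismatch")
  if (any(intensity < 0, na.rm = TRUE)) abort("intensities must be non-negative")
  bad <- setdiff(unique(as.vector(calls)), c("A", "M", "P"))
  if (length(bad)) abort("invalid detection call(s): %s", paste(bad, collapse = ", "))
  dimnames(intensity) <- dimnames(calls) <- list(probeset_ids, sample_ids)
  structure(list(probeset_ids = probeset_ids, sample_ids = sample_ids,
                 intensity = intensity, calls = calls),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("<expression_bundle> %d probesets x %d samples\n",
              length(x$probeset_ids), length(x$sample_ids)))
  invisible(x)
}

generate_followup <- function(visits, cfg, trait_liability) {
  per_subj <- visits[!duplicated(visits$subject_id), c("subject_id"), drop = FALSE]
  idx_day <- tapply(visits$day, visits$subject_id, max)
  per_subj$index_visit_day <- as.numeric(idx_day[per_subj$subject_id])
  n <- nrow(per_subj)
  last_note <- round(stats::runif(n, 0.8, 1.2) * cfg$followup_days)
  rate <- cfg$base_ed_rate *
    exp(cfg$trait_hazard_beta * trait_liability[per_subj$subject_id])
  events <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, rate[i] * last_note[i])
    if (k == 0) integer(0) else sort(sample.int(last_note[i], k, replace = TRUE))
  })
  per_subj$ed_pain_event_days <- I(events)
  per_subj$last_note_day <- last_note
  rownames(per_subj) <- NULL
  per_subj
}

#' Generate a full synthetic cohort
#'
#' Draws subjects, visits, phenotypes, expression, and ED follow-up from a
#' [sim_config()]. Three cohort roles mirror the pipeline's stages:
#' `"discovery"` guarantees every subject at least one Low Pain (VAS <= 2)
#' and one High Pain (VAS >= 6) visit via alternating pain blocks;
#' `"validation"` is uniformly clinically severe (VAS >= 6 and
#' SF-36 item21 + item22 >= 10); `"test"` spans the full VAS range including
#' intermediate visits. The same config and seed always reproduce the same
#' cohort.
#'
#' @param cfg A [sim_config()].
#' @param role One of "discovery", "validation", "test".
#' @return List with `visits` (one row per testing visit), `bundle`
#'   ([expression_bundle()]), `followup` (one row per subject: index visit
#'   day, ED pain-event day offsets after index, last-note day offset), and
#'   `truth` (the planted-marker key, see [probe_truth()]).
#' @export
generate_cohort <- function(cfg, role = c("discovery", "validation", "test")) {
  role <- match.arg(role)
  validate_sim_config(cfg)
  with_seed(role_seed(cfg, role), {
    visits <- generate_visits(cfg, role)
    subj <- unique(visits$subject_id)
    trait_liability <- stats::setNames(stats::rnorm(length(subj)), subj)
    expr <- generate_expression(visits, cfg, trait_liability)
    followup <- generate_followup(visits, cfg, trait_liability)
    list(visits = visits, bundle = expr$bundle, followup = followup,
         truth = expr$truth)
  })
}

#' Deterministic discovery-design visit table
#'
#' A fixed 28-subject longitudinal cohort reproducing the discovery design the
#' pipeline assumes: three subjects with five visits, one with four, twelve
#' with three, and twelve with two (79 visits in all), 19 males and 9 females,
#' diagnosis counts BP 9, MDD 3, SZA 6, SZ 3, PTSD 5, PSYCH 2. Every subject
#' alternates Low Pain and High Pain visits, so each has at least one
#' diametric change. No randomness: repeated calls are identical.
#'
#' @return Visit table in the same format as `generate_cohort()$visits`.
#' @export
cohort_fixture <- function() {
  n_visits <- c(rep(5L, 3), 4L, rep(3L, 12), rep(2L, 12))
  n <- length(n_visits)  # 28 subjects, 79 visits
  gender <- rep("M", n)
  gender[seq(1, n, by = 3)[1:9]] <- "F"  # 9 F interleaved, 19 M
  diagnosis <- rep(c("BP", "SZA", "PTSD", "MDD", "SZ", "PSYCH"),
                   times = c(9, 6, 5, 3, 3, 2))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- n_visits[i]
    states <- rep(if (i %% 2 == 1) c("Low", "High") else c("High", "Low"),
                  length.out = v)
    k <- seq_len(v)
    vas <- ifelse(states == "Low", (i + k) %% 3, 6 + (i + k) %% 5)
    severe <- vas >= 6 & (i %% 3 == 0)
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%03d", i),
      visit_id = sprintf("V%d", k),
      day = (k - 1) * 120,
      gender = gender[i],
      diagnosis = diagnosis[i],
      pain_vas = as.integer(vas),
      sf36_21 = ifelse(vas <= 2, 1L, ifelse(severe, 5L, 4L)),
      sf36_22 = ifelse(vas <= 2, 1L, ifelse(severe, 5L, 4L)),
      stringsAsFactors = FALSE
    )
  }
  visits <- do.call(rbind, rows)
  visits$sample_id <- sample_key(visits$subject_id, visits$visit_id)
  rownames(visits) <- NULL
  visits
}

#' Full cohort on the fixed discovery design
#'
#' Combines the deterministic [cohort_fixture()] visit table with simulated
#' expression, follow-up, and planted-marker truth drawn under a
#' [sim_config()]'s array parameters (the subject count comes from the
#' fixture, not the config).
#'
#' @param cfg A [sim_config()]; its seed makes the result reproducible.
#' @return A cohort list like [generate_cohort()]'s.
#' @export
fixture_cohort <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  visits <- cohort_fixture()
  with_seed(cfg$seed, {
    subj <- unique(visits$subject_id)
    tl <- stats::setNames(stats::rnorm(length(subj)), subj)
    expr <- generate_expression(visits, cfg, tl)
    followup <- generate_followup(visits, cfg, tl)
    list(visits = visits, bundle = expr$bundle, followup = followup,
         truth = expr$truth)
  })
}

#' The six literature-evidence categories feeding the external CFG score
#'
#' Human and non-human evidence, each split into genetic, nervous-tissue, and
#' peripheral tissue/fluid study types.
#'
#' @return Character vector of the six category codes.
#' @export
evidence_categories <- function() {
  c("human_genetic", "human_nervous", "human_peripheral",
    "nonhuman_genetic", "nonhuman_nervous", "nonhuman_peripheral")
}

#' Deterministic literature-evidence fixture
#'
#' A synthetic evidence table with the canonical per-category citation counts
#' of the curated pain databases the external CFG score draws on: 212 human
#' genetic, 3 human nervous tissue, 57 human peripheral tissue/fluid, 26
#' non-human genetic, 48 non-human nervous tissue, and 9 non-human peripheral
#' studies (355 in total), distributed round-robin over synthetic gene
#' symbols.
#'
#' @param gene_symbols Character vector of gene symbols to spread the
#'   citations over (default 60 synthetic symbols).
#' @return data.frame with columns gene_symbol, category, citation_tag.
#' @export
evidence_fixture <- function(gene_symbols = sprintf("GENE%05d", 1:60)) {
  counts <- c(human_genetic = 212L, human_nervous = 3L, human_peripheral = 57L,
              nonhuman_genetic = 26L, nonhuman_nervous = 48L,
              nonhuman_peripheral = 9L)
  rows <- lapply(names(counts), function(cat) {
    k <- counts[[cat]]
    data.frame(
      gene_symbol = rep_len(gene_symbols, k),
      category = cat,
      citation_tag = sprintf("%s_ref%03d", cat, seq_len(k)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Generate a synthetic evidence table aligned with planted markers
#'
#' Gives planted markers a higher chance of prior literature evidence than
#' null genes, emulating the situation where some discovered biomarkers are
#' well known and others (the interesting novel ones) have none.
#'
#' @param truth A [probe_truth()] table.
#' @param seed Integer seed.
#' @param p_null_evidence Probability a null gene has any evidence.
#' @return Evidence table (gene_symbol, category, citation_tag).
#' @export
generate_evidence <- function(truth, seed = 1, p_null_evidence = 0.1) {
  cats <- evidence_categories()
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      planted <- truth$role[i] != "null"
      n_cat <- if (planted) {
        sample(0:6, 1, prob = c(2, 2, 2, 1.5, 1, 1, 0.5))
      } else if (stats::runif(1) < p_null_evidence) {
        sample(1:3, 1)
      } else 0L
      if (n_cat == 0) return(NULL)
      got <- sample(cats, n_cat)
      data.frame(gene_symbol = truth$gene_symbol[i], category = got,
                 citation_tag = sprintf("%s_%s", truth$gene_symbol[i], got),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(gene_symbol = character(), category = character(),
                        citation_tag = character(), stringsAsFactors = FALSE)
    }
    out
  })
}
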