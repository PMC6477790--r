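small_cfg <- function(seed = 7, ...) {
  sim_config(n_subjects = 20, n_probesets = 120, n_algogenes = 10,
             n_suppressors = 10, seed = seed, ...)
}

test_that("identical configs and seeds reproduce cohorts exactly", {
  a <- generate_cohort(small_cfg(), "discovery")
  b <- generate_cohort(small_cfg(), "discovery")
  expect_identical(a$visits, b$visits)
  expect_identical(a$bundle$intensity, b$bundle$intensity)
  expect_identical(a$bundle$calls, b$bundle$calls)
  expect_identical(a$followup, b$followup)
  c <- generate_cohort(small_cfg(seed = 8), "discovery")
  expect_false(identical(a$bundle$intensity, c$bundle$intensity))
})

test_that("cohort invariants hold: diametric changes, sample links, call alphabet", {
  for (role in c("discovery", "test")) {
    co <- generate_cohort(small_cfg(), role)
    expect_setequal(co$bundle$sample_ids, co$visits$sample_id)
    expect_true(all(co$bundle$intensity >= 0))
    expect_true(all(co$bundle$calls %in% c("A", "M", "P")))
    expect_true(all(co$visits$pain_vas >= 0 & co$visits$pain_vas <= 10))
    days_ok <- tapply(co$visits$day, co$visits$subject_id,
                      function(d) !is.unsorted(d))
    expect_true(all(days_ok))
  }
  disc <- generate_cohort(small_cfg(), "discovery")
  st <- split(label_pain_state(disc$visits$pain_vas), disc$visits$subject_id)
  expect_true(all(vapply(st, function(s) any(s == "Low") && any(s == "High"),
                         logical(1))))
  sev <- generate_cohort(small_cfg(), "validation")
  expect_true(all(clinically_severe(sev$visits)))
})

test_that("planted effect size is recovered by the pooled-SD standardized difference", {
  cfg <- sim_config(n_subjects = 50, n_probesets = 200, n_algogenes = 20,
                    n_suppressors = 20, effect_size = 1.5, noise_sd = 0.5,
                    trait_load = 0, seed = 11)
  co <- generate_cohort(cfg, "discovery")
  hi <- co$visits$pain_vas >= 6 & !clinically_severe(co$visits)
  lo <- co$visits$pain_vas <= 2
  lg <- log2(co$bundle$intensity)
  smd <- function(rows) {
    vapply(rows, function(i) {
      x <- lg[i, hi]; y <- lg[i, lo]
      sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                   (length(x) + length(y) - 2))
      (mean(x) - mean(y)) / sp
    }, numeric(1))
  }
  alg <- which(co$truth$role == "algogene")
  sup <- which(co$truth$role == "suppressor")
  nul <- which(co$truth$role == "null")
  expect_equal(mean(smd(alg)), 1.5, tolerance = 0.3 / 1.5)
  expect_equal(mean(smd(sup)), -1.5, tolerance = 0.3 / 1.5)
  expect_lt(abs(mean(smd(nul))), 0.15)
})

test_that("zero effect size leaves planted and null probesets indistinguishable", {
  cfg <- sim_config(n_subjects = 50, n_probesets = 200, n_algogenes = 20,
                    n_suppressors = 20, effect_size = 0, trait_load = 0,
                    seed = 12)
  co <- generate_cohort(cfg, "discovery")
  hi <- co$visits$pain_vas >= 6
  lo <- co$visits$pain_vas <= 2
  lg <- log2(co$bundle$intensity)
  d <- rowMeans(lg[, hi]) - rowMeans(lg[, lo])
  expect_lt(abs(mean(d[co$truth$role == "algogene"])), 0.1)
  expect_lt(abs(mean(d[co$truth$role == "algogene"]) -
                  mean(d[co$truth$role == "null"])), 0.1)
})

test_that("planted direction is sign-correct in nearly all replicates at effect >= 1", {
  correct <- total <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n_subjects = 20, n_probesets = 60, n_algogenes = 10,
                      n_suppressors = 10, effect_size = 1, trait_load = 0,
                      seed = seed)
    co <- generate_cohort(cfg, "discovery")
    hi <- co$visits$pain_vas >= 6
    lo <- co$visits$pain_vas <= 2
    lg <- log2(co$bundle$intensity)
    d <- rowMeans(lg[, hi]) - rowMeans(lg[, lo])
    planted <- co$truth$role != "null"
    sign_ok <- sign(d[planted]) == ifelse(co$truth$role[planted] == "algogene", 1, -1)
    correct <- correct + sum(sign_ok)
    total <- total + sum(planted)
  }
  expect_gte(correct / total, 0.95)
})

test_that("Present-call fraction is non-decreasing across intensity deciles", {
  co <- generate_cohort(small_cfg(), "discovery")
  dec <- cut(as.vector(co$bundle$intensity),
             stats::quantile(co$bundle$intensity, 0:10 / 10),
             include.lowest = TRUE, labels = FALSE)
  pfrac <- tapply(as.vector(co$bundle$calls) == "P", dec, mean)
  expect_true(all(diff(pfrac) >= 0))
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(n_probesets = 10, n_algogenes = 8, n_suppressors = 8),
               "exceed")
  expect_error(sim_config(diagnosis_weights = c(BP = 0.5, MDD = 0.2)), "sum to 1")
  expect_error(sim_config(p_female = 1.5), "probability")
  expect_error(generate_cohort(sim_config(visits_per_subject = 1), "discovery"),
               "diametric")
})

test_that("the fixed discovery-design cohort matches the published structure", {
  v <- cohort_fixture()
  expect_identical(v, cohort_fixture())  # deterministic
  expect_equal(length(unique(v$subject_id)), 28)
  expect_equal(nrow(v), 79)
  counts <- table(table(v$subject_id))
  expect_equal(as.integer(counts[c("2", "3", "4", "5")]), c(12L, 12L, 1L, 3L))
  g <- table(v$gender[!duplicated(v$subject_id)])
  expect_equal(as.integer(g[c("M", "F")]), c(19L, 9L))
  dx <- table(v$diagnosis[!duplicated(v$subject_id)])
  expect_equal(as.integer(dx[c("BP", "MDD", "SZA", "SZ", "PTSD", "PSYCH")]),
               c(9L, 3L, 6L, 3L, 5L, 2L))
  st <- split(label_pain_state(v$pain_vas), v$subject_id)
  expect_true(all(vapply(st, function(s) any(s == "Low") && any(s == "High"),
                         logical(1))))
})

test_that("evidence fixture reproduces the curated per-category citation counts", {
  ev <- evidence_fixture()
  expect_equal(nrow(ev), 355)
  counts <- table(ev$category)
  expect_equal(as.integer(counts[c("human_genetic", "human_nervous",
                                   "human_peripheral", "nonhuman_genetic",
                                   "nonhuman_nervous", "nonhuman_peripheral")]),
               c(212L, 3L, 57L, 26L, 48L, 9L))
  empty <- ev[0, ]
  expect_equal(unname(cfg_external_score(c("GENE00001", "GENE00002"), empty)),
               c(0, 0))
})

test_that("ED event hazards increase with planted trait liability", {
  cfg <- sim_config(n_subjects = 300, n_probesets = 60, n_algogenes = 10,
                    n_suppressors = 10, effect_size = 0, trait_hazard_beta = 0.5,
                    seed = 5)
  co <- generate_cohort(cfg, "test")
  n_ev <- vapply(co$followup$ed_pain_event_days, length, numeric(1))
  # recover liability from the planted-marker panel at subject level
  lg <- log2(co$bundle$intensity)
  ori <- ifelse(co$truth$role == "algogene", 1, -1)
  planted <- co$truth$role != "null"
  subj_score <- tapply(colMeans(lg[planted, ] * ori[planted]),
                       co$visits$subject_id, mean)
  subj_score <- subj_score[co$followup$subject_id]
  expect_gt(cor(as.numeric(subj_score), n_ev, method = "spearman"), 0.2)
})
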