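test_that("risk-oriented composite sums increased minus decreased markers", {
  expect_equal(risk_oriented_score(1.5, "I"), 1.5)
  expect_equal(risk_oriented_score(1.5, "D"), -1.5)
  expect_equal(risk_oriented_score(matrix(c(1, 1), 2), c("I", "D")), 0)
  expect_equal(risk_oriented_score(matrix(c(0.5, -0.2, 1.0), 3), c("I", "I", "D")),
               -0.7)
  # orientation invariance: negating a D marker and flipping its label
  z <- matrix(rnorm(20), 2)
  expect_equal(risk_oriented_score(z, c("I", "D")),
               risk_oriented_score(rbind(z[1, ], -z[2, ]), c("I", "I")))
  expect_error(risk_oriented_score(z, c("I", "X")), "'I' or 'D'")
})

test_that("longitudinal features capture last/max levels and slopes", {
  f1 <- longitudinal_features(0.4, 0)
  expect_equal(unlist(f1), c(last_level = 0.4, max_level = 0.4,
                             last_slope = 0, max_slope = 0))
  f2 <- longitudinal_features(c(0, 1), c(0, 100))
  expect_equal(f2$last_slope, 0.01)
  expect_equal(f2$max_slope, 0.01)
  f3 <- longitudinal_features(c(0.3, 0.3, 0.3), c(0, 50, 120))
  expect_equal(f3$last_level, f3$max_level)
  expect_equal(f3$max_slope, 0)
  f4 <- longitudinal_features(c(0, 2, 1), c(0, 10, 20))
  expect_equal(f4$max_slope, 0.2)
  expect_equal(f4$last_slope, -0.1)
  expect_equal(f4$max_level, 2)
  expect_error(longitudinal_features(c(0, 1), c(10, 10)), "strictly increasing")
})

test_that("ROC AUC equals brute-force pair counting, including ties", {
  expect_equal(roc_auc(c(3, 2, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  expect_equal(brute_force_auc(c(3, 2, 1, 2.5), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  all_tied <- roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(all_tied$auc, 0.5)
  expect_equal(all_tied$p, 1)
  set.seed(1)
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    scores <- sample(c(rnorm(n), round(rnorm(n), 1)), n)  # ties likely
    cases <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(cases) || all(cases)) next
    expect_equal(roc_auc(scores, cases)$auc, brute_force_auc(scores, cases))
  }
})

test_that("AUC and its one-sided p agree with independent implementations", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (rep in 1:10) {
    n <- 40
    cases <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.4, 0.6))
    if (!any(cases) || all(cases)) next
    # coarse score grid guarantees ties, so wilcox.test uses the same
    # tie-corrected normal approximation rather than the exact distribution
    scores <- sample(seq(-2, 2, by = 0.5), n, TRUE) + cases
    got <- roc_auc(scores, cases)
    expect_equal(got$auc,
                 as.numeric(pROC::auc(pROC::roc(cases, scores, quiet = TRUE,
                                                direction = "<"))))
    # wilcox.test with ties uses the same tie-corrected normal approximation
    wt <- suppressWarnings(stats::wilcox.test(scores[cases], scores[!cases],
                                              alternative = "greater"))
    expect_equal(got$p, wt$p.value, tolerance = 1e-8)
  }
})

test_that("single-class inputs are untestable rather than scored", {
  got <- roc_auc(1:5, rep(TRUE, 5))
  expect_true(is.na(got$auc))
  ot <- or_test(1:5, rep(FALSE, 5))
  expect_true(is.na(ot$or))
})

test_that("a planted state marker separates High Pain visits; permuted labels do not", {
  set.seed(3)
  n <- 200
  cases <- rep(c(TRUE, FALSE), each = n / 2)
  scores <- rnorm(n) + 1.5 * cases
  vas <- pmin(10, pmax(0, round(2 + 6 * cases + rnorm(n))))
  st <- state_tests(scores, cases, vas)
  expect_gt(st$auc, 0.7)
  expect_lt(st$auc_p, 0.05)
  expect_lt(st$t_p, 0.05)
  expect_gt(st$r, 0)
  expect_lt(st$r_p, 0.05)
  # label permutation null: AUC centred at 0.5
  aucs <- replicate(200, roc_auc(scores, sample(cases))$auc)
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("first-year trait cases respect the 365-day boundary and censoring", {
  scores <- c(2, 1.5, 0.3, -0.5, -1, 0.8, -0.2, 1.1, 0.1, -1.4)
  days_to_first <- c(100, 200, 400, Inf, Inf, 50, Inf, 300, Inf, Inf)
  fdays <- rep(800, 10)
  res <- trait_year1_tests(scores, days_to_first, fdays, (days_to_first < 800) * 1)
  # an event at day 400 is not a first-year case; it is censored at 365
  expect_equal(res$n_cases, 4L)
  expect_equal(res$n_total, 10L)
  # visits with under a year of possible follow-up are excluded
  fdays2 <- c(rep(800, 9), 100)
  res2 <- trait_year1_tests(scores, days_to_first, fdays2, rep(0, 10))
  expect_equal(res2$n_total, 9L)
})

test_that("all-years trait analysis recovers null and planted odds ratios", {
  set.seed(4)
  n <- 500
  z <- rnorm(n)
  null_cases <- runif(n) < 0.3
  ot <- or_test(z, null_cases)
  expect_lt(abs(ot$log_or), 0.3)
  # planted log-OR 0.3 per z unit
  est <- vapply(1:5, function(i) {
    zz <- rnorm(400)
    cc <- runif(400) < stats::plogis(-0.5 + 0.3 * zz)
    or_test(zz, cc)$log_or
  }, numeric(1))
  expect_equal(mean(est), 0.3, tolerance = 0.15 / 0.3)
})

test_that("Cox regression is near-null for independent markers and oriented to risk", {
  set.seed(5)
  n <- 400
  z <- rnorm(n)
  time <- rexp(n, 1 / 300)
  event <- time < 365
  cx <- cox_hr(pmin(time, 365), event, z)
  expect_lt(abs(cx$log_hr), 0.25)
  expect_true(abs(cx$log_hr) < 1.96 * cx$se)  # CI covers the null
  # a protective marker, once oriented, reports HR > 1
  risky <- rexp(n, exp(0.6 * z) / 300)
  cxp <- cox_hr(pmin(risky, 365), risky < 365, risk_oriented_score(-z, "D"))
  expect_gt(cxp$hr, 1)
})

test_that("first-year cases are a subset of all-years cases on generated cohorts", {
  cfg <- sim_config(n_subjects = 60, n_probesets = 20, n_algogenes = 2,
                    n_suppressors = 2, seed = 17)
  co <- generate_cohort(cfg, "test")
  fu <- painmarkers:::visit_followup(co$visits, co$followup)
  y1 <- fu$followup_days >= 365 & fu$days_to_first <= 365
  all_years <- is.finite(fu$days_to_first)
  expect_true(all(!y1 | all_years))
})

test_that("stratified runs cover all-subject rows, skip tiny strata, find planted effects", {
  set.seed(6)
  n <- 240
  visits <- data.frame(
    subject_id = sprintf("T%03d", seq_len(n)),
    visit_id = "V1", day = 0,
    gender = rep(c("F", "M"), each = n / 2),
    diagnosis = rep(c("BP", "MDD", "BP", "MDD"), each = n / 4),
    pain_vas = as.integer(rep(c(8, 1), n / 2)),
    sf36_21 = 3L, sf36_22 = 3L, stringsAsFactors = FALSE)
  visits$sample_id <- paste(visits$subject_id, visits$visit_id, sep = "_")
  # marker shifted in High Pain females only (effect 2 z units)
  high <- visits$pain_vas >= 6
  female <- visits$gender == "F"
  lg <- 7 + 0.5 * rnorm(n) + 1.0 * (high & female)
  bundle <- expression_bundle(matrix(2^lg, 1), matrix("P", 1, n),
                              "PS1", visits$sample_id)
  res <- stratified_run(data.frame(probeset_id = "PS1", direction = "I"),
                        bundle, visits, outcomes = "state",
                        modes = "cross_sectional")
  expect_true(any(res$stratum_level == "all"))
  f_row <- res[res$stratum == "F" & res$stratum_level == "gender", ]
  m_row <- res[res$stratum == "M" & res$stratum_level == "gender", ]
  expect_true(f_row$significant)
  expect_false(m_row$significant)
  # a stratum with no cases is reported as skipped, with the reason
  visits2 <- visits
  visits2$pain_vas[visits2$gender == "M"] <- 1L
  res2 <- stratified_run(data.frame(probeset_id = "PS1", direction = "I"),
                         bundle, visits2, outcomes = "state",
                         modes = "cross_sectional")
  m2 <- res2[res2$stratum == "M" & res2$stratum_level == "gender", ]
  expect_true(m2$skipped)
  expect_match(m2$reason, "below minimum")
})

test_that("longitudinal mode uses expanding visit histories from the second visit", {
  cfg <- sim_config(n_subjects = 40, n_probesets = 30, n_algogenes = 5,
                    n_suppressors = 5, seed = 19)
  co <- generate_cohort(cfg, "test")
  mk <- data.frame(probeset_id = co$truth$probeset_id[1], direction = "I")
  res <- stratified_run(mk, co$bundle, co$visits, co$followup,
                        outcomes = "state")
  cs <- res[res$mode == "cross_sectional" & res$stratum_level == "all", ]
  lg <- res[res$mode == "longitudinal" & res$stratum_level == "all", ]
  n_multi <- sum(table(co$visits$subject_id) - 1)
  expect_lte(lg$n_total, n_multi)
  expect_lt(lg$n_total, cs$n_total)
})
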