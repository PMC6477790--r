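test_that("pain-state labelling follows the VAS cutoffs inclusively", {
  expect_equal(label_pain_state(c(0, 2, 3, 5, 6, 10)),
               c("Low", "Low", "Intermediate", "Intermediate", "High", "High"))
  expect_error(label_pain_state(11), "0, 10")
  expect_error(label_pain_state(-1), "0, 10")
})

test_that("comparison enumeration yields all within-subject Low x High pairs", {
  v <- data.frame(
    subject_id = c("A", "A", "B", "B", "B", "B", "C", "C"),
    visit_id = c("V1", "V2", "V1", "V2", "V3", "V4", "V1", "V2"),
    pain_vas = c(1L, 8L, 0L, 2L, 7L, 9L, 4L, 5L),
    stringsAsFactors = FALSE)
  v$sample_id <- paste(v$subject_id, v$visit_id, sep = "_")
  cmp <- enumerate_comparisons(v)
  expect_equal(sum(cmp$subject_id == "A"), 1)   # 1 Low x 1 High
  expect_equal(sum(cmp$subject_id == "B"), 4)   # 2 Low x 2 High
  expect_equal(sum(cmp$subject_id == "C"), 0)   # intermediates only
  # exhaustive oracle: per subject, #Low * #High
  st <- label_pain_state(v$pain_vas)
  for (s in unique(v$subject_id)) {
    expect_equal(sum(cmp$subject_id == s),
                 sum(st == "Low" & v$subject_id == s) *
                   sum(st == "High" & v$subject_id == s))
  }
  expect_true(all(label_pain_state(v$pain_vas[match(cmp$low_sample,
                                                    v$sample_id)]) == "Low"))
  expect_true(all(label_pain_state(v$pain_vas[match(cmp$high_sample,
                                                    v$sample_id)]) == "High"))
})

test_that("detection calls encode as A=0, M=0.5, P=1 and reject anything else", {
  expect_equal(encode_ap(c("A", "M", "P")), c(0, 0.5, 1))
  m <- matrix(c("A", "P", "M", "P"), 2)
  expect_equal(encode_ap(m), matrix(c(0, 1, 0.5, 1), 2))
  expect_error(encode_ap("Q"), "unknown detection call")
})

test_that("concordance fractions map onto 0/2/4/6 points at 33/50/80 percent", {
  expect_equal(discovery_points(c(0, 0.3, 0.33, 1 / 3, 0.49, 0.5, 0.79, 0.8, 1)),
               c(0L, 0L, 2L, 2L, 2L, 4L, 4L, 6L, 6L))
  # monotone in the fraction
  f <- seq(0, 1, by = 0.01)
  expect_true(all(diff(discovery_points(f)) >= 0))
})

test_that("probeset scoring reproduces worked concordance examples", {
  # 10 subjects, one comparison each
  lo <- rbind(rep(10, 10),                      # P1: halves in all 10 -> D 1.0
              rep(10, 10),                      # P2: up 1.5x in 5, flat in 5
              rep(10, 10),                      # P3: up in 3 of 10 -> 0 pts
              c(0, rep(10, 9)),                 # P4: zero Low, nonzero High
              rep(10, 10))                      # P5: 5 up, 5 down -> tie
  hi <- rbind(rep(5, 10),
              c(rep(15, 5), rep(10, 5)),
              c(rep(15, 3), rep(10, 7)),
              c(5, rep(10, 9)),
              c(rep(15, 5), rep(5, 5)))
  co <- paired_cohort(lo, hi)
  cmp <- enumerate_comparisons(co$visits)
  s1 <- score_probeset("P001", cmp, co$bundle, "DE")
  expect_equal(c(s1$direction, s1$fraction, s1$points), c("D", 1, 6))
  s2 <- score_probeset("P002", cmp, co$bundle, "DE")
  expect_equal(c(s2$direction, s2$fraction, s2$points), c("I", 0.5, 4))
  expect_equal(score_probeset("P003", cmp, co$bundle, "DE")$points, 0L)
  # zero Low intensity with nonzero High counts as increased (ratio -> Inf)
  s4 <- score_probeset("P004", cmp, co$bundle, "DE")
  expect_equal(s4$fraction, 0.1)
  # exact direction tie scores zero and carries no direction
  s5 <- score_probeset("P005", cmp, co$bundle, "DE")
  expect_true(is.na(s5$direction))
  expect_equal(s5$points, 0L)

  # 4 concordant of 12 comparisons sits exactly on the 33% boundary
  co12 <- paired_cohort(matrix(10, 1, 12),
                        matrix(c(rep(15, 4), rep(10, 8)), 1))
  s <- score_probeset("P001", enumerate_comparisons(co12$visits), co12$bundle, "DE")
  expect_equal(s$points, 2L)
})

test_that("AP scoring counts only strict Absent/Present switches", {
  lo_c <- rbind(rep("A", 10),                       # A->P in all
                c(rep("P", 6), rep("M", 4)),        # P->A in 6
                rep("M", 10))                       # M never switches
  hi_c <- rbind(rep("P", 10),
                c(rep("A", 6), rep("M", 4)),
                rep("P", 10))
  co <- paired_cohort(matrix(10, 3, 10), matrix(10, 3, 10), lo_c, hi_c)
  cmp <- enumerate_comparisons(co$visits)
  s1 <- score_probeset("P001", cmp, co$bundle, "AP")
  expect_equal(c(s1$direction, s1$points), c("I", 6))
  s2 <- score_probeset("P002", cmp, co$bundle, "AP")
  expect_equal(c(s2$direction, s2$fraction), c("D", 0.6))
  expect_equal(score_probeset("P003", cmp, co$bundle, "AP")$points, 0L)
})

test_that("scoring matches the brute-force oracle on small random cohorts", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    p <- 8
    lo <- matrix(2^rnorm(p * n, 7, 1), p, n)
    hi <- matrix(2^rnorm(p * n, 7, 1), p, n)
    lo_c <- matrix(sample(c("A", "M", "P"), p * n, TRUE), p, n)
    hi_c <- matrix(sample(c("A", "M", "P"), p * n, TRUE), p, n)
    co <- paired_cohort(lo, hi, lo_c, hi_c)
    cmp <- enumerate_comparisons(co$visits)
    disc <- discovery_table(co$bundle, co$visits)
    for (i in seq_len(p)) {
      ps <- sprintf("P%03d", i)
      ora_de <- oracle_discovery(lo[i, ], hi[i, ], "DE")
      got_de <- disc[disc$probeset_id == ps & disc$method == "DE", ]
      expect_equal(got_de$fraction, ora_de$fraction)
      expect_equal(got_de$points, ora_de$points)
      expect_identical(got_de$direction, ora_de$direction)
      ora_ap <- oracle_discovery(lo_c[i, ], hi_c[i, ], "AP")
      got_ap <- disc[disc$probeset_id == ps & disc$method == "AP", ]
      expect_equal(got_ap$fraction, ora_ap$fraction)
      expect_equal(got_ap$points, ora_ap$points)
    }
  }
})

test_that("the top-set flag is inclusive at 90 percent concordance", {
  co <- paired_cohort(matrix(10, 1, 10), matrix(c(rep(15, 9), 10), 1))
  d <- discovery_table(co$bundle, co$visits)
  expect_true(d$top_flag[d$method == "DE"])      # 9/10 = 0.90
  co2 <- paired_cohort(matrix(10, 1, 9), matrix(c(rep(15, 8), 10), 1))
  d2 <- discovery_table(co2$bundle, co2$visits)
  expect_false(d2$top_flag[d2$method == "DE"])   # 8/9 = 0.889
})

test_that("planted markers are recovered with correct direction and points >= 4", {
  cfg <- sim_config(n_subjects = 25, n_probesets = 150, n_algogenes = 15,
                    n_suppressors = 15, effect_size = 2, seed = 21)
  co <- generate_cohort(cfg, "discovery")
  best <- best_discovery(discovery_table(co$bundle, co$visits))
  planted <- co$truth[co$truth$role != "null", ]
  got <- best[match(planted$probeset_id, best$probeset_id), ]
  ok <- got$points >= 4 & got$direction == planted$direction
  expect_gte(mean(ok), 0.9)
})

test_that("null probesets rarely reach a perfect concordance score", {
  cfg <- sim_config(n_subjects = 30, n_probesets = 400, n_algogenes = 0,
                    n_suppressors = 0, effect_size = 0, trait_load = 0,
                    seed = 31)
  co <- generate_cohort(cfg, "discovery")
  best <- best_discovery(discovery_table(co$bundle, co$visits, fold_threshold = 1.2))
  expect_lt(mean(best$points == 6), 0.05)
})
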