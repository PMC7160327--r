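test_that("classification follows the selection bands", {
  crit <- selection_criteria()
  s <- make_scored(3, best_dr_norm = c(-2, -2, 1.5),
                   min_all_norm = c(-2, -2, 1.5),
                   liberal_released = c(TRUE, TRUE, FALSE),
                   strict_eligible = c(FALSE, FALSE, TRUE),
                   fc = c(18L, 12L, 10L))
  expect_equal(classify_candidates(s, crit),
               c("stimulatory", "none", "inert"))

  # tolerogenic band and the unreleased case
  s2 <- make_scored(2, best_dr_norm = -2, fc = 5L,
                    liberal_released = c(TRUE, FALSE))
  expect_equal(classify_candidates(s2, crit), c("tolerogenic", "none"))

  expect_error(classify_candidates(s[, -which(names(s) == "fc")], crit),
               "fc")
})

test_that("panels take the top-abundance candidates after deduplication", {
  s <- make_scored(50, transcript_count = 101:150)
  pan <- suppressWarnings(build_patient_panels(s, selection_criteria()))
  expect_equal(nrow(pan$stimulatory), 10)
  # every member at least as abundant as any excluded qualifier
  expect_true(min(pan$stimulatory$transcript_count) >=
                max(setdiff(s$transcript_count,
                            pan$stimulatory$transcript_count)))
  expect_true(is.na(attr(pan$stimulatory, "relaxed_threshold_used")))

  # duplicate peptide strings collapse to one
  dup <- make_scored(12, fc = 5L)
  dup$peptide[2] <- dup$peptide[1]
  pan2 <- suppressWarnings(build_patient_panels(dup, selection_criteria()))
  expect_equal(anyDuplicated(pan2$tolerogenic$peptide), 0)
  expect_equal(nrow(pan2$tolerogenic), 5)
})

test_that("the affinity limit relaxes stepwise until the panel fills", {
  # 3 tolerogenic qualifiers at -1.5 but 5 at -1.2
  s <- make_scored(5, fc = 5L,
                   best_dr_norm = c(-1.9, -1.8, -1.7, -1.3, -1.25))
  suppressWarnings(pan <- build_patient_panels(s, selection_criteria()))
  expect_equal(nrow(pan$tolerogenic), 5)
  expect_equal(attr(pan$tolerogenic, "relaxed_threshold_used"), -1.2)
  # relaxation touches only affinity: FC band members unchanged
  expect_true(all(pan$tolerogenic$fc <= 7))

  # still short at the limit: under-filled with warning
  s2 <- make_scored(3, fc = 18L, best_dr_norm = c(-2, -0.2, -0.1))
  w <- capture_warnings(pan2 <- build_patient_panels(s2,
                                                     selection_criteria()))
  expect_true(any(grepl("under-filled", w)))
  expect_equal(nrow(pan2$stimulatory), 1)
})

test_that("stimulatory and tolerogenic panels are disjoint and selection is deterministic", {
  set.seed(99)
  s <- make_scored(60, best_dr_norm = runif(60, -3, 0),
                   fc = sample(c(3L, 5L, 18L, 20L), 60, replace = TRUE),
                   transcript_count = sample(1:500, 60))
  pan <- suppressWarnings(build_patient_panels(s, selection_criteria()))
  expect_length(intersect(pan$stimulatory$peptide,
                          pan$tolerogenic$peptide), 0)
  shuffled <- s[sample(nrow(s)), ]
  pan2 <- suppressWarnings(build_patient_panels(shuffled,
                                                selection_criteria()))
  expect_equal(as.data.frame(pan$stimulatory),
               as.data.frame(pan2$stimulatory))
  expect_equal(as.data.frame(pan$tolerogenic),
               as.data.frame(pan2$tolerogenic))
})

test_that("the inert panel needs all-patient inertness and mixes TCEM frequencies", {
  crit <- selection_criteria()
  # exactly 7 eligible -> those 7
  s <- make_scored(10, best_dr_norm = 0,
                   min_all_norm = c(rep(1.5, 7), rep(0.5, 3)),
                   liberal_released = FALSE, strict_eligible = TRUE,
                   fc = 18L)
  pan <- build_inert_panel(s, crit)
  expect_equal(nrow(pan), 7)
  expect_true(all(pan$min_all_norm > 1))

  # a newly added patient whose allele binds one peptide drops it
  s2 <- s; s2$min_all_norm[1] <- -0.5
  pan2 <- suppressWarnings(build_inert_panel(s2, crit))
  expect_false(s$peptide[1] %in% pan2$peptide)

  # an eligible pool of 20 with both rare and frequent motifs keeps both
  s3 <- make_scored(20, best_dr_norm = 0, min_all_norm = 1.5,
                    liberal_released = FALSE, strict_eligible = TRUE,
                    fc = c(rep(18L, 19), 5L),
                    transcript_count = c(rep(100, 19), 1))
  pan3 <- build_inert_panel(s3, crit)
  expect_equal(nrow(pan3), 7)
  expect_true(any(pan3$fc >= crit$fc_min_stimulatory))
  expect_true(any(pan3$fc <= crit$fc_max_tolerogenic))
})
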