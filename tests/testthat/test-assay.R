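mk_counts <- function(memory, cd154_mem, naive = memory,
                      cd154_nai = 0, reps = 1) {
  data.frame(memory = rep(memory, reps), naive = rep(naive, reps),
             cd154_memory = rep(cd154_mem, reps),
             cd154_naive = rep(cd154_nai, reps))
}

test_that("fold-over-background and the 3x positivity boundary", {
  bg <- activation_metrics(mk_counts(10000, 10))   # 0.10 %
  stim <- activation_metrics(mk_counts(10000, 31), bg)  # 0.31 %
  expect_equal(stim$fold_over_background, 3.1)
  expect_true(stim$positive)

  same <- activation_metrics(mk_counts(10000, 10), bg)
  expect_equal(same$fold_over_background, 1)
  expect_false(same$positive)

  # inclusive boundary: exactly 3x is positive
  edge <- activation_metrics(mk_counts(10000, 30), bg)
  expect_equal(edge$fold_over_background, 3)
  expect_true(edge$positive)

  # memory:naive activation ratio, Fig-style arithmetic
  r <- activation_metrics(mk_counts(10000, 30, naive = 10000,
                                    cd154_nai = 10), bg)
  expect_equal(r$memory_naive_ratio, 3)
})

test_that("degenerate backgrounds are flagged, zero memory is an error", {
  bg0 <- activation_metrics(mk_counts(10000, 0))
  pos <- activation_metrics(mk_counts(10000, 25), bg0)
  expect_equal(pos$fold_over_background, Inf)
  expect_true(pos$positive)
  expect_equal(pos$flag, "background-zero")
  expect_error(activation_metrics(mk_counts(0, 0)), "memory")
})

test_that("positivity calls are invariant to proportional count scaling", {
  set.seed(5)
  for (i in 1:10) {
    mem <- sample(5000:50000, 1); act <- rbinom(1, mem, 0.003)
    bgc <- rbinom(1, mem, 0.001)
    a1 <- activation_metrics(mk_counts(mem, act),
                             activation_metrics(mk_counts(mem, bgc)))
    a2 <- activation_metrics(mk_counts(10 * mem, 10 * act),
                             activation_metrics(mk_counts(10 * mem,
                                                          10 * bgc)))
    expect_equal(a1$positive, a2$positive)
    expect_equal(a1$fold_over_background, a2$fold_over_background)
  }
})

test_that("replicate means drive the metrics", {
  two <- data.frame(memory = c(10000, 20000), naive = c(10000, 20000),
                    cd154_memory = c(10, 40), cd154_naive = c(0, 0))
  m <- activation_metrics(two)
  expect_equal(m$pct_activated_memory, mean(c(10 / 10000, 40 / 20000)) * 100)
})

test_that("the mixed model matches OLS on balanced designs without patient effects", {
  d <- simulate_group_response(n_patients = 6, sigma_patient = 0,
                               sigma_resid = 0.2, seed = 13)
  got <- suppressMessages(compare_groups(d, ddf = "wald"))
  ols <- lm(pct_activated_memory ~ category, data = d)
  cf <- coef(ols)   # inert is the reference level
  stim_inert <- unname(cf["categorystimulatory"])
  pw <- got$pairwise
  est <- pw$estimate[pw$contrast == "inert - stimulatory"]
  expect_equal(-est, stim_inert, tolerance = 0.02)

  # all observations equal: all differences zero, zero random variance
  d0 <- d; d0$pct_activated_memory <- 0.5
  got0 <- suppressWarnings(compare_groups(d0, ddf = "wald"))
  expect_true(all(abs(got0$pairwise$estimate) < 1e-10))
  expect_equal(got0$var_patient, 0)
})

test_that("satterthwaite path reports pairwise CIs and variance components", {
  d <- simulate_group_response(seed = 21)
  cmp <- compare_groups(d)
  expect_s3_class(cmp, "group_comparison")
  expect_equal(nrow(cmp$pairwise), 3)
  expect_true(all(c("estimate", "lower", "upper", "p") %in%
                    names(cmp$pairwise)))
  expect_gt(cmp$var_patient, 0)
  # planted: stimulatory and tolerogenic exceed inert by 0.3
  pw <- cmp$pairwise
  si <- pw[pw$contrast == "inert - stimulatory", ]
  expect_lt(si$estimate, 0)
  expect_lt(si$p, 0.05)
  expect_error(compare_groups(d[d$category == "inert", ]), "two categories")
})

test_that("chemokine enrichment detects a planted CCR6 shift but not CXCR3", {
  stim <- data.frame(stimulus = sprintf("pep%02d", 1:5),
                     category = "stimulatory")
  fl <- simulate_flow_counts(stim, sprintf("MS-%02d", 1:9),
                             category_enrichment = c(stimulatory = 0.01,
                                                     tolerogenic = 0,
                                                     inert = 0),
                             ccr6_background = 0.30, ccr6_activated = 0.60,
                             cxcr3_background = 0.40, cxcr3_activated = 0.40,
                             seed = 31)
  ar <- activation_results(fl$flow)
  pos <- ar[!is.na(ar$positive) & ar$positive & ar$category != "control", ]
  ce <- chemokine_enrichment(fl$flow, pos)
  ccr6 <- ce[ce$marker == "CCR6", ]
  cxcr3 <- ce[ce$marker == "CXCR3", ]
  expect_gt(ccr6$estimate, 15)
  expect_lt(ccr6$p, 0.01)
  expect_gt(cxcr3$p, 0.05)
  expect_lt(abs(cxcr3$unadjusted_difference), 5)

  # identical fractions everywhere: difference collapses to zero
  flat <- fl$flow
  flat$ccr6_cd154pos <- round(flat$cd154_memory * 0.3)
  flat$ccr6_cd154neg <- round(flat$cd154neg_memory * 0.3)
  ce0 <- suppressWarnings(chemokine_enrichment(flat, pos))
  expect_lt(abs(ce0$estimate[ce0$marker == "CCR6"]), 2)

  # single patient: estimate returned, patient variance not identifiable
  one <- suppressWarnings(
    chemokine_enrichment(fl$flow[fl$flow$patient_id == "MS-01", ],
                         pos[pos$patient_id == "MS-01", ]))
  expect_true(is.finite(one$estimate[1]))
  expect_true(is.na(one$var_patient[1]))

  # no positives: empty result with message
  expect_message(out <- chemokine_enrichment(fl$flow, pos[0, ]),
                 "no positive")
  expect_null(out)
})
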