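test_that("zero mutation rate reproduces germlines exactly and seeds reproduce", {
  sim <- simulate_repertoire(n_patients = 2, seqs_mean = 10, seqs_sd = 2,
                             min_seqs = 5, shm_rate = 0, seed = 61)
  expect_identical(sim$repertoire$sequence,
                   sim$repertoire$germline_sequence)
  expect_equal(nrow(sim$mutations), 0)

  again <- simulate_repertoire(n_patients = 2, seqs_mean = 10, seqs_sd = 2,
                               min_seqs = 5, shm_rate = 0, seed = 61)
  expect_identical(as.data.frame(sim$repertoire),
                   as.data.frame(again$repertoire))

  # written FASTA is byte-identical across re-runs
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  t1 <- withr::local_tempfile(); t2 <- withr::local_tempfile()
  write_repertoire(sim$repertoire, f1, t1)
  write_repertoire(again$repertoire, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("observed mutation frequency matches the binomial rate", {
  rate <- 0.02
  sim <- simulate_repertoire(n_patients = 1, seqs_mean = 1000, seqs_sd = 0,
                             min_seqs = 1000, shm_rate = rate, seed = 67)
  n_pos <- sum(nchar(sim$repertoire$sequence)) - 2 * nrow(sim$repertoire)
  # two anchor residues per sequence are never mutated
  p_hat <- nrow(sim$mutations) / n_pos
  se <- sqrt(rate * (1 - rate) / n_pos)
  expect_lt(abs(p_hat - rate), 3 * se)
  # every recorded mutation really differs from germline at that position
  i <- sample(nrow(sim$mutations), 50)
  mu <- sim$mutations[i, ]
  seqs <- sim$repertoire$sequence[match(mu$record_id,
                                        sim$repertoire$record_id)]
  germ <- sim$repertoire$germline_sequence[match(mu$record_id,
                                                 sim$repertoire$record_id)]
  expect_identical(substr(seqs, mu$position + 1, mu$position + 1),
                   mu$mutated_aa)
  expect_identical(substr(germ, mu$position + 1, mu$position + 1),
                   mu$germline_aa)
})

test_that("structural invariants of simulated repertoires hold", {
  sim <- simulate_repertoire(n_patients = 3, seqs_mean = 20, seqs_sd = 5,
                             min_seqs = 10, seed = 71)
  rep <- sim$repertoire
  len <- nchar(rep$sequence)
  expect_true(all(len >= 30 & len <= 45))
  expect_true(all(substr(rep$sequence, rep$cdr3_start + 1,
                         rep$cdr3_start + 1) == "C"))
  expect_true(all(substr(rep$sequence, rep$cdr3_end + 1,
                         rep$cdr3_end + 1) == "W"))
  expect_true(all(rep$transcript_count >= 1))
  expect_error(simulate_repertoire(seed = 1, length_range = c(10, 20)),
               "length")
  expect_error(simulate_repertoire(n_patients = 1))   # seed mandatory
})

test_that("flow simulation plants responders at the requested rates", {
  stim <- data.frame(stimulus = c("pepA", "pepB"),
                     category = c("stimulatory", "inert"))
  planted <- data.frame(patient_id = "MS-01", stimulus = "pepA",
                        rate = 0.01)
  fl <- simulate_flow_counts(stim, c("MS-01", "MS-02"),
                             category_enrichment = c(stimulatory = 0,
                                                     tolerogenic = 0,
                                                     inert = 0),
                             planted_responders = planted, seed = 73)
  expect_true(all(c("pepA", "pepB", "unstimulated", "CD3CD28") %in%
                    fl$flow$stimulus))
  expect_equal(fl$truth$stimulus[fl$truth$patient_id == "MS-01" &
                                   fl$truth$stimulus == "pepA"], "pepA")
  # subset counts never exceed their parents
  expect_true(all(fl$flow$memory + fl$flow$naive == fl$flow$cd4_total))
  expect_true(all(fl$flow$cd154_memory <= fl$flow$memory))
  expect_true(all(fl$flow$ccr6_cd154pos <= fl$flow$cd154_memory))

  ar <- activation_results(fl$flow)
  hit <- ar[ar$patient_id == "MS-01" & ar$stimulus == "pepA", ]
  expect_true(hit$positive)   # 10x background responder is called

  expect_error(simulate_flow_counts(stim, "MS-01", seed = 1,
                                    planted_responders = data.frame(
                                      patient_id = "MS-01",
                                      stimulus = "pepA", rate = 2)),
               "frequency")
})
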