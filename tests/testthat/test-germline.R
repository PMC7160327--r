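# Fully controlled toy models so that every expected delta can be
# hand-computed: two DR "alleles" whose matrices are zero except a strong
# bonus for tryptophan at core position 1, and a cleavage table where only
# K|K bonds cut.
toy_affinity <- function(bonus = -3) {
  aa <- amino_acids()
  m <- matrix(0, nrow = 20, ncol = 9, dimnames = list(aa, NULL))
  m["W", 1] <- bonus
  affinity_model(list(`HLA-DRB1*15:01` = m, `HLA-DRB1*03:01` = m),
                 name = "toy")
}

toy_cleavage <- function(kk = 0.9, base = 0.05) {
  aa <- amino_acids()
  tab <- matrix(base, nrow = 20, ncol = 20, dimnames = list(aa, aa))
  tab["K", "K"] <- kk
  cleavage_model(list(S = tab, B = tab), name = "toy")
}

toy_record <- function(sequence, germline) {
  rec <- data.frame(record_id = "R1", patient_id = "P1",
                    sequence = sequence, transcript_count = 1L,
                    cdr3_start = 11L, cdr3_end = 21L,
                    germline_sequence = germline, padded = FALSE,
                    stringsAsFactors = FALSE)
  ighv_repertoire(rec)
}

DRS <- c("HLA-DRB1*15:01", "HLA-DRB1*03:01")

test_that("germline alignment flags substitutions and insertion offsets", {
  same <- align_to_germline("ACDEFGHIKL", "ACDEFGHIKL")
  expect_length(same$mutations, 0)
  expect_equal(same$map, 0:9)

  one <- align_to_germline("ACDEFGHWKL", "ACDEFGHIKL")
  expect_equal(one$mutations, 7)

  # a 2-aa insertion: downstream positions map with offset 2
  ins <- align_to_germline("ACDEFWWGHIKLMNP", "ACDEFGHIKLMNP")
  expect_equal(ins$insertions, c(5, 6))
  expect_equal(ins$map[8:15], 5:12)
  expect_length(ins$mutations, 0)

  expect_error(align_to_germline("ACDEF", NA_character_), "germline")
})

test_that("an unmutated window is classified unchanged with zero FC delta", {
  seqc <- paste0(strrep("A", 11), "CARDWLLYKG", strrep("G", 10))
  rec <- toy_record(seqc, seqc)
  refs <- list(a = tiny_repertoire(2, 6, seed = 41))
  idx <- build_frequency_index(refs)
  d <- compute_delta(5, rec, toy_affinity(), toy_cleavage(), idx,
                     dr_alleles = DRS)
  expect_equal(d$net_effect, "unchanged")
  expect_equal(d$delta_fc, 0)
  expect_equal(d$mutations_in_window, 0)
  expect_equal(d$`affinity_HLA-DRB1*15:01`, "unchanged")
})

test_that("a planted affinity-raising mutation is classified improved", {
  # germline all-A; mutation plants W inside the window core region, which
  # lowers ln(IC50) by 3 on both alleles under the toy matrix
  germ <- strrep("A", 31)
  mut <- paste0(strrep("A", 10), "W", strrep("A", 20))
  rec <- toy_record(mut, germ)
  d <- compute_delta(5, rec, toy_affinity(), toy_cleavage(),
                     dr_alleles = DRS)
  # oracle: recompute through the public predictor
  pm <- predict_affinity(toy_affinity(), substr(mut, 6, 20),
                         DRS[1])$raw_lnic50
  pg <- predict_affinity(toy_affinity(), substr(germ, 6, 20),
                         DRS[1])$raw_lnic50
  expect_lt(pm - pg, -0.1)
  expect_equal(d$`affinity_HLA-DRB1*15:01`, "lower")
  expect_equal(d$net_effect, "improved")
  expect_equal(d$mutations_in_window, 1)
})

test_that("opposing affinity and cleavage changes give a mixed call", {
  # mutation plants W in the core (affinity up) but destroys a K|K cut at
  # the C-terminal flank (cleavage down)
  germ <- paste0(strrep("A", 19), "KK", strrep("A", 10))   # bond 19 is K|K
  mut <- paste0(strrep("A", 8), "W", strrep("A", 10), "AK",
                strrep("A", 10))
  rec <- toy_record(mut, germ)
  d <- compute_delta(5, rec, toy_affinity(), toy_cleavage(),
                     dr_alleles = DRS)
  expect_equal(d$cleavage_C, "lower")
  expect_equal(d$`affinity_HLA-DRB1*15:01`, "lower")
  expect_equal(d$net_effect, "mixed")
})

test_that("mutations outside window and flank leave the call unchanged", {
  set.seed(17)
  for (i in 1:10) {
    germ <- paste(sample(setdiff(amino_acids(), "W"), 31, replace = TRUE),
                  collapse = "")
    # mutate the last residue; window at start 5 spans 5..19, flank to 22
    far <- paste0(substr(germ, 1, 27), "W",
                  substr(germ, 29, 31))
    rec <- toy_record(far, germ)
    d <- compute_delta(5, rec, toy_affinity(), toy_cleavage(),
                       dr_alleles = DRS)
    expect_equal(d$net_effect, "unchanged")
    expect_equal(d$mutations_in_window, 0)
    expect_equal(d$mutations_in_flank, 0)
  }
})

test_that("windows disrupted by insertions are reported not computable", {
  germ <- strrep("A", 29)
  mut <- paste0(strrep("A", 10), "WW", strrep("A", 19))  # 2-aa insertion
  rec <- toy_record(mut, germ)
  d <- compute_delta(5, rec, toy_affinity(), toy_cleavage(),
                     dr_alleles = DRS)
  expect_true(d$not_computable)
  expect_true(is.na(d$net_effect))
})

test_that("on synthetic data mutations rarefy motifs (non-negative FC delta on average)", {
  sim <- simulate_repertoire(n_patients = 2, seqs_mean = 40, seqs_sd = 5,
                             min_seqs = 20, shm_rate = 0.06, seed = 53)
  refs <- list(
    a = simulate_repertoire(n_patients = 2, seqs_mean = 60, seqs_sd = 5,
                            min_seqs = 20, shm_rate = 0, seed = 54)$repertoire)
  idx <- build_frequency_index(refs)
  rep <- sim$repertoire
  hla <- simulate_hla(unique(rep$patient_id), seed = 55)
  cand <- enumerate_15mers(rep)
  # windows containing at least one mutation
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    mu <- sim$mutations[sim$mutations$record_id == cand$record_id[i], ]
    any(mu$position >= cand$start[i] & mu$position < cand$start[i] + 15)
  }, logical(1))
  cand <- cand[keep, ][1:100, ]
  d <- germline_deltas(cand, rep, hla, AFF, CLV, idx)
  expect_gt(mean(d$delta_fc, na.rm = TRUE), -1e-9)
})
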