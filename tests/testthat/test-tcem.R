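test_that("motif extraction applies the position mask deterministically", {
  # homopolymer: any mask reads off the same residue
  expect_equal(extract_tcem(strrep("A", 15), 3, "IIa")$motif, "AAAAA")
  expect_equal(extract_tcem(strrep("A", 15), 0, "IIb")$valid, FALSE)

  # all-distinct peptide, default IIa mask {2,3,5,7,8}, core_start = 3:
  # 0-based positions 5,6,8,10,11 -> G,H,K,M,N (hand-applied oracle)
  pep <- "ACDEFGHIKLMNPQR"
  expect_equal(extract_tcem(pep, 3, "IIa")$motif, "GHKMN")
  # IIb mask {-1,3,5,7,8} at core 3 -> positions 2,6,8,10,11 -> D,H,K,M,N
  expect_equal(extract_tcem(pep, 3, "IIb")$motif, "DHKMN")

  # residues outside the mask positions do not matter
  pep2 <- "YYYYYGHYKYMNYYY"
  expect_equal(extract_tcem(pep2, 3, "IIa")$motif,
               extract_tcem("AAAAAGHAKAMNAAA", 3, "IIa")$motif)

  expect_error(extract_tcem(pep, 7, "IIa"), "core_start")
  expect_false(extract_tcem("AAAAAXAAAAAAAAA", 3, "IIa")$valid)
})

test_that("frequency index counts motifs once per sequence and is order-invariant", {
  rep1 <- ighv_repertoire(data.frame(
    record_id = "one", patient_id = "P", sequence = strrep("A", 15),
    transcript_count = 1, cdr3_start = 2, cdr3_end = 10))
  idx1 <- build_frequency_index(list(r = rep1))
  expect_equal(unname(idx1$sets$r$counts[["IIa\rAAAAA"]]), 1)

  # the same motif in two windows of one sequence still counts once
  rep2 <- ighv_repertoire(data.frame(
    record_id = "two", patient_id = "P", sequence = strrep("A", 20),
    transcript_count = 1, cdr3_start = 2, cdr3_end = 10))
  idx2 <- build_frequency_index(list(r = rep2))
  expect_equal(unname(idx2$sets$r$counts[["IIa\rAAAAA"]]), 1)

  rep <- tiny_repertoire(n_patients = 2, seqs_mean = 6, seed = 31)
  fwd <- build_frequency_index(list(a = rep))
  perm <- rep[rev(seq_len(nrow(rep))), ]
  class(perm) <- class(rep)
  bwd <- build_frequency_index(list(a = perm))
  expect_equal(fwd$sets$a$counts[sort(names(fwd$sets$a$counts))],
               bwd$sets$a$counts[sort(names(bwd$sets$a$counts))])
  expect_error(build_frequency_index(list()), "at least one")
})

test_that("frequency classes reproduce the inverse-log2 scale", {
  mk_idx <- function(count, total) {
    tcem_index(data.frame(set = "a", variant = "IIa", motif = "AAAAA",
                          count = count), c(a = total))
  }
  # count = total: maximally frequent
  expect_equal(frequency_class("AAAAA", "IIa", mk_idx(1024, 1024)), 0)
  # once per 2^17 sequences: the rare-band boundary
  expect_equal(frequency_class("AAAAA", "IIa", mk_idx(1, 131072)), 17)
  # floor(-log2(3/1024)) = 8, by independent arithmetic
  expect_equal(frequency_class("AAAAA", "IIa", mk_idx(3, 1024)), 8)
  # unobserved motif gets the cap
  expect_equal(frequency_class("CCCCC", "IIa", mk_idx(1, 131072)), 24)
  expect_true(is.na(frequency_class(NA_character_, "IIa", mk_idx(1, 10))))
})

test_that("FC is monotone in count and combined FC is the min over sets", {
  total <- 256
  fc <- vapply(1:total, function(cnt) {
    idx <- tcem_index(data.frame(set = "a", variant = "IIa",
                                 motif = "AAAAA", count = cnt),
                      c(a = total))
    frequency_class("AAAAA", "IIa", idx)
  }, integer(1))
  expect_true(all(diff(fc) <= 0))
  expect_true(all(fc >= 0 & fc <= 24))

  idx2 <- tcem_index(data.frame(set = c("a", "b"), variant = "IIa",
                                motif = "AAAAA", count = c(1, 64)),
                     c(a = 1024, b = 1024))
  fa <- frequency_class("AAAAA", "IIa",
                        tcem_index(data.frame(set = "a", variant = "IIa",
                                              motif = "AAAAA", count = 1),
                                   c(a = 1024)))
  fb <- frequency_class("AAAAA", "IIa",
                        tcem_index(data.frame(set = "b", variant = "IIa",
                                              motif = "AAAAA", count = 64),
                                   c(b = 1024)))
  expect_equal(frequency_class("AAAAA", "IIa", idx2), min(fa, fb))
})

test_that("index serialization round-trips and candidate FC uses both variants", {
  rep <- tiny_repertoire(n_patients = 2, seqs_mean = 6, seed = 37)
  idx <- build_frequency_index(list(a = rep))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tcem_index(idx, path)
  back <- read_tcem_index(path)
  peps <- random_peptides(20, seed = 5)
  expect_equal(candidate_fc(peps, idx), candidate_fc(peps, back))

  # candidate FC is the min over the two mask variants
  one <- rep[1, ]; class(one) <- class(rep)
  idx1 <- build_frequency_index(list(a = one))
  pep <- substr(one$sequence, 1, 15)
  fc_a <- frequency_class(extract_tcem(pep, 3, "IIa")$motif, "IIa", idx1)
  fc_b <- frequency_class(extract_tcem(pep, 3, "IIb")$motif, "IIb", idx1)
  expect_equal(candidate_fc(pep, idx1), min(fc_a, fc_b))
})
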