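# Shared fixtures: models are loaded once; repertoires are generated in
# code at fixed seeds so no binary fixtures are needed.

AFF <- surrogate_affinity_model()
CLV <- surrogate_cleavage_model()

tiny_repertoire <- function(n_patients = 2, seqs_mean = 12, seed = 7) {
  simulate_repertoire(n_patients = n_patients, seqs_mean = seqs_mean,
                      seqs_sd = 3, min_seqs = 5, seed = seed)$repertoire
}

# A single hand-built record with known coordinates: FW3 (11 aa), CDR3
# (C + 9 aa = 10 aa), FW4 (11 aa); total length 32.
hand_record <- function(padded = FALSE) {
  rec <- data.frame(
    record_id = "R1", patient_id = "P1",
    sequence = paste0("SLRAEDTAVYY", "CARDWLLYKG", "WGQGTLVTVSS"),
    transcript_count = 5L, cdr3_start = 11L, cdr3_end = 21L,
    germline_sequence = NA_character_, padded = FALSE,
    stringsAsFactors = FALSE)
  rec <- ighv_repertoire(rec)
  if (padded) rec <- pad_records(rec) else rec
}

# Minimal scored-candidate table for selection tests; every scoring column
# is set explicitly so band membership is fully controlled.
make_scored <- function(n, patient_id = "P1", peptide = NULL,
                        transcript_count = seq(n, 1), best_dr_norm = -2,
                        min_all_norm = 0, liberal_released = TRUE,
                        strict_eligible = FALSE, fc = 18L) {
  if (is.null(peptide)) peptide <- random_peptides(n, seed = n)
  data.frame(peptide = peptide, record_id = paste0("r", seq_len(n)),
             patient_id = patient_id, start = 0L,
             cdr3_relative_position = 0L, region_label = "CDR3",
             contains_padding = FALSE,
             transcript_count = transcript_count,
             best_dr_norm = best_dr_norm, best_dr_allele = "HLA-DRB1*15:01",
             min_all_norm = min_all_norm,
             liberal_released = liberal_released,
             strict_eligible = strict_eligible,
             released_by = ifelse(liberal_released, "S", ""),
             intra_destruction_prob = 0, fc = fc,
             stringsAsFactors = FALSE)
}

# Deterministic distinct peptide strings.
random_peptides <- function(n, seed = 1) {
  set.seed(seed)
  unique(vapply(seq_len(2 * n), function(i) {
    paste(sample(amino_acids(), 15, replace = TRUE), collapse = "")
  }, ""))[seq_len(n)]
}
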