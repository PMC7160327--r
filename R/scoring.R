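# Glue stage: attach affinity, release and TCEM scores to enumerated
# candidates, against a patient HLA table.

#' Construct a patient HLA table
#'
#' @param patient_id,allele parallel vectors (one row per patient-allele).
#' @return data.frame `patient_id`, `allele`, `locus`.
#' @export
hla_table <- function(patient_id, allele) {
  locus <- hla_locus(allele)
  if (anyNA(locus)) {
    stop_idioscope("cannot determine locus for: %s",
                   paste(allele[is.na(locus)], collapse = ", "))
  }
  data.frame(patient_id = as.character(patient_id), allele = allele,
             locus = locus, stringsAsFactors = FALSE)
}

#' Score candidate 15-mers for presentability
#'
#' Computes, for every candidate: the best (minimum) normalized affinity
#' over the candidate patient's own HLA-DR alleles (`best_dr_norm`, the
#' quantity thresholded for stimulatory/tolerogenic selection), the minimum
#' normalized affinity over ALL patients' class II alleles (`min_all_norm`,
#' the quantity used for the shared inert panel), cathepsin release
#' assessments, and the combined TCEM frequency class. Candidates whose
#' peptide contains `X` are dropped (conservative exclusion of ambiguous
#' translations).
#'
#' @param candidates data.frame from [enumerate_15mers()].
#' @param repertoire the source [ighv_repertoire()] (for cleavage context).
#' @param hla a [hla_table()] covering every candidate patient.
#' @param affinity an `affinity_model`.
#' @param cleavage a `cleavage_model`.
#' @param tcem a `tcem_index`.
#' @param flank_window,cut_liberal,cut_strict release parameters, see
#'   [assess_release()].
#' @param tcem_core `"central"` (core offset 3 for both index and query,
#'   the default, keeping index and lookup registers consistent) or
#'   `"affinity"` (use the best-DR binding register per candidate).
#' @return The candidate data.frame with score columns appended.
#' @export
score_candidates <- function(candidates, repertoire, hla, affinity, cleavage,
                             tcem, flank_window = 3L, cut_liberal = 0.5,
                             cut_strict = 0.3, tcem_core = c("central",
                                                             "affinity")) {
  tcem_core <- match.arg(tcem_core)
  keep <- !grepl("X", candidates$peptide, fixed = TRUE)
  if (any(!keep)) {
    message(sum(!keep), " candidate(s) containing 'X' excluded from scoring")
  }
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) == 0) stop_idioscope("no scoreable candidates")

  alleles <- unique(hla$allele)
  aff <- affinity_table(affinity, cand$peptide, alleles, normalize = TRUE)
  # peptide x allele matrices of normalized scores and core offsets
  peps <- unique(cand$peptide)
  norm_mat <- matrix(NA_real_, nrow = length(peps), ncol = length(alleles),
                     dimnames = list(peps, alleles))
  core_mat <- matrix(NA_integer_, nrow = length(peps), ncol = length(alleles),
                     dimnames = list(peps, alleles))
  norm_mat[cbind(match(aff$peptide, peps), match(aff$allele, alleles))] <-
    aff$normalized
  core_mat[cbind(match(aff$peptide, peps), match(aff$allele, alleles))] <-
    aff$core_start

  pid <- unique(cand$patient_id)
  dr_of <- lapply(setNames(nm = pid), function(p) {
    unique(hla$allele[hla$patient_id == p & hla$locus == "DR"])
  })
  row_i <- match(cand$peptide, peps)
  best_dr_norm <- rep(NA_real_, nrow(cand))
  best_dr_allele <- rep(NA_character_, nrow(cand))
  for (p in pid) {
    drs <- dr_of[[p]]
    if (length(drs) == 0) stop_idioscope("no DR alleles for patient %s", p)
    i <- which(cand$patient_id == p)
    sub <- norm_mat[row_i[i], drs, drop = FALSE]
    j <- max.col(-sub, ties.method = "first")
    best_dr_norm[i] <- sub[cbind(seq_along(i), j)]
    best_dr_allele[i] <- drs[j]
  }
  cand$best_dr_norm <- best_dr_norm
  cand$best_dr_allele <- best_dr_allele
  cand$min_all_norm <- apply(norm_mat[row_i, , drop = FALSE], 1, min)

  # release assessment, per source record
  rel <- vector("list", length(unique(cand$record_id)))
  names(rel) <- unique(cand$record_id)
  out_rel <- data.frame()
  cand$liberal_released <- NA
  cand$strict_eligible <- NA
  cand$released_by <- NA_character_
  cand$intra_destruction_prob <- NA_real_
  for (rid in names(rel)) {
    seq <- repertoire$sequence[match(rid, repertoire$record_id)]
    prof <- cleavage_profiles(cleavage, seq)
    i <- which(cand$record_id == rid)
    a <- assess_release(cand$start[i], prof, flank_window = flank_window,
                        cut_liberal = cut_liberal, cut_strict = cut_strict)
    cand$liberal_released[i] <- a$liberal_released
    cand$strict_eligible[i] <- a$strict_eligible
    cand$released_by[i] <- a$released_by
    cand$intra_destruction_prob[i] <- a$intra_destruction_prob
  }

  if (tcem_core == "central") {
    cand$fc <- candidate_fc(cand$peptide, tcem)
  } else {
    core <- core_mat[cbind(row_i, match(cand$best_dr_allele, alleles))]
    cand$fc <- candidate_fc(cand$peptide, tcem, core_start = core)
  }
  rownames(cand) <- NULL
  cand
}
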