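# Imputation of somatic-mutation effects: compare each candidate window's
# presentability metrics between the mutated IGHV sequence and its assigned
# germline counterpart.

#' Align a mutated IGHV sequence to its germline
#'
#' Produces a per-position correspondence map. Equal-length pairs map
#' positionally; unequal lengths are aligned globally (Needleman-Wunsch via
#' Biostrings) so that insertions relative to germline map to `NA` and
#' downstream positions carry the offset.
#'
#' @param sequence mutated amino-acid sequence.
#' @param germline germline amino-acid sequence.
#' @return List with `map` (integer vector, length `nchar(sequence)`:
#'   0-based germline position of each 0-based sequence position, `NA` for
#'   insertions), `mutations` (0-based sequence positions whose residue
#'   differs from the mapped germline residue), `insertions` (0-based
#'   positions with no germline counterpart).
#' @export
align_to_germline <- function(sequence, germline) {
  if (is.na(germline) || !nzchar(germline)) {
    stop_idioscope("no germline sequence available")
  }
  s <- strsplit(sequence, "", fixed = TRUE)[[1]]
  g <- strsplit(germline, "", fixed = TRUE)[[1]]
  if (length(s) == length(g)) {
    map <- seq_along(s) - 1L
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sequence), Biostrings::AAString(germline),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    su <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    map <- rep(NA_integer_, length(s))
    si <- 0L; gi <- 0L
    for (k in seq_along(pa)) {
      if (pa[k] != "-" && su[k] != "-") {
        si <- si + 1L; gi <- gi + 1L
        map[si] <- gi - 1L
      } else if (pa[k] != "-") {
        si <- si + 1L            # insertion relative to germline
      } else {
        gi <- gi + 1L            # deletion relative to germline
      }
    }
  }
  mapped <- which(!is.na(map))
  mutations <- mapped[s[mapped] != g[map[mapped] + 1L]] - 1L
  list(map = map, mutations = mutations,
       insertions = which(is.na(map)) - 1L)
}

# Windowed terminal cleavage maximum used for delta comparisons: max S/B
# (by default) bond probability within +/- flank bonds of a terminus.
terminal_cut_max <- function(profiles, bond0, flank, cathepsins) {
  nb <- length(profiles[[1]])
  lo <- max(bond0 - flank, 0L); hi <- min(bond0 + flank, nb - 1L)
  if (lo > hi) return(0)
  max(vapply(profiles[cathepsins], function(p) max(p[(lo + 1L):(hi + 1L)]),
             numeric(1)))
}

#' Impute the somatic-mutation effect on one candidate window
#'
#' Re-runs the affinity, cleavage and TCEM predictions on the germline
#' counterpart of the candidate's 15-mer window (same coordinates through
#' the alignment map) and classifies the change. Directions use a
#' biologically signed bookkeeping: "favors presentation" means ln(IC50)
#' lower by more than `threshold` on a DR allele, or a terminal cleavage
#' probability (max over cathepsins S/B within `flank` bonds of that
#' terminus) higher by more than `threshold`. The net effect is `improved`
#' when at least one component favors and none disfavors, `negative` when
#' the reverse, `mixed` when both, `unchanged` otherwise. The TCEM
#' frequency-class change is reported but by default not entered into the
#' net call.
#'
#' @param start 0-based candidate window start in the mutated sequence.
#' @param record one-row repertoire subset holding the mutated sequence and
#'   its germline.
#' @param affinity an `affinity_model`.
#' @param cleavage a `cleavage_model`.
#' @param tcem a `tcem_index` (optional; `NULL` skips the FC delta).
#' @param dr_alleles the patient's DR alleles (typically two).
#' @param flank flank width in residues/bonds (default 3).
#' @param threshold change magnitude below which a component is
#'   "unchanged" (default 0.1, on both the ln IC50 and probability scales).
#' @param delta_cathepsins cathepsins entering the cleavage delta
#'   (default S and B).
#' @param include_fc_in_net include the FC change in the net call?
#' @return One-row data.frame (class `germline_delta`) with per-allele
#'   affinity directions, per-side cleavage directions, FC delta, mutation
#'   counts and net classification.
#' @export
compute_delta <- function(start, record, affinity, cleavage, tcem = NULL,
                          dr_alleles, flank = 3L, threshold = 0.1,
                          delta_cathepsins = c("S", "B"),
                          include_fc_in_net = FALSE) {
  seqm <- record$sequence
  aln <- align_to_germline(seqm, record$germline_sequence)
  win <- (start + 1L):(start + 15L)
  map_win <- aln$map[win]
  not_computable <- anyNA(map_win) ||
    any(diff(map_win) != 1L)   # insertion disrupts the window
  flank_pos <- setdiff(intersect(c((start - flank):(start - 1L),
                                   (start + 15L):(start + 14L + flank)),
                                 0:(nchar(seqm) - 1L)), NA)
  mutations_in_window <- sum(aln$mutations %in% (win - 1L))
  mutations_in_flank <- sum(aln$mutations %in% flank_pos)

  direction <- function(delta) {
    # delta = mutated - germline, on the metric's own scale (ln IC50 for
    # affinity, probability for cleavage)
    if (is.na(delta)) return(NA_character_)
    if (abs(delta) <= threshold) return("unchanged")
    if (delta < 0) "lower" else "higher"
  }

  aff_dir <- setNames(rep(NA_character_, length(dr_alleles)), dr_alleles)
  cut_dir <- c(N = NA_character_, C = NA_character_)
  delta_fc <- NA_integer_
  favors <- 0L; disfavors <- 0L
  if (!not_computable) {
    gstart <- map_win[1]
    pep_m <- substr(seqm, start + 1L, start + 15L)
    pep_g <- substr(record$germline_sequence, gstart + 1L, gstart + 15L)
    for (al in dr_alleles) {
      raw_m <- predict_affinity(affinity, pep_m, al)$raw_lnic50
      raw_g <- predict_affinity(affinity, pep_g, al)$raw_lnic50
      d <- raw_m - raw_g
      aff_dir[al] <- direction(d)
      if (!is.na(d) && abs(d) > threshold) {
        if (d < 0) favors <- favors + 1L else disfavors <- disfavors + 1L
      }
    }
    prof_m <- cleavage_profiles(cleavage, seqm)
    prof_g <- cleavage_profiles(cleavage, record$germline_sequence)
    term <- c(N = start - 1L, C = start + 14L)
    gterm <- c(N = gstart - 1L, C = gstart + 14L)
    for (side in c("N", "C")) {
      pm <- terminal_cut_max(prof_m, term[[side]], flank, delta_cathepsins)
      pg <- terminal_cut_max(prof_g, gterm[[side]], flank, delta_cathepsins)
      d <- pm - pg
      cut_dir[side] <- direction(d)
      if (abs(d) > threshold) {
        if (d > 0) favors <- favors + 1L else disfavors <- disfavors + 1L
      }
    }
    if (!is.null(tcem)) {
      fc_m <- candidate_fc(pep_m, tcem)
      fc_g <- candidate_fc(pep_g, tcem)
      delta_fc <- fc_m - fc_g
      if (include_fc_in_net && !is.na(delta_fc) && delta_fc != 0) {
        if (delta_fc > 0) favors <- favors + 1L else disfavors <- disfavors + 1L
      }
    }
    net <- if (favors > 0 && disfavors == 0) "improved"
    else if (disfavors > 0 && favors == 0) "negative"
    else if (favors > 0 && disfavors > 0) "mixed"
    else "unchanged"
  } else {
    net <- NA_character_
  }
  out <- data.frame(
    record_id = record$record_id, start = start,
    mutations_in_window = mutations_in_window,
    mutations_in_flank = mutations_in_flank,
    delta_fc = delta_fc, net_effect = net,
    not_computable = not_computable,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(dr_alleles)) {
    out[[paste0("affinity_", dr_alleles[k])]] <- aff_dir[k]
  }
  out$cleavage_N <- cut_dir[["N"]]
  out$cleavage_C <- cut_dir[["C"]]
  out
}

#' Impute somatic-mutation effects for a panel of candidates
#'
#' Applies [compute_delta()] to every row of a selected-panel table whose
#' source record carries a germline sequence; records without one are
#' skipped with a message.
#'
#' @param panel_table rows with `record_id`, `start`, `patient_id` (e.g.
#'   the `table` element of [build_all_panels()]).
#' @param repertoire the source [ighv_repertoire()].
#' @param hla a [hla_table()]; the patient's DR alleles are used.
#' @param affinity,cleavage,tcem models as in [compute_delta()].
#' @param ... passed to [compute_delta()].
#' @return data.frame of per-candidate deltas (peptide and patient columns
#'   prepended).
#' @export
germline_deltas <- function(panel_table, repertoire, hla, affinity, cleavage,
                            tcem = NULL, ...) {
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(panel_table))) {
    rec <- repertoire[repertoire$record_id == panel_table$record_id[i], ,
                      drop = FALSE]
    if (nrow(rec) != 1 || is.na(rec$germline_sequence)) {
      skipped <- skipped + 1L
      next
    }
    drs <- unique(hla$allele[hla$patient_id == rec$patient_id &
                               hla$locus == "DR"])
    d <- compute_delta(panel_table$start[i], rec, affinity, cleavage, tcem,
                       dr_alleles = drs, ...)
    d <- cbind(data.frame(peptide = panel_table$peptide[i],
                          patient_id = rec$patient_id,
                          stringsAsFactors = FALSE), d)
    rows[[length(rows) + 1]] <- d
  }
  if (skipped > 0) {
    message(skipped, " candidate(s) skipped (no germline sequence)")
  }
  if (length(rows) == 0) return(NULL)
  # different patients can have different DR allele columns; harmonise
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (c in setdiff(cols, names(r))) r[[c]] <- NA_character_
    r[, cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
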