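# Candidate 15-mer enumeration and CDR3-relative region labeling.

#' Enumerate candidate 15-mer idiotopes
#'
#' Slides a 15-residue window over every sequence of a repertoire. A
#' sequence of length L yields `max(0, L - 14)` windows; shorter sequences
#' yield none (logged via `message`, not an error). For padded records,
#' windows that overlap the `pad_len` terminal padding residues are flagged
#' `contains_padding` and dropped when `include_padding = FALSE`.
#'
#' The CDR3-relative position of a window is the position of its first
#' amino acid minus `cdr3_start`; the region label follows the same
#' first-amino-acid convention by default (see [assign_region()]).
#'
#' @param repertoire an [ighv_repertoire()].
#' @param include_padding keep windows overlapping terminal padding?
#' @param pad_len padding width assumed for padded records (default 3).
#' @param region_rule `"first_aa"` (default) or `"overlap"`.
#' @return data.frame with columns `peptide`, `record_id`, `patient_id`,
#'   `start`, `cdr3_relative_position`, `region_label`, `contains_padding`,
#'   `transcript_count`.
#' @export
enumerate_15mers <- function(repertoire, include_padding = TRUE,
                             pad_len = 3L, region_rule = "first_aa") {
  k <- 15L
  len <- nchar(repertoire$sequence)
  n_win <- pmax(0L, len - k + 1L)
  if (any(n_win == 0)) {
    message(sum(n_win == 0), " sequence(s) shorter than 15 residues yielded no windows")
  }
  keep <- which(n_win > 0)
  if (length(keep) == 0) return(empty_candidates())
  rec_idx <- rep.int(keep, n_win[keep])
  start <- unlist(lapply(n_win[keep], function(n) seq_len(n) - 1L),
                  use.names = FALSE)
  seqs <- repertoire$sequence[rec_idx]
  peptide <- substr(seqs, start + 1L, start + k)
  pad <- ifelse(repertoire$padded[rec_idx], pad_len, 0L)
  contains_padding <- start < pad | (start + k) > (nchar(seqs) - pad)
  out <- data.frame(
    peptide = peptide,
    record_id = repertoire$record_id[rec_idx],
    patient_id = repertoire$patient_id[rec_idx],
    start = start,
    cdr3_relative_position = start - repertoire$cdr3_start[rec_idx],
    region_label = assign_region(start,
                                 repertoire$cdr3_start[rec_idx],
                                 repertoire$cdr3_end[rec_idx],
                                 rule = region_rule),
    contains_padding = contains_padding,
    transcript_count = repertoire$transcript_count[rec_idx],
    stringsAsFactors = FALSE
  )
  if (!include_padding) out <- out[!out$contains_padding, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(peptide = character(), record_id = character(),
             patient_id = character(), start = integer(),
             cdr3_relative_position = integer(), region_label = character(),
             contains_padding = logical(), transcript_count = integer(),
             stringsAsFactors = FALSE)
}

#' Assign a region label to 15-mer windows
#'
#' Under `rule = "first_aa"` the label is the region containing the window's
#' first amino acid (the convention used for CDR3-relative positional maps):
#' FW3 before `cdr3_start`, CDR3 in `[cdr3_start, cdr3_end)`, FW4 after.
#' Under `rule = "overlap"` a window is labeled CDR3 whenever
#' `[start, start + 15)` intersects the CDR3 interval, otherwise FW3/FW4 by
#' side.
#'
#' @param start 0-based window start position(s).
#' @param cdr3_start,cdr3_end 0-based half-open CDR3 interval.
#' @param rule `"first_aa"` or `"overlap"`.
#' @return Character vector of labels.
#' @export
assign_region <- function(start, cdr3_start, cdr3_end, rule = "first_aa") {
  if (!rule %in% c("first_aa", "overlap")) {
    stop_idioscope("unknown region rule: %s", rule)
  }
  if (rule == "first_aa") {
    ifelse(start < cdr3_start, "FW3",
           ifelse(start < cdr3_end, "CDR3", "FW4"))
  } else {
    end <- start + 15L
    ifelse(start < cdr3_end & end > cdr3_start, "CDR3",
           ifelse(end <= cdr3_start, "FW3", "FW4"))
  }
}
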