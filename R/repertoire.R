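# IGHV repertoire container and I/O.
#
# A repertoire is a data.frame (class "ighv_repertoire") with one row per
# translated IGHV sequence. All coordinates are 0-based, half-open.

REPERTOIRE_COLS <- c("record_id", "patient_id", "sequence", "transcript_count",
                     "cdr3_start", "cdr3_end", "germline_sequence", "padded")

#' Construct an IGHV repertoire
#'
#' Builds and validates the central container of the package: a data.frame
#' with one row per translated IGHV amino-acid sequence. Sequences typically
#' span part of framework region 3 (FW3), the entire CDR3 and part of FW4.
#' CDR3 coordinates are 0-based, half-open: `cdr3_start` indexes the first
#' cysteine of CDR3, `cdr3_end` is the exclusive end.
#'
#' @param records data.frame with columns `record_id`, `patient_id`,
#'   `sequence`, `transcript_count`, `cdr3_start`, `cdr3_end`, and optionally
#'   `germline_sequence` (NA when no germline is assigned) and `padded`
#'   (logical; whether 3 residues were added at each terminus).
#' @return The validated data.frame with class `ighv_repertoire`.
#' @export
ighv_repertoire <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"germline_sequence" %in% names(records)) {
    records$germline_sequence <- NA_character_
  }
  if (!"padded" %in% names(records)) records$padded <- FALSE
  missing <- setdiff(REPERTOIRE_COLS, names(records))
  if (length(missing) > 0) {
    stop_idioscope("repertoire is missing columns: %s",
                   paste(missing, collapse = ", "))
  }
  records <- records[, REPERTOIRE_COLS]
  records$transcript_count <- as.integer(records$transcript_count)
  records$cdr3_start <- as.integer(records$cdr3_start)
  records$cdr3_end <- as.integer(records$cdr3_end)
  records$padded <- as.logical(records$padded)
  validate_repertoire(records)
  class(records) <- c("ighv_repertoire", "data.frame")
  rownames(records) <- NULL
  records
}

validate_repertoire <- function(records) {
  if (anyDuplicated(records$record_id)) {
    stop_idioscope("duplicate record_id values: %s",
                   paste(unique(records$record_id[duplicated(records$record_id)]),
                         collapse = ", "))
  }
  bad <- !valid_aa_string(records$sequence)
  if (any(bad)) {
    stop_idioscope("non-amino-acid characters in sequences of: %s",
                   paste(records$record_id[bad], collapse = ", "))
  }
  if (any(records$transcript_count < 0)) {
    stop_idioscope("negative transcript_count")
  }
  len <- nchar(records$sequence)
  bad_coord <- records$cdr3_start < 0 | records$cdr3_start >= records$cdr3_end |
    records$cdr3_end > len
  if (any(bad_coord)) {
    stop_idioscope("invalid CDR3 coordinates for: %s",
                   paste(records$record_id[bad_coord], collapse = ", "))
  }
  invisible(records)
}

#' Read an IGHV repertoire from FASTA plus metadata
#'
#' Sequences come from an amino-acid FASTA file; per-sequence metadata from a
#' tab-separated table keyed by FASTA ID (column `record_id`), with required
#' columns `patient_id`, `transcript_count`, `cdr3_start`, `cdr3_end` and
#' optional `germline_sequence` and `padded`. FASTA order is preserved.
#'
#' @param fasta_path path to an amino-acid FASTA file.
#' @param metadata_path path to the TSV metadata table.
#' @return An [ighv_repertoire()].
#' @export
read_repertoire <- function(fasta_path, metadata_path) {
  if (!file.exists(fasta_path)) stop_idioscope("FASTA not found: %s", fasta_path)
  if (!file.exists(metadata_path)) {
    stop_idioscope("metadata not found: %s", metadata_path)
  }
  seqs <- Biostrings::readAAStringSet(fasta_path)
  meta <- read.delim(metadata_path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = c(record_id = "character"))
  required <- c("record_id", "patient_id", "transcript_count",
                "cdr3_start", "cdr3_end")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0) {
    stop_idioscope("metadata is missing columns: %s",
                   paste(missing, collapse = ", "))
  }
  ids <- names(seqs)
  orphans <- setdiff(ids, meta$record_id)
  if (length(orphans) > 0) {
    stop_idioscope("FASTA entries missing from metadata: %s",
                   paste(orphans, collapse = ", "))
  }
  meta <- meta[match(ids, meta$record_id), , drop = FALSE]
  records <- data.frame(
    record_id = ids,
    patient_id = as.character(meta$patient_id),
    sequence = as.character(seqs),
    transcript_count = meta$transcript_count,
    cdr3_start = meta$cdr3_start,
    cdr3_end = meta$cdr3_end,
    germline_sequence = if ("germline_sequence" %in% names(meta)) {
      as.character(meta$germline_sequence)
    } else NA_character_,
    padded = if ("padded" %in% names(meta)) as.logical(meta$padded) else FALSE,
    stringsAsFactors = FALSE
  )
  ighv_repertoire(records)
}

#' Write an IGHV repertoire to FASTA plus metadata
#'
#' Inverse of [read_repertoire()]: field-level round trips are exact.
#'
#' @param repertoire an [ighv_repertoire()].
#' @param fasta_path,metadata_path output paths.
#' @return Invisibly, the repertoire.
#' @export
write_repertoire <- function(repertoire, fasta_path, metadata_path) {
  seqs <- Biostrings::AAStringSet(setNames(repertoire$sequence,
                                           repertoire$record_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  meta <- repertoire[, setdiff(REPERTOIRE_COLS, "sequence")]
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(repertoire)
}

#' Remove computational terminal padding
#'
#' Repertoires assembled for window enumeration sometimes carry `pad_len`
#' extra residues at each terminus. This removes them and shifts the CDR3
#' coordinates by `-pad_len`. Records already unpadded are returned as-is
#' with a warning; `pad_len = 0` is the identity.
#'
#' @param records an [ighv_repertoire()] (or any subset of its rows).
#' @param pad_len residues to remove from each terminus (default 3).
#' @return The repertoire with padding removed and `padded = FALSE`.
#' @export
strip_padding <- function(records, pad_len = 3L) {
  stopifnot(pad_len >= 0)
  if (pad_len == 0L) return(records)
  if (any(!records$padded)) {
    warning("strip_padding: some records are not padded; returned unchanged")
  }
  idx <- which(records$padded)
  if (length(idx) == 0) return(records)
  len <- nchar(records$sequence[idx])
  if (any(len <= 2 * pad_len)) {
    stop_idioscope("cannot strip %d-residue padding from sequences of length <= %d",
                   pad_len, 2 * pad_len)
  }
  records$sequence[idx] <- substr(records$sequence[idx], pad_len + 1L,
                                  len - pad_len)
  records$cdr3_start[idx] <- records$cdr3_start[idx] - pad_len
  records$cdr3_end[idx] <- records$cdr3_end[idx] - pad_len
  records$padded[idx] <- FALSE
  validate_repertoire(records)
  records
}

#' Add terminal padding residues
#'
#' Inverse of [strip_padding()]: prepends `left` and appends `right` to each
#' unpadded sequence, shifting CDR3 coordinates by `nchar(left)`.
#'
#' @param records repertoire rows with `padded = FALSE`.
#' @param left,right flank strings (default `"AAA"`, mirroring the 3-residue
#'   convention).
#' @return The repertoire with `padded = TRUE`.
#' @export
pad_records <- function(records, left = "AAA", right = "AAA") {
  if (any(records$padded)) stop_idioscope("records are already padded")
  if (nchar(left) != nchar(right)) {
    stop_idioscope("left and right flanks must have equal length")
  }
  records$sequence <- paste0(left, records$sequence, right)
  records$cdr3_start <- records$cdr3_start + nchar(left)
  records$cdr3_end <- records$cdr3_end + nchar(left)
  records$padded <- TRUE
  records
}
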