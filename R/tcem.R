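# T cell exposed motifs (TCEM): extraction from 15-mers and inverse-log2
# frequency classes over reference repertoires.
#
# A TCEM is the non-linear pentamer of residues that an HLA-II-bound peptide
# exposes to the T cell receptor. Motif positions are given relative to the
# 9-mer binding core; the IIa and IIb variants use different position masks.

#' Default TCEM position masks
#'
#' Core-relative, 0-based positions of the five T-cell-exposed residues.
#' `-1` denotes the residue immediately N-terminal of the 9-mer core. The
#' masks are configuration, not ground truth: pass alternatives to
#' [extract_tcem()] / [build_frequency_index()] to change the definition
#' everywhere downstream.
#'
#' @return Named list of two integer vectors (`IIa`, `IIb`).
#' @export
tcem_masks <- function() {
  list(IIa = c(2L, 3L, 5L, 7L, 8L),
       IIb = c(-1L, 3L, 5L, 7L, 8L))
}

#' Extract a TCEM pentamer from 15-mer peptides
#'
#' Applies the variant's position mask to the 9-mer binding core placed at
#' `core_start` within each 15-mer. Motifs reaching outside the peptide
#' (e.g. IIb's `-1` position with `core_start = 0`) or touching an `X`
#' residue are marked invalid (`NA` motif).
#'
#' @param peptides character vector of 15-mers.
#' @param core_start 0-based core offset(s) in `[0, 6]`; scalar or vector.
#' @param variant `"IIa"` or `"IIb"`.
#' @param masks mask configuration, see [tcem_masks()].
#' @return data.frame with `peptide`, `variant`, `core_start`, `motif`
#'   (`NA` when invalid), `valid`.
#' @export
extract_tcem <- function(peptides, core_start = 3L, variant = "IIa",
                         masks = tcem_masks()) {
  if (!variant %in% names(masks)) {
    stop_idioscope("unknown TCEM variant: %s", variant)
  }
  if (any(core_start < 0 | core_start > 6)) {
    stop_idioscope("core_start must lie in [0, 6]")
  }
  mask <- sort(as.integer(masks[[variant]]))
  n <- length(peptides)
  core_start <- rep_len(as.integer(core_start), n)
  pm <- peptide_matrix(peptides, 15L)
  pos0 <- outer(core_start, mask, "+")   # 0-based positions in the 15-mer
  in_range <- pos0 >= 0L & pos0 <= 14L
  res <- matrix(NA_character_, nrow = n, ncol = length(mask))
  ok <- which(in_range)
  res[ok] <- pm[cbind(row(pos0)[ok], pos0[ok] + 1L)]
  valid <- rowSums(!in_range) == 0 & rowSums(res == "X", na.rm = TRUE) == 0
  motif <- ifelse(valid, apply(res, 1, paste0, collapse = ""), NA_character_)
  data.frame(peptide = peptides, variant = variant, core_start = core_start,
             motif = motif, valid = valid, stringsAsFactors = FALSE)
}

#' Build a TCEM frequency index over reference repertoires
#'
#' For each reference set, a motif is counted once per IGHV sequence that
#' contains it (in any 15-mer window, both variants); the set's total is its
#' number of sequences. Using two or more independent reference sets guards
#' against intra-dataset bias; frequency classes are combined across sets by
#' [frequency_class()].
#'
#' @param references named list of [ighv_repertoire()] objects (unpadded).
#' @param core_start 0-based core offset used for motif extraction within
#'   each window (default 3, the central register).
#' @param masks mask configuration, see [tcem_masks()].
#' @param fc_cap frequency class assigned to motifs never observed in a set
#'   (default 24).
#' @return Object of class `tcem_index`.
#' @export
build_frequency_index <- function(references, core_start = 3L,
                                  masks = tcem_masks(), fc_cap = 24L) {
  if (length(references) == 0) stop_idioscope("need at least one reference set")
  if (is.null(names(references)) || any(!nzchar(names(references)))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  sets <- lapply(references, function(rep) {
    if (nrow(rep) == 0) stop_idioscope("empty reference repertoire")
    cand <- enumerate_15mers(rep, include_padding = FALSE)
    keys <- character(0)
    for (v in names(masks)) {
      tc <- extract_tcem(cand$peptide, core_start = core_start, variant = v,
                         masks = masks)
      ok <- tc$valid
      keys <- c(keys, unique(paste(v, tc$motif[ok], cand$record_id[ok],
                                   sep = "\r")))
    }
    # one count per (variant, motif, sequence): strip the record id and
    # tabulate motif keys
    motif_key <- sub("\r[^\r]*$", "", keys)
    counts <- table(motif_key)
    list(counts = setNames(as.integer(counts), names(counts)),
         total = nrow(rep))
  })
  structure(list(sets = sets, core_start = core_start, masks = masks,
                 fc_cap = as.integer(fc_cap)),
            class = "tcem_index")
}

#' Construct a TCEM frequency index from explicit counts
#'
#' Lower-level companion of [build_frequency_index()] for building an index
#' from tabulated motif counts (e.g. read back from disk, or constructed
#' for calibration).
#'
#' @param counts data.frame with columns `set`, `variant`, `motif`,
#'   `count`.
#' @param totals named numeric vector: sequences per reference set.
#' @param core_start,masks,fc_cap as in [build_frequency_index()].
#' @return Object of class `tcem_index`.
#' @export
tcem_index <- function(counts, totals, core_start = 3L,
                       masks = tcem_masks(), fc_cap = 24L) {
  sets <- lapply(setNames(nm = names(totals)), function(s) {
    sub <- counts[counts$set == s, , drop = FALSE]
    if (any(sub$count > totals[[s]])) {
      stop_idioscope("count exceeds total in set %s", s)
    }
    list(counts = setNames(as.integer(sub$count),
                           paste(sub$variant, sub$motif, sep = "\r")),
         total = as.integer(totals[[s]]))
  })
  structure(list(sets = sets, core_start = as.integer(core_start),
                 masks = masks, fc_cap = as.integer(fc_cap)),
            class = "tcem_index")
}

#' Serialize a TCEM frequency index to TSV
#' @param index a `tcem_index`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tcem_index <- function(index, path) {
  rows <- lapply(names(index$sets), function(s) {
    k <- names(index$sets[[s]]$counts)
    vm <- do.call(rbind, strsplit(k, "\r", fixed = TRUE))
    data.frame(set = s, variant = vm[, 1], motif = vm[, 2],
               count = unname(index$sets[[s]]$counts),
               total = index$sets[[s]]$total, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a TCEM frequency index from TSV
#' @param path TSV written by [write_tcem_index()].
#' @param core_start,masks,fc_cap as in [build_frequency_index()].
#' @return Object of class `tcem_index`.
#' @export
read_tcem_index <- function(path, core_start = 3L, masks = tcem_masks(),
                            fc_cap = 24L) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  totals <- vapply(split(tab$total, tab$set), function(x) x[1], numeric(1))
  tcem_index(tab, totals, core_start = core_start, masks = masks,
             fc_cap = fc_cap)
}

#' @export
print.tcem_index <- function(x, ...) {
  cat("TCEM frequency index:", length(x$sets), "reference set(s)\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %s: %d motifs over %d sequences\n", nm,
                length(x$sets[[nm]]$counts), x$sets[[nm]]$total))
  }
  invisible(x)
}

#' Frequency class of TCEM motifs
#'
#' Within one reference set, a motif observed in `count` of `total`
#' sequences gets frequency class `floor(-log2(count / total))`; class k
#' means the motif occurs no more often than once per 2^k sequences (class
#' 17 is the 1-in-131,072 boundary). Motifs never observed get the index's
#' `fc_cap`. Classes are combined across reference sets by taking the
#' minimum (the most frequent observation wins), so the combined class is
#' conservative towards tolerance.
#'
#' @param motifs character vector of pentamer motifs (`NA` allowed,
#'   propagates).
#' @param variant motif variant(s), `"IIa"`/`"IIb"`; scalar or vector.
#' @param index a [build_frequency_index()] result.
#' @return Integer vector of combined frequency classes.
#' @export
frequency_class <- function(motifs, variant, index) {
  stopifnot(inherits(index, "tcem_index"))
  n <- length(motifs)
  variant <- rep_len(variant, n)
  key <- paste(variant, motifs, sep = "\r")
  per_set <- vapply(index$sets, function(s) {
    count <- s$counts[key]
    count[is.na(count)] <- 0L
    fc <- ifelse(count == 0, index$fc_cap,
                 pmin(floor(-log2(count / s$total)), index$fc_cap))
    as.numeric(fc)
  }, numeric(n))
  per_set <- matrix(per_set, nrow = n)
  out <- as.integer(apply(per_set, 1, min))
  out[is.na(motifs)] <- NA_integer_
  out
}

#' Combined TCEM frequency class of candidate 15-mers
#'
#' Extracts both mask variants at the given core placement and returns, per
#' peptide, the minimum combined frequency class over the valid variants
#' (again conservative towards the more frequent motif). Peptides with no
#' valid motif return `NA`.
#'
#' @param peptides character vector of 15-mers.
#' @param index a [build_frequency_index()] result.
#' @param core_start core offset(s); defaults to the index's.
#' @return Integer vector of frequency classes.
#' @export
candidate_fc <- function(peptides, index, core_start = NULL) {
  stopifnot(inherits(index, "tcem_index"))
  core_start <- core_start %||% index$core_start
  fc <- rep(NA_integer_, length(peptides))
  for (v in names(index$masks)) {
    tc <- extract_tcem(peptides, core_start = core_start, variant = v,
                       masks = index$masks)
    fcv <- frequency_class(tc$motif, v, index)
    fc <- pmin(fc, fcv, na.rm = TRUE)
  }
  fc
}
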