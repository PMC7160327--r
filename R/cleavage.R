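# Cathepsin S/L/B bond-cleavage prediction and 15-mer release feasibility.
#
# Bond i (0-based) is the peptide bond between residues i and i+1 of the
# source sequence. Release of a 15-mer starting at s requires plausible
# cuts near its N-terminal bond (s-1) and C-terminal bond (s+14); the
# "fuzzy" flank window admits cuts a few bonds away, mirroring how class II
# grooves accept peptides of varying length.

CATHEPSINS <- c("S", "L", "B")

#' Generate surrogate cathepsin dipeptide cleavage tables
#'
#' One synthetic 20x20 table per cathepsin giving the cleavage probability
#' of a bond as a function of its P1 (row) and P1' (column) residues.
#' Entries are sparse-high: most bonds are poorly cleavable and a small
#' fraction (`hot_frac`) are good substrates, as for real S1/S1' pocket
#' specificity. Deterministic for a fixed seed; used to produce the TSVs
#' shipped in `inst/extdata`.
#'
#' @param cathepsins subset of `c("S", "L", "B")`.
#' @param seed RNG seed (the shipped files use 240117).
#' @param hot_frac fraction of dipeptides that are good substrates.
#' @return Named list of 20x20 matrices.
#' @export
make_surrogate_cleavage <- function(cathepsins = CATHEPSINS, seed = 240117,
                                    hot_frac = 0.07) {
  aa <- amino_acids()
  set.seed(seed)
  out <- lapply(cathepsins, function(c) {
    hot <- runif(400) < hot_frac
    p <- ifelse(hot, runif(400, 0.6, 0.95), runif(400, 0.01, 0.25))
    matrix(p, nrow = 20, dimnames = list(aa, aa))
  })
  names(out) <- cathepsins
  out
}

#' Load the surrogate cleavage model
#'
#' Reads per-cathepsin 20x20 dipeptide probability tables from TSV files
#' (`cathepsin_S.tsv` etc., rows = P1 residue, columns = P1' residue).
#'
#' @param dir directory holding the TSVs (default: shipped tables).
#' @param cathepsins subset of `c("S", "L", "B")`.
#' @return Object of class `cleavage_model`.
#' @export
surrogate_cleavage_model <- function(dir = system.file("extdata",
                                                       package = "idioscope"),
                                     cathepsins = CATHEPSINS) {
  tables <- lapply(cathepsins, function(c) {
    tab <- read.delim(file.path(dir, sprintf("cathepsin_%s.tsv", c)),
                      row.names = 1, check.names = FALSE)
    as.matrix(tab)[amino_acids(), amino_acids()]
  })
  names(tables) <- cathepsins
  structure(list(name = "surrogate_dipeptide", tables = tables),
            class = "cleavage_model")
}

#' Build a cleavage model from in-memory tables
#' @param tables named list of 20x20 matrices, e.g.
#'   [make_surrogate_cleavage()].
#' @param name model name.
#' @return Object of class `cleavage_model`.
#' @export
cleavage_model <- function(tables, name = "dipeptide") {
  structure(list(name = name, tables = tables), class = "cleavage_model")
}

#' Write surrogate cleavage tables to TSV
#' @param tables named list of 20x20 matrices.
#' @param dir output directory.
#' @return Invisibly, `dir`.
#' @export
write_surrogate_cleavage <- function(tables, dir) {
  for (c in names(tables)) {
    write.table(round(tables[[c]], 4),
                file.path(dir, sprintf("cathepsin_%s.tsv", c)),
                sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(dir)
}

#' Per-bond cathepsin cleavage probabilities of a sequence
#'
#' @param model a `cleavage_model`.
#' @param sequence amino-acid string (length >= 2).
#' @param cathepsin one of the model's cathepsins.
#' @return Numeric vector of length `nchar(sequence) - 1`: element i is the
#'   probability of cleaving the bond between residues i and i+1 (1-based;
#'   0-based bond i-1). Bonds involving `X` get probability 0.
#' @export
predict_cleavage <- function(model, sequence, cathepsin) {
  stopifnot(inherits(model, "cleavage_model"))
  if (!cathepsin %in% names(model$tables)) {
    stop_idioscope("unknown cathepsin '%s'; available: %s", cathepsin,
                   paste(names(model$tables), collapse = ", "))
  }
  L <- nchar(sequence)
  if (L < 2) stop_idioscope("sequence too short for cleavage prediction")
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- model$tables[[cathepsin]]
  i <- match(aa[-L], rownames(tab))
  j <- match(aa[-1], colnames(tab))
  p <- tab[cbind(i, j)]
  p[is.na(p)] <- 0
  p
}

#' Cleavage profiles for all cathepsins of a model
#' @param model a `cleavage_model`.
#' @param sequence amino-acid string.
#' @return Named list of per-bond probability vectors.
#' @export
cleavage_profiles <- function(model, sequence) {
  lapply(setNames(nm = names(model$tables)),
         function(c) predict_cleavage(model, sequence, c))
}

#' Assess release feasibility of 15-mer candidates
#'
#' Liberal mode: a candidate is released by cathepsin c when the maximum
#' bond probability within `flank_window` bonds of EACH terminus reaches
#' `cut_liberal` for c (same cathepsin at both ends by default; set
#' `mixed_cathepsins = TRUE` to allow different enzymes per end). Strict
#' mode: a candidate is inert-eligible only when NO cathepsin reaches
#' `cut_strict` at any bond near either terminus. Flank windows are
#' truncated to the bonds that exist when a candidate sits at a sequence
#' edge. `intra_destruction_prob` is the maximum probability over bonds
#' strictly inside the 15-mer, any cathepsin — reported as an annotation,
#' not used as a filter.
#'
#' @param starts 0-based candidate start position(s) in the source sequence.
#' @param profiles named list of per-bond probability vectors (one per
#'   cathepsin), from [cleavage_profiles()].
#' @param flank_window bonds admitted on each side of a terminus (default 3).
#' @param cut_liberal,cut_strict probability cut-offs (defaults 0.5, 0.3).
#' @param mixed_cathepsins allow release with different cathepsins at the
#'   two termini?
#' @return data.frame with `start`, `released_by` (comma-separated, "" if
#'   none), `liberal_released`, `strict_eligible`, `n_terminal_cut_prob`,
#'   `c_terminal_cut_prob`, `intra_destruction_prob`.
#' @export
assess_release <- function(starts, profiles, flank_window = 3L,
                           cut_liberal = 0.5, cut_strict = 0.3,
                           mixed_cathepsins = FALSE) {
  nb <- length(profiles[[1]])        # number of bonds = L - 1
  caths <- names(profiles)
  win_max <- function(p, center) {
    # max of bond vector p over 0-based bonds [center - fw, center + fw],
    # truncated to existing bonds; -Inf when the window is empty
    lo <- pmax(center - flank_window, 0L)
    hi <- pmin(center + flank_window, nb - 1L)
    vapply(seq_along(center), function(i) {
      if (lo[i] > hi[i]) return(-Inf)
      max(p[(lo[i] + 1L):(hi[i] + 1L)])
    }, numeric(1))
  }
  starts <- as.integer(starts)
  n_bond <- starts - 1L          # 0-based N-terminal bond
  c_bond <- starts + 14L         # 0-based C-terminal bond
  n_max <- lapply(profiles, win_max, center = n_bond)
  c_max <- lapply(profiles, win_max, center = c_bond)
  rel <- vapply(caths, function(c) {
    pmin(n_max[[c]], c_max[[c]]) >= cut_liberal
  }, logical(length(starts)))
  rel <- matrix(rel, ncol = length(caths), dimnames = list(NULL, caths))
  released_by <- apply(rel, 1, function(r) paste(caths[r], collapse = ","))
  liberal <- rowSums(rel) > 0
  if (mixed_cathepsins) {
    n_any <- do.call(pmax, n_max)
    c_any <- do.call(pmax, c_max)
    liberal <- liberal | (n_any >= cut_liberal & c_any >= cut_liberal)
  }
  strict <- vapply(caths, function(c) {
    pmax(n_max[[c]], c_max[[c]]) < cut_strict
  }, logical(length(starts)))
  strict <- rowSums(matrix(strict, ncol = length(caths))) == length(caths)
  intra <- vapply(seq_along(starts), function(i) {
    lo <- starts[i] + 1L; hi <- starts[i] + 14L   # 1-based bond indices
    lo <- max(lo, 1L); hi <- min(hi, nb)
    if (lo > hi) return(0)
    max(vapply(profiles, function(p) max(p[lo:hi]), numeric(1)))
  }, numeric(1))
  data.frame(
    start = starts,
    released_by = released_by,
    liberal_released = liberal,
    strict_eligible = strict,
    n_terminal_cut_prob = do.call(pmax, n_max),
    c_terminal_cut_prob = do.call(pmax, c_max),
    intra_destruction_prob = intra,
    stringsAsFactors = FALSE
  )
}
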