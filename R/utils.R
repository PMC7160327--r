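# Shared constants and small helpers.

#' Standard amino-acid alphabet
#'
#' The twenty standard one-letter residue codes, in alphabetical order.
#' Translated NGS repertoires may additionally contain `X` (ambiguous
#' residue); windows containing `X` are excluded from scoring.
#'
#' @return Character vector of length 20.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a vector of equal-length peptides into a character matrix
# (one row per peptide, one column per position).
peptide_matrix <- function(peptides, width) {
  stopifnot(all(nchar(peptides) == width))
  matrix(unlist(strsplit(peptides, "", fixed = TRUE), use.names = FALSE),
         ncol = width, byrow = TRUE)
}

valid_aa_string <- function(x, allow_x = TRUE) {
  alphabet <- amino_acids()
  if (allow_x) alphabet <- c(alphabet, "X")
  pattern <- sprintf("^[%s]*$", paste(alphabet, collapse = ""))
  grepl(pattern, x)
}

# Discrete power-law sampler used for clonal transcript-count skew:
# P(X = k) proportional to k^(-alpha), sampled by inverse transform of the
# continuous Pareto and floored, capped to keep counts finite.
rpowerlaw <- function(n, alpha = 1.5, xmax = 10000) {
  u <- runif(n)
  x <- floor(u^(-1 / (alpha - 1)))
  pmin(pmax(x, 1), xmax)
}

stop_idioscope <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
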