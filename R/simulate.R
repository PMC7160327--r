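# Synthetic-data module: IGHV repertoires with known germlines and planted
# somatic mutations, patient HLA typings, and gated flow-cytometry counts
# with planted responder populations. Everything is reproducible from the
# seed.

#' Built-in germline template pool
#'
#' Synthetic IGHV-like templates (not real IMGT alleles) with the
#' FW3-CDR3-FW4 architecture of the sequenced fragment: a framework-3
#' stretch ending just before the canonical CDR3-opening cysteine, a
#' CDR3 whose junctional middle is generated per clone, and a framework-4
#' stretch starting at the conserved tryptophan. Framework residues are
#' shared across many sequences (so their TCEM are frequent); CDR3 middles
#' are clone-private (so their TCEM are rare).
#'
#' @return data.frame `template_id`, `fw3`, `cdr3_prefix`, `fw4`.
#' @export
germline_templates <- function() {
  data.frame(
    template_id = sprintf("TPL%02d", 1:6),
    fw3 = c("SLRAEDTAVYY", "TLRAEDTGVYY", "SLSSEDTAVYY",
            "KLSSVTAADTA", "QMNSLRAEDTA", "TLYLQMNSLRA"),
    cdr3_prefix = c("CAR", "CAK", "CAR", "CVR", "CAR", "CTT"),
    fw4 = c("WGQGTLVTVSS", "WGQGTTVTVSS", "WGRGTLVTVSS",
            "WGQGVLVTVSS", "WGKGTTVTVSS", "WGQGTMVTVSS"),
    stringsAsFactors = FALSE)
}

#' Simulate an IGHV repertoire with known ground truth
#'
#' Per patient, draws a sequence count from a truncated normal (defaults
#' match CSF IGHV repertoires: mean 1,079, SD 1,213, minimum 30), builds
#' each sequence from a germline template with a clone-private CDR3 middle
#' (total length uniform in `length_range`), applies somatic hypermutation
#' at `shm_rate` per position (sparing the CDR3-opening cysteine and the
#' FW4 tryptophan anchors), and assigns power-law transcript counts to
#' emulate clonal-expansion skew. The unmutated clone sequence is stored as
#' the record's germline, and every planted substitution is returned as
#' ground truth.
#'
#' @param n_patients number of patients (default 9).
#' @param seqs_mean,seqs_sd,min_seqs per-patient sequence count
#'   distribution (defaults 1079 / 1213 / 30).
#' @param length_range total sequence length range (default 30-45).
#' @param shm_rate per-position substitution probability (default 0.04).
#' @param clone_abundance_alpha power-law exponent of transcript counts
#'   (default 1.5).
#' @param templates germline template pool (default
#'   [germline_templates()]).
#' @param seed RNG seed (mandatory).
#' @return List: `repertoire` (an [ighv_repertoire()], unpadded),
#'   `mutations` (data.frame `record_id`, `position` (0-based),
#'   `germline_aa`, `mutated_aa`).
#' @export
simulate_repertoire <- function(n_patients = 9, seqs_mean = 1079,
                                seqs_sd = 1213, min_seqs = 30,
                                length_range = c(30, 45), shm_rate = 0.04,
                                clone_abundance_alpha = 1.5,
                                templates = germline_templates(), seed) {
  if (missing(seed)) stop_idioscope("seed is mandatory")
  if (length_range[1] < 15) stop_idioscope("minimum length below 15")
  if (shm_rate < 0 || shm_rate > 1) stop_idioscope("shm_rate outside [0, 1]")
  set.seed(seed)
  aa <- amino_acids()
  min_len <- min(nchar(templates$fw3) + nchar(templates$cdr3_prefix) +
                   nchar(templates$fw4)) + 1
  if (length_range[1] < min_len) {
    stop_idioscope("length_range[1] must be at least %d for these templates",
                   min_len)
  }
  recs <- list(); muts <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("MS-%02d", p)
    n_seq <- max(min_seqs, round(rnorm(1, seqs_mean, seqs_sd)))
    t_idx <- sample(nrow(templates), n_seq, replace = TRUE)
    len <- sample(length_range[1]:length_range[2], n_seq, replace = TRUE)
    for (i in seq_len(n_seq)) {
      tpl <- templates[t_idx[i], ]
      fixed_len <- nchar(tpl$fw3) + nchar(tpl$cdr3_prefix) + nchar(tpl$fw4)
      mid_len <- max(1, len[i] - fixed_len)
      middle <- paste(sample(aa, mid_len, replace = TRUE), collapse = "")
      germ <- paste0(tpl$fw3, tpl$cdr3_prefix, middle, tpl$fw4)
      cdr3_start <- nchar(tpl$fw3)
      cdr3_end <- cdr3_start + nchar(tpl$cdr3_prefix) + mid_len
      g <- strsplit(germ, "", fixed = TRUE)[[1]]
      mutable <- setdiff(seq_along(g), c(cdr3_start + 1L, cdr3_end + 1L))
      hit <- mutable[runif(length(mutable)) < shm_rate]
      s <- g
      rid <- sprintf("%s_seq%05d", pid, i)
      if (length(hit) > 0) {
        for (h in hit) s[h] <- sample(setdiff(aa, g[h]), 1)
        muts[[length(muts) + 1]] <- data.frame(
          record_id = rid, position = hit - 1L, germline_aa = g[hit],
          mutated_aa = s[hit], stringsAsFactors = FALSE)
      }
      recs[[length(recs) + 1]] <- data.frame(
        record_id = rid, patient_id = pid,
        sequence = paste(s, collapse = ""),
        transcript_count = rpowerlaw(1, clone_abundance_alpha),
        cdr3_start = cdr3_start, cdr3_end = cdr3_end,
        germline_sequence = germ, padded = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  list(repertoire = ighv_repertoire(do.call(rbind, recs)),
       mutations = if (length(muts) > 0) do.call(rbind, muts) else
         data.frame(record_id = character(), position = integer(),
                    germline_aa = character(), mutated_aa = character()))
}

#' Simulate patient HLA class II typings
#'
#' Assigns each patient two DR, two DQ and two DP alleles drawn without
#' replacement from the surrogate model's allele panel.
#'
#' @param patient_ids patient identifiers.
#' @param alleles allele pool (default [default_hla_alleles()]).
#' @param seed RNG seed.
#' @return A [hla_table()].
#' @export
simulate_hla <- function(patient_ids, alleles = default_hla_alleles(), seed) {
  if (missing(seed)) stop_idioscope("seed is mandatory")
  set.seed(seed)
  locus <- hla_locus(alleles)
  rows <- lapply(patient_ids, function(p) {
    picked <- unlist(lapply(c("DR", "DQ", "DP"), function(l) {
      sample(alleles[locus == l], 2)
    }))
    data.frame(patient_id = p, allele = picked, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  hla_table(tab$patient_id, tab$allele)
}

#' Simulate gated flow-cytometry counts for a stimulus panel
#'
#' Emulates the activation-induced-marker assay: per patient, a
#' memory-cell fraction drawn uniformly from `memory_fraction_range`
#' (default 0.32-0.68) of the gated CD4 T cells from `cells_per_well`
#' PBMC; per stimulus and replicate, CD154+ counts drawn binomially at the
#' patient's background rate plus any planted responder frequency; and
#' CCR6/CXCR3 marker counts within CD154+ and CD154- memory cells, with
#' configurable CCR6 enrichment among responders. Control stimuli
#' (`unstimulated`, `insulin`, `EBNA1`, `CD3CD28`) are included.
#'
#' @param stimuli data.frame `stimulus`, `category` (the per-patient
#'   stimulus set, e.g. 22 peptides; controls are added automatically).
#' @param patient_ids patient identifiers.
#' @param cells_per_well PBMC per well (default 500000).
#' @param cd4_fraction fraction of PBMC in the CD3+CD4+CD8- gate (default
#'   0.25).
#' @param memory_fraction_range CD45RO+ fraction range (default
#'   `c(0.32, 0.68)`).
#' @param background_rate CD154+ background rate among memory cells
#'   (default 0.001).
#' @param patient_sd lognormal SD of the per-patient background multiplier
#'   (default 0.3; models interpatient variation in activation).
#' @param category_enrichment additive CD154+ rate increments per category
#'   (defaults: stimulatory 0.0022, tolerogenic 0.0038, inert 0 — the
#'   adjusted mean group differences of the motivating study, on the
#'   proportion scale).
#' @param naive_factor responder enrichment in naive cells as a fraction of
#'   the memory enrichment (default 0.25).
#' @param planted_responders optional data.frame `patient_id`, `stimulus`,
#'   `rate`: overrides the category enrichment with an absolute responder
#'   frequency for those wells.
#' @param ccr6_background,ccr6_activated CCR6+ fractions among CD154- and
#'   CD154+ memory cells (defaults 0.30, 0.55).
#' @param cxcr3_background,cxcr3_activated CXCR3+ fractions (defaults
#'   0.40, 0.40: no enrichment).
#' @param replicates technical replicates per well (default 2).
#' @param seed RNG seed (mandatory).
#' @return List: `flow` (tidy count table), `truth` (data.frame of wells
#'   whose true rate exceeds background).
#' @export
simulate_flow_counts <- function(stimuli, patient_ids,
                                 cells_per_well = 500000,
                                 cd4_fraction = 0.25,
                                 memory_fraction_range = c(0.32, 0.68),
                                 background_rate = 0.001,
                                 patient_sd = 0.3,
                                 category_enrichment = c(stimulatory = 0.0022,
                                                         tolerogenic = 0.0038,
                                                         inert = 0),
                                 naive_factor = 0.25,
                                 planted_responders = NULL,
                                 ccr6_background = 0.30,
                                 ccr6_activated = 0.55,
                                 cxcr3_background = 0.40,
                                 cxcr3_activated = 0.40,
                                 replicates = 2, seed) {
  if (missing(seed)) stop_idioscope("seed is mandatory")
  if (!is.null(planted_responders) && any(planted_responders$rate > 1)) {
    stop_idioscope("planted responder frequency above 1")
  }
  set.seed(seed)
  controls <- data.frame(
    stimulus = c("unstimulated", "insulin", "EBNA1", "CD3CD28"),
    category = "control", stringsAsFactors = FALSE)
  stim_all <- rbind(controls, stimuli[, c("stimulus", "category")])
  rows <- list(); truth <- list()
  for (p in patient_ids) {
    mem_frac <- runif(1, memory_fraction_range[1], memory_fraction_range[2])
    bg_p <- background_rate * exp(rnorm(1, 0, patient_sd))
    ebna_responder <- runif(1) < 1 / 3
    for (s in seq_len(nrow(stim_all))) {
      stim <- stim_all$stimulus[s]
      cat <- stim_all$category[s]
      extra <- switch(stim,
                      unstimulated = 0, insulin = 0,
                      EBNA1 = if (ebna_responder) 4 * bg_p else 0,
                      CD3CD28 = 0.45,
                      category_enrichment[[cat]])
      if (!is.null(planted_responders)) {
        hit <- planted_responders$patient_id == p &
          planted_responders$stimulus == stim
        if (any(hit)) extra <- planted_responders$rate[hit][1]
      }
      rate_mem <- min(bg_p + extra, 1)
      rate_nai <- min(bg_p + naive_factor * extra, 1)
      if (extra > 0) {
        truth[[length(truth) + 1]] <- data.frame(
          patient_id = p, stimulus = stim, rate = rate_mem,
          stringsAsFactors = FALSE)
      }
      for (r in seq_len(replicates)) {
        cd4 <- rbinom(1, cells_per_well, cd4_fraction)
        memory <- rbinom(1, cd4, mem_frac)
        naive <- cd4 - memory
        cd154_mem <- rbinom(1, memory, rate_mem)
        cd154_nai <- rbinom(1, naive, rate_nai)
        cd154neg_mem <- memory - cd154_mem
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = p, stimulus = stim, category = cat, replicate = r,
          cd4_total = cd4, memory = memory, naive = naive,
          cd154_memory = cd154_mem, cd154_naive = cd154_nai,
          cd154neg_memory = cd154neg_mem,
          ccr6_cd154pos = rbinom(1, cd154_mem, ccr6_activated),
          cxcr3_cd154pos = rbinom(1, cd154_mem, cxcr3_activated),
          ccr6_cd154neg = rbinom(1, cd154neg_mem, ccr6_background),
          cxcr3_cd154neg = rbinom(1, cd154neg_mem, cxcr3_background),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(flow = do.call(rbind, rows),
       truth = if (length(truth) > 0) do.call(rbind, truth) else
         data.frame(patient_id = character(), stimulus = character(),
                    rate = numeric()))
}
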