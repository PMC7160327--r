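#!/usr/bin/env Rscript
# Stage 3: select per-patient peptide panels.
#
# Ten stimulatory and five tolerogenic peptides per patient from that
# patient's own repertoire (abundance-ranked, deduplicated, with stepwise
# affinity relaxation when a band is short), plus one shared panel of
# seven inert peptides valid against every patient's class II alleles.

library(idioscope)

scored <- read.delim("scratch/scored_candidates.tsv",
                     stringsAsFactors = FALSE)
sel <- build_all_panels(scored, selection_criteria())
write.table(sel$table, "results/03_panels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

counts <- table(sel$table$panel_patient, sel$table$category)
cat("Selected peptides per patient and category:\n")
print(counts)
n_stimuli <- length(unique(sel$table$peptide[sel$table$category == "inert"])) +
  max(table(sel$table$panel_patient[sel$table$category != "inert"]))
cat(sprintf("Stimulus set per patient: %d peptides\n", n_stimuli))

relaxed <- unique(sel$table[!is.na(sel$table$relaxed_threshold_used),
                            c("panel_patient", "category",
                              "relaxed_threshold_used")])
if (nrow(relaxed) > 0) {
  cat("Affinity threshold relaxations used:\n")
  print(relaxed, row.names = FALSE)
} else {
  cat("No affinity relaxation was needed.\n")
}

# region of origin per category (stimulatory panels should map mainly to
# CDR3, tolerogenic to the framework)
origin <- table(sel$table$category, sel$table$region_label)
write.table(as.data.frame(origin), "results/03_panel_regions.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
print(origin)
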