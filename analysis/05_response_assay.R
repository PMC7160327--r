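#!/usr/bin/env Rscript
# Stage 5: simulate the activation-induced-marker assay on the selected
# panels and analyze it.
#
# Flow counts are drawn for every patient x stimulus x replicate with the
# generator's default responder enrichments (the study's adjusted group
# differences on the proportion scale), activation metrics and 3x
# positivity calls computed, the category contrast estimated with a
# patient random-intercept mixed model, and CCR6/CXCR3 enrichment among
# activated memory cells assessed.

library(idioscope)

panels <- read.delim("results/03_panels.tsv", stringsAsFactors = FALSE)
patients <- sort(unique(panels$panel_patient[panels$panel_patient !=
                                               "shared"]))
inert <- panels[panels$panel_patient == "shared", c("peptide", "category")]

# each patient is stimulated with their own 15 antigenic peptides plus the
# 7 shared inert controls (22 stimuli), as in the assay design
fl <- do.call(function(...) {
  parts <- list(...)
  list(flow = do.call(rbind, lapply(parts, `[[`, "flow")),
       truth = do.call(rbind, lapply(parts, `[[`, "truth")))
}, lapply(seq_along(patients), function(i) {
  own <- panels[panels$panel_patient == patients[i],
                c("peptide", "category")]
  stimuli <- rbind(own, inert)
  names(stimuli)[1] <- "stimulus"
  simulate_flow_counts(stimuli, patients[i], seed = 20501 + i)
}))
write.table(fl$flow, "scratch/flow_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ar <- activation_results(fl$flow)
write.table(ar, "results/05_activation_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

pep <- ar[ar$category != "control", ]
cat(sprintf("Positive responses: %d of %d peptide wells (%d patients with >= 1)\n",
            sum(pep$positive), nrow(pep),
            length(unique(pep$patient_id[pep$positive]))))
print(table(pep$category, pep$positive))

cmp <- compare_groups(pep)
print(cmp)
pw <- cmp$pairwise
jsonlite::write_json(list(
  pairwise = pw, var_patient = cmp$var_patient,
  var_residual = cmp$var_residual, singular = cmp$singular),
  "results/05_group_comparison.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows")

pos <- pep[pep$positive, c("patient_id", "stimulus")]
ce <- chemokine_enrichment(fl$flow, pos)
write.table(ce, "results/05_chemokine_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Chemokine-receptor enrichment on activated (CD154+) memory cells:\n")
print(ce, row.names = FALSE)
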