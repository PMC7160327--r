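#!/usr/bin/env Rscript
# Stage 4: impute somatic-mutation effects on the selected antigenic
# peptides.
#
# Each stimulatory/tolerogenic panel member is compared against its
# germline counterpart: per-DR-allele ln(IC50) direction (> 0.1 change),
# cathepsin S/B terminal cleavage direction within +/- 3 bonds (> 0.1
# change), and the TCEM frequency-class shift; the net effect is
# classified improved / mixed / negative / unchanged. Inert peptides are
# not patient-specific and are left out.

library(idioscope)

rep <- read_repertoire("scratch/sim/repertoire.fasta",
                       "scratch/sim/repertoire.tsv")
hla_tab <- read.delim("scratch/sim/hla.tsv", stringsAsFactors = FALSE)
hla <- hla_table(hla_tab$patient_id, hla_tab$allele)
panels <- read.delim("results/03_panels.tsv", stringsAsFactors = FALSE)
idx <- read_tcem_index("scratch/tcem_index.tsv")

own <- panels[panels$category != "inert", ]
deltas <- germline_deltas(own, rep, hla,
                          affinity = surrogate_affinity_model(),
                          cleavage = surrogate_cleavage_model(),
                          tcem = idx)
write.table(deltas, "results/04_germline_deltas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Net imputed effect of somatic mutations on the antigenic panels:\n")
print(table(deltas$net_effect, useNA = "ifany"))
cat(sprintf("Mean TCEM frequency-class shift (mutated - germline): %.2f\n",
            mean(deltas$delta_fc, na.rm = TRUE)))
cat(sprintf("Windows with mutations in the 15-mer: %d of %d; flank only: %d\n",
            sum(deltas$mutations_in_window > 0), nrow(deltas),
            sum(deltas$mutations_in_window == 0 &
                  deltas$mutations_in_flank > 0)))
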