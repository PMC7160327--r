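# idioscope

In silico prioritization of B-cell receptor (BCR) idiotopes for HLA
class II presentation, and analysis of the activation-induced-marker
assay that tests them.

## What problem this solves

B cells in the cerebrospinal fluid of multiple sclerosis patients
display peptides from their own immunoglobulin heavy-chain variable
(IGHV) regions — *idiotopes* — on HLA class II. Which of the many
thousands of candidate peptides in a patient's repertoire could actually
activate CD4+ T cells? `idioscope` answers this with three predicted
bottlenecks, applied to every 15-mer window of a translated IGHV
repertoire (fragments spanning part of FW3, all of CDR3, part of FW4):

1. **HLA class II affinity** — best 9-mer register score, standardized
   per allele with a Johnson S_U quantile fit (robust-z fallback), so
   that a single threshold (`< -1.5` strong, `> +1` weak) is meaningful
   across alleles;
2. **cathepsin release** — fuzzy cleavage logic on cathepsin S/L/B
   per-bond probabilities: a *liberal* call needs plausible cuts
   (p ≥ 0.5 within ±3 bonds) at both termini, a *strict* call requires
   no cut (p ≥ 0.3) by any cathepsin near either terminus;
3. **T-cell exposed motif (TCEM) rarity** — the pentamer the TCR sees,
   binned by inverse-log2 frequency class over reference repertoires:
   class k ⇔ at most once per 2^k sequences. FC ≥ 17 (once per 131,072)
   marks rare, potentially stimulatory motifs; FC ≤ 7 (once per 128)
   frequent, potentially tolerogenic ones.

From candidates passing these filters it selects, per patient, the 10
most transcript-abundant *stimulatory* and 5 *tolerogenic* peptides
(deduplicated; affinity limit relaxed stepwise when a band runs short)
plus a panel of 7 *inert* control peptides shared across patients — 22
stimuli per patient. Downstream modules impute the effect of somatic
hypermutation on presentability versus germline (per-DR-allele
Δ ln IC50 > 0.1, cathepsin S/B terminal-cut Δp > 0.1 within ±3 bonds,
TCEM class shift; net improved / mixed / negative / unchanged) and
analyze CD154 flow-cytometry counts: replicate-mean activation
percentages among memory cells, positivity at ≥ 3× the patient's
unstimulated background, memory:naive ratios, patient random-intercept
mixed models for category contrasts, and CCR6/CXCR3 enrichment among
activated cells.

The proprietary neural-net predictors behind (1)–(2) are out of scope;
the package defines pluggable model interfaces and ships deterministic
synthetic surrogates (`inst/extdata/`) so the full pipeline is testable.
A synthetic-data module generates repertoires with germline ground
truth and flow counts with planted responders.

## Worked example

The numbered scripts under `analysis/` run the whole study workflow on
synthetic data (`Rscript analysis/01_simulate_data.R`, then 02–05).
Equivalently, in R:

```r
library(idioscope)

sim  <- simulate_repertoire(n_patients = 9, seqs_mean = 120, seqs_sd = 40,
                            min_seqs = 30, seed = 101)
refs <- list(
  a = simulate_repertoire(3, 150, 50, min_seqs = 30, seed = 102)$repertoire,
  b = simulate_repertoire(3, 150, 50, min_seqs = 30, seed = 103)$repertoire)
hla  <- simulate_hla(unique(sim$repertoire$patient_id), seed = 104)

res <- run_pipeline(sim$repertoire, hla, refs, compute_deltas = FALSE)
with(res$panel_table, table(panel_patient, category))
```

```
             category
panel_patient inert stimulatory tolerogenic
       MS-01      0          10           5
       ...
       MS-09      0          10           5
       shared     7           0           0
```

Every patient gets exactly 10 stimulatory and 5 tolerogenic peptides
from their own repertoire plus the 7 shared inert controls — 22 distinct
stimuli. Running the assay stage (`analysis/05_response_assay.R`) on
these panels simulates flow counts with the default planted enrichments
and recovers them:

```
                  contrast   estimate      lower      upper       p
       inert - stimulatory -0.2172022 -0.2230512 -0.2113533  <1e-10
       inert - tolerogenic -0.3770653 -0.3840150 -0.3701157  <1e-10
 marker   estimate        p
   CCR6 25.065      <1e-200
  CXCR3 -0.121         0.63
```

i.e. stimulatory and tolerogenic panels activate ~0.22% and ~0.38% more
memory T cells than inert controls, and activated cells are enriched for
CCR6 but not CXCR3 — the planted structure, recovered by the
mixed-model machinery.

## Input formats

Repertoires are amino-acid FASTA plus a TSV keyed by FASTA ID with
columns `record_id`, `patient_id`, `transcript_count`, `cdr3_start`,
`cdr3_end` (0-based, half-open; `cdr3_start` indexes the CDR3-opening
cysteine) and optional `germline_sequence`, `padded`. A 3-residue
terminal padding convention is supported (`pad_records()` /
`strip_padding()`). HLA typings are `(patient_id, allele)` pairs; flow
counts a tidy TSV with one row per patient × stimulus × replicate.
A 5-record synthetic example repertoire ships in `inst/extdata/`
(`example_repertoire.fasta` / `.tsv`), alongside the surrogate model
tables.

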