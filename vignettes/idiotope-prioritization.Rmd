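---
title: "Prioritizing BCR idiotopes for HLA class II presentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing BCR idiotopes for HLA class II presentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idioscope)
```

## The problem

B cells in the cerebrospinal fluid of multiple sclerosis patients carry
B-cell receptors whose variable regions are, like any endogenous protein,
digested in the endolysosome and displayed on HLA class II molecules.
Peptides from the hypervariable parts of these receptors — *idiotopes* —
are effectively private neo-antigens: T cells may never have been
tolerized against them. Whether a given idiotope can actually engage a
CD4+ T cell depends on three bottlenecks: the peptide must be excised by
the endosomal cathepsins, it must bind the patient's HLA class II
molecules, and a T cell able to see it must have escaped tolerance.

`idioscope` implements this reasoning as a reproducible pipeline. From a
translated IGHV repertoire (short fragments spanning part of framework 3,
the whole CDR3 and part of framework 4) it enumerates all 15-mer windows,
scores each for the three bottlenecks, and selects per-patient panels of
predicted *stimulatory*, *tolerogenic* and shared *inert* peptides sized
for an in vitro activation experiment. Downstream modules impute how
somatic hypermutation changed presentability relative to germline, and
analyze activation-induced-marker (CD154) flow-cytometry counts from the
resulting stimulation assay.

## The scoring model

**Affinity.** Binding of a 15-mer to a class II molecule is scored over
all seven 9-mer registers; the best (lowest ln IC50) register wins. Raw
predictions are standardized per allele so that one threshold means the
same thing for every allele. The normalization fits a Johnson S_U
distribution by the Slifker–Shapiro quantile procedure and maps raw
values through its normalizing transform; when the quantile signature
does not clearly indicate an S_U shape (the selection statistic
`mn/p^2` is near its normal-theory value of 1, where the fit is
ill-conditioned), a robust z-score (median location, 1%-trimmed SD
scale) is used instead. Both paths are strictly monotone and exactly
location–scale invariant, which is what the thresholding actually
requires: `< -1.5` selects strong binders, `> +1` weak ones, and both
cuts are invariant to affine changes of the raw scale.

**Cleavage.** Per-bond cathepsin S/L/B cut probabilities are combined
into a release call with deliberately fuzzy geometry: a candidate is
*liberally released* by a cathepsin when a plausible cut (probability at
or above 0.5) exists within 3 bonds of each terminus — class II grooves
tolerate ragged ends, so cuts just outside the core 15-mer still count.
It is *strictly inert-eligible* only when no cathepsin reaches
probability 0.3 near either terminus. The same-cathepsin-at-both-ends
rule is the default (a single enzyme plausibly excises the peptide);
mixed-enzyme release is available as an option. The maximal bond
probability strictly inside the 15-mer is reported as an
intra-peptide-destruction annotation but is not used as a filter.
Windows at a sequence edge have their flank truncated to the bonds that
exist.

**Tolerance (TCEM rarity).** The T-cell receptor sees only a pentamer of
residues of the bound core — the T-cell exposed motif, in its IIa and IIb
variants with different position masks. How often a motif occurs across
IGHV repertoires is a proxy for tolerance: frequent (germline framework)
motifs are candidates for tolerance, rare (junctional or
mutation-created) motifs are candidates for stimulation. Motifs are
counted once per sequence in each reference repertoire, and the
frequency class is `floor(-log2(count/total))`: class k means "at most
once per 2^k sequences". Class 17 (once per 131,072) bounds the rare
band; class 7 (once per 128) the frequent band. Classes from multiple
reference sets are combined by the minimum — the most frequent
observation wins, a conservative choice for a quantity meant to flag
possible tolerance. The same rule combines the two mask variants into a
candidate-level class.

The position masks default to IIa = {2,3,5,7,8} and IIb = {−1,3,5,7,8}
relative to the 9-mer core. They are configuration, not ground truth:
published mask definitions live in supplementary material we do not
reproduce, and all downstream machinery is mask-independent.

**Core placement.** The frequency index and candidate lookups both use
the central register (core offset 3) by default. An index counted at one
register is only meaningful for queries at the same register; tying the
query register to each candidate's best affinity register (available via
`tcem_core = "affinity"`) would make the lookup inconsistent with the
index unless the index itself were rebuilt per allele. Consistency won.

## Panel selection

Selection encodes the study design bands:

| band | affinity (normalized, best own DR) | cleavage | TCEM FC | n |
|---|---|---|---|---|
| stimulatory | < −1.5 | released by S, L or B (liberal) | ≥ 17 | 10/patient |
| tolerogenic | < −1.5 | released (liberal) | ≤ 7 | 5/patient |
| inert | > +1 on *all* patients' DR, DQ and DP | no cut by S, L or B (strict) | mixed | 7 shared |

Within a band, candidates are ranked by transcript abundance (the most
expanded clones first), ties broken by normalized affinity and then the
peptide string so that selection is a total order; duplicate peptide
strings are dropped. When a patient has too few qualifiers the affinity
limit — and only the affinity limit — is raised in steps of 0.1 up to
−0.5, and the relaxed threshold is recorded in the output. The shared
inert panel is drawn from the pooled repertoire and must be inert
against every patient's complete class II typing; it deliberately mixes
rare and frequent motifs (at least one of each when available) so that
inertness cannot be confounded with motif frequency.

## Germline deltas

For each selected antigenic peptide with an assigned germline, the
pipeline re-runs the predictions on the germline counterpart of the same
window (equal-length pairs map positionally; length changes are aligned
globally, and windows disrupted by insertions are reported
not-computable). A component changes when it moves by more than 0.1 —
on the ln IC50 scale for each of the patient's DR alleles, and on the
probability scale for the cathepsin S/B terminal cut maxima within ±3
bonds. The net call is *improved* when at least one component favors
presentation (affinity up or terminal cleavage up) and none disfavors,
*negative* in the mirror case, *mixed* when both occur, *unchanged*
otherwise. The TCEM frequency-class shift is reported alongside but not
entered into the net call by default: motif rarity speaks to tolerance,
not to the presentation mechanics the delta is meant to summarize (a
config flag includes it). Cathepsin L is excluded from deltas by
default, matching the observation that antigenic idiotopes associate
with S/B processing; this too is configurable. Both DR alleles are
weighed equally in the net call rather than only the best binder — a
genuine open choice; equal weighting keeps the call symmetric in the
patient's two alleles.

## Assay statistics

Activation metrics are computed on replicate-mean percentages (technical
duplicates in the emulated design): the proportion of CD154+ cells among
CD45RO+ memory CD4+ T cells, the same among naive cells, and their
ratio. A response is *positive* when the memory percentage reaches 3
times the same patient's unstimulated background — inclusive, with a
floating-point-safe boundary. A zero background with signal yields an
infinite fold, flagged but still called.

Group differences are estimated with a linear mixed model: activation
percentage on peptide category, with a per-patient random intercept
(REML). The default inference path uses Satterthwaite denominator
degrees of freedom and Tukey-adjusted pairwise contrasts; a fast Wald
path serves simulation loops. Singular (zero-variance) fits fall back to
a fixed-effects-only model, flagged. Chemokine-receptor enrichment uses
the same structure with activation status (CD154+/−) as the fixed
effect, and reports unadjusted mean differences alongside the model
estimate.

## The synthetic-data module

The generator is a first-class module, not a test fixture. It emulates:

* nine patients with per-patient sequence counts drawn from a truncated
  normal (mean 1,079, SD 1,213, minimum 30 — the study-scale defaults),
  sequence lengths 30–45;
* a germline architecture of shared framework templates flanking a
  clone-private CDR3 middle (canonical opening cysteine and closing
  tryptophan), so framework motifs are frequent and junctional motifs
  rare — exactly the structure the TCEM logic exploits;
* somatic hypermutation as i.i.d. substitutions at 4% per position
  (anchors spared), with every planted mutation returned as ground
  truth;
* clonal expansion as power-law transcript counts (exponent 1.5);
* flow counts of 500,000 PBMC per well with a CD4 gate fraction of 0.25,
  memory fractions uniform in 0.32–0.68, a background CD154+ rate of
  0.1% of memory cells with lognormal inter-patient variation (SD 0.3 on
  the log scale), and additive responder enrichments per category
  defaulting to +0.22% (stimulatory) and +0.38% (tolerogenic) — the
  adjusted group differences the assay statistics should recover;
  CCR6 is enriched among activated memory cells (55% vs 30%), CXCR3 is
  not (40% vs 40%).

What it does **not** emulate: V(D)J recombination and lineage structure,
nucleotide-level mutation hotspots, biological (as opposed to binomial)
overdispersion of flow counts, plate or batch effects, and any real HLA
binding chemistry. Passing tests therefore demonstrate that the
machinery is correct and calibrated under the stated statistical
structure — not that the surrogate predictors approximate real
cathepsin or HLA biology.

The surrogate predictors are synthetic by design (the production neural
nets are proprietary): per-allele 20×9 position-weight matrices on an
ln IC50-like scale whose entries share 92% of their variance across
alleles — real class II predictions are strongly correlated across
alleles (promiscuous binders exist) and the inert band (weak on *all*
twelve alleles) is only populated when that correlation is present —
and per-cathepsin 20×20 dipeptide tables in which 7% of P1/P1' pairs
are good substrates (0.6–0.95) and the rest poor (0.01–0.25), mirroring
sparse S1/S1' pocket specificity. Both are shipped as TSV and
regenerable from exported functions with fixed seeds.

## Numerical choices and degenerate inputs

* All coordinates are 0-based, half-open, everywhere.
* Windows containing `X` are excluded from scoring; registers whose
  core touches an `X` are skipped, and a motif touching `X` is invalid.
* Ties in selection are broken by (abundance ↓, normalized affinity ↑,
  peptide lexicographic) — a total order, so selection is deterministic.
* The unobserved-motif frequency class is capped at 24: a finite
  sentinel above the rare band for motifs never seen in a reference set.
* Sequences shorter than 15 yield zero windows (logged, not an error);
  empty repertoires and empty reference sets are errors.
* Normalization requires ≥ 30 values per allele and rejects constant
  input (scale undefined).
* Mixed-model fits that are singular or fail (e.g. constant responses)
  fall back to ordinary least squares, flagged in the result.

## Problem sizes

The analysis drivers under `analysis/` run the whole workflow at desk
scale — 9 patients averaging 300 sequences (≈ 47,000 candidate windows,
scored against 12 alleles in ≈ 15 s) — while the generator's
study-scale defaults remain available for larger runs. The test suite
uses smaller repertoires still, plus Monte-Carlo suites of 200–500
replicates for coverage, power, false-positive and type-I-error
calibration of the assay statistics.

## Known limitations

* Germline assignment is taken as input; there is no V-gene inference.
* The per-sequence motif-counting convention (vs per-window) for
  reference frequencies is a documented choice; with the min-combination
  rule it is the more conservative of the two.
* Release logic is threshold-based, not kinetic; pH, compartment and
  enzyme abundance are out of scope.
* The inert panel relaxes nothing: if fewer than seven peptides satisfy
  all-patient inertness the panel is returned under-filled with a
  warning rather than silently weakened.
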