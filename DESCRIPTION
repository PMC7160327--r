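Package: idioscope
Title: In Silico Prioritization of B-Cell Receptor Idiotopes for HLA
    Class II Presentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Enumerates candidate 15-mer idiotopes from translated IGHV
    (immunoglobulin heavy-chain variable region) repertoires and
    prioritizes them for HLA class II presentation using predicted
    binding affinity with Johnson-family normalization, cathepsin
    S/L/B cleavage-release logic, and rarity classes of T-cell exposed
    motifs (TCEM). Selects per-patient stimulatory, tolerogenic and
    shared inert peptide panels, imputes the effect of somatic
    hypermutation on presentability relative to germline, and analyzes
    activation-induced-marker (CD154) flow-cytometry counts with
    fold-over-background positivity calls and random-intercept mixed
    models. Ships deterministic surrogate affinity and cleavage models
    and a synthetic-data module so the full pipeline is testable
    without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
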