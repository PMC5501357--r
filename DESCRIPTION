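Package: lfqpair
Title: Label-Free Quantitative Proteomics for Paired Treatment Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential protein expression analysis for paired label-free
    shotgun proteomics experiments, built around summed MS/MS fragment
    intensity quantitation. Peptide-spectrum matches are filtered on search
    engine expectation scores, proteins are quantified per run from their
    unique peptides, and per-donor paired log2 differences are partitioned
    into three populations (detected in both conditions, or uniquely in one)
    and normalised by the central population before a cross-donor consensus
    call. Includes membrane/secreted classification from local
    transmembrane and signal-peptide annotations, cross-referencing against
    transcript-level interferon response tables, and a peptide-spectrum-match
    level simulator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
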