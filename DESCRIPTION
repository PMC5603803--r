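Package: igumi
Title: UMI-Based Error Correction and Detectability Analysis for Ig-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of unique-molecular-identifier (UMI)
    tagged immunoglobulin heavy-chain (IGHV-D-J) repertoire sequencing.
    Provides a truth-tagged generative model of the library-preparation
    protocol (polyclonal naive repertoires, per-cell mRNA copy sampling,
    13-16 nt UMIs, PCR amplification bias, substitution sequencing errors,
    leukemic spike-in lysates and ds-cDNA dilution), UMI read grouping with
    single-error clustering and identity sub-clustering, majority-rule
    consensus calling with paired-end assembly and read-count filters,
    anchor-motif junction annotation, a quantile-regression estimate of
    per-gene relative detectability, and spike-in clone detection
    sensitivity analysis across depth, input amount, dilution and
    filtering thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
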