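Package: truguide
Title: Activity and Specificity Assessment of Truncated CRISPR/Cas9 Guides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for assessing CRISPR/Cas9 sgRNA activity and
    specificity with variable-length (17-20 nt) spacers. Enumerates
    candidate guides and genome-wide off-target sites under an NRG PAM with
    up to five mismatches, quantifies indels from amplicon or
    capture-sequencing reads by semi-global alignment around the cut site,
    detects perfect and compound microsatellites whose slippage masquerades
    as editing signal, applies coverage and control-background filters to
    paired control/edited samples, and computes the T7 endonuclease I
    densitometry estimate. Includes a seeded synthetic-data generator
    (genomes with planted target, off-target and microsatellite loci, and
    simulated read sets with known truth) so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
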