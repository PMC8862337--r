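Package: gslprofiler
Title: Glucosinolate Profiling and Metabolic-Gene Evolution Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rule-based LC-MS/MS screening of glucosinolates,
    internal-standard HPLC quantification with class aggregation and
    elicitor fold-change summaries, multi-group accumulation statistics
    with compact letter displays, qRT-PCR relative expression by the
    2^-ddCt method, reciprocal-best-hit homolog pairing from tabular
    BLAST output, Nei-Gojobori (1986) Ka/Ks estimation with
    Jukes-Cantor correction and divergence-time dating, and
    classification of duplicate genes into singleton, dispersed,
    proximal, tandem and WGD/segmental categories. Seeded synthetic-data
    generators emit peak tables, fragment spectra, codon-pair sequences,
    planted genomes and Ct tables with machine-readable ground truth so
    every stage can be validated without instrument or genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
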