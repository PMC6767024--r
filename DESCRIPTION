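Package: teaheterosis
Title: Volatile Heterosis and Expression-Level Dominance Analysis for Hybrid Tea Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying hybrid vigor (heterosis) of volatile
    compounds and gene expression in two-parent / two-hybrid designs such as
    tea plant (Camellia sinensis) crosses. Provides internal-standard
    semi-quantification of GC-MS volatiles, compound-class sums with compact
    letter displays, mid-parent (MPV) and over-high-parent (OPV) heterosis
    indices, a statistical expression-level-dominance classifier that assigns
    genes to ten additive/dominance/overdominance pattern classes from
    replicated FPKM-like matrices, deterministic batch self-organizing-map
    co-expression modules for transcription-factor screening, Pearson
    correlation matrices with exact small-n p-values, hypergeometric
    over-representation analysis with Benjamini-Hochberg FDR, a 2^-ddCt qPCR
    utility, and a synthetic-data generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
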