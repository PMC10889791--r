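Package: ctstab
Title: Reference-Gene Stability Analysis for RT-qPCR Ct Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for selecting and validating reference (housekeeping) genes
    from RT-qPCR cycle-threshold (Ct) data. Implements four stability
    algorithms (comparative Delta-Ct, geNorm M-value with pairwise-variation
    V-curve, NormFinder model-based variance decomposition, and BestKeeper
    descriptive statistics), a RefFinder-style comprehensive consensus ranking
    by the geometric mean of per-method ranks, selection of the optimal number
    and combination of reference genes, dilution-series standard-curve fitting
    with amplification-efficiency estimation, and multi-reference 2^-ddCt
    relative quantification of target genes with group statistics (pooled
    Student's t, one-way ANOVA with Tukey HSD and compact letter displays).
    A seeded synthetic Ct-data generator with known ground-truth stability
    structure makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
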