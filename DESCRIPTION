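Package: rccxgcn
Title: Gene Copy Number Determination for the RCCX Copy Number Variation
    from Duplex qPCR
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Determines integer gene copy numbers (GCNs) of the RCCX copy
    number variation loci (C4A, C4B, CYP21A1P, CYP21A2, the HERV-K(C4)
    insertion and deletion alleles, and the RCCX segment breakpoint) from
    duplex quantitative PCR quantification-cycle (Cq) data normalised to
    the RPPH1 internal reference gene. Provides the delta-Cq to measured
    GCN transform, calibration-offset tuning to zero mean relative error,
    replicate aggregation and the +/-0.3 ambiguity rule, assay quality
    control (standard-curve efficiency, Hubaux-Vos limit of detection,
    pooled coefficients of variation, normalised root-mean-square error),
    a closed-form normal relative-error model for ambiguity and
    misclassification rates, a from-scratch linear discriminant analysis
    caller with leave-one-out cross-validation and genomic-constraint
    consistency checks, and a synthetic Cq data generator built on a
    segment-level haplotype model of the RCCX region.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
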