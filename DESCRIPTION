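Package: finemapSNV
Title: Multiethnic Fine-Mapping of Targeted-Sequencing Case-Control Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for fine-mapping disease susceptibility regions from
    targeted sequencing of multiethnic case-control cohorts. Provides genotype,
    variant and sample quality control with depth/quality-aware filters and an
    exact Hardy-Weinberg test; per-variant logistic-regression association scans
    with principal-component adjustment, conditional analysis and fixed-effect
    meta-analysis across populations; an effective-number-of-tests multiplicity
    correction; approximate-Bayesian single-causal posterior probabilities and
    credible (posterior probability) sets; gene-based rare-variant burden and
    SKAT tests with cross-population meta-analysis (inverse-variance burden and
    homogeneous-effect SKAT); and a multiethnic case-control genotype simulator
    (founder-mosaic haplotypes under the Balding-Nichols model with a logistic
    disease model) that provides ground truth for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    metafor
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, Sequencing, StatisticalMethod,
    Genetics, VariantAnnotation
RoxygenNote: 7.3.3
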