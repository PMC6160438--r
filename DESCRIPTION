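Package: TriPlatVal
Title: Cross-Platform Validation and Integrative Analysis of Somatic
    Variants from Three-Platform Tumor Sequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytical core for clinical tumor profiling that combines
    whole-genome, whole-exome and transcriptome sequencing of paired
    tumor/normal samples. Implements cross-platform validation of SNVs and
    indels under a four-criteria concordance rule, Fisher-exact adjudication
    of capture-validation markers into somatic/germline/wildtype status,
    tumor purity estimation from loss-of-heterozygosity and allele-fraction
    mixture clustering, tumor-in-normal contamination and subclone-absence
    testing, closed-form and resampling limits-of-detection under binomial
    read sampling, splice-aware linking of RNA fusion transcripts to DNA
    structural-variant junctions, driver-catalog curation with rule-based
    pathogenicity tiering, performance metrics, and a synthetic
    multi-platform data generator with known truth for end-to-end testing.
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
    VariantAnnotation,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
biocViews: SomaticMutation, CopyNumberVariation, StructuralVariation,
    Sequencing, VariantDetection
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'capval.R'
    'classify.R'
    'config.R'
    'crossval.R'
    'io.R'
    'metrics.R'
    'power.R'
    'purity.R'
    'svlink.R'
    'synthetic.R'
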