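Package: sweepscan
Title: Selective-Sweep Scans for Case-Control Resequencing Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective-sweep signatures in two-population (case/control)
    whole-genome resequencing cohorts. Implements GATK-style site hard filters
    and genotype-level GQ/DP/AD masking, per-site Weir-Cockerham FST variance
    components and unbiased nucleotide diversity, sliding-window aggregation
    (100 kb windows, 50 kb step) with the pi-ratio statistic, top-1% dual-statistic
    outlier intersection, candidate-gene annotation within +/-50 kb of selected
    SNPs, case down-sampling concordance and chromosome-wise block-jackknife
    robustness procedures, phenotype group comparison with Welch t-tests, and
    hypergeometric over-representation analysis with Benjamini-Hochberg
    correction. Ships a Balding-Nichols synthetic cohort generator with planted
    sweep regions so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    IRanges,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
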