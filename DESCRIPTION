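Package: ednamix
Title: Population Allele Frequencies and DNA-Mixture Contributor
    Estimation from Environmental DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating population allele frequencies and the
    number of unique diploid contributors in environmental DNA (eDNA)
    samples sequenced over a panel of multiallelic microsatellite loci.
    Implements the masked-allele DNA-mixture likelihood in both its
    combinatorial (composition-sum) form and the numerically equivalent
    inclusion-exclusion form, with a stable binomial-convolution grid
    evaluator for multi-locus maximum-likelihood contributor estimation.
    Includes amplicon read processing (quality trimming, pair merging,
    primer-based locus assignment, reference-prefix filtering), diploid
    microsatellite genotype calling with Hardy-Weinberg locus QC,
    eDNA read-count filtering, scaling and pooling under fixed and
    richness-dependent frequency thresholds, comparison statistics
    (frequency correlations, PCA ordination, bootstrap mixture
    experiments), and a ground-truthed simulator of mesocosm and field
    study designs for validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    Biostrings,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
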