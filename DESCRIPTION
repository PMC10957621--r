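Package: tetragp
Title: Genomic Prediction and GWAS for Tetraploid Crops from
    Allele-Frequency Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic selection and genome-wide association analysis
    in autotetraploid crops genotyped by low-depth sequencing. Genotypes are
    taken as per-sample alternative-allele read frequencies (continuous dosage
    on [0,1]), from which a missingness-weighted, tetraploid-scaled genomic
    relationship matrix is built. Provides GBLUP with REML variance components
    on the eigendecomposition of the relationship matrix, k-fold
    cross-validation with prediction-bias diagnostics, marker-density reduction
    experiments, genomic and mid-parent heritability estimation, and
    single-marker mixed-model GWAS with leave-one-chromosome-out relationship
    correction and genomic-control p-value adjustment. Includes a simulator of
    diallel-cross tetraploid populations with linked markers, sequencing-style
    read counts and additive phenotypes for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
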