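Package: popmash
Title: Cross-Population Transcriptome Prediction via Multivariate Adaptive Shrinkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds population-specific transcriptome prediction models that
    borrow strength across populations. Per-population marginal cis-eQTL effect
    sizes are shrunken with an empirical-Bayes multivariate normal mixture
    (populations as conditions), the top SNP per population is selected by
    local false sign rate, and the resulting PredictDB-style models support
    both individual-level prediction of genetically regulated expression and
    summary-statistics transcriptome-wide association with cross-study
    replication. Includes genotype and expression quality control, GREML
    cis-heritability screening, elastic-net and marginal-effect baseline
    models, and a multi-population genotype/expression/GWAS simulator
    (Balding-Nichols allele frequency divergence, block LD).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Matrix,
    glmnet,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    RSQLite,
    DBI,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
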