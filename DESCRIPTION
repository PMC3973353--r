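Package: gwcanet
Title: Differential Metabolite Correlation Networks and Genome-Wide
    Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-stage integration of quantitative metabolomics and
    genome-wide genotype data. Stage one contrasts shrinkage-estimated
    partial-correlation networks of serum metabolites between two
    physiological groups (e.g. non-obese versus obese) with a two-sample
    permutation test, yielding a differential network whose replication
    across cohorts is assessed by a hypergeometric overlap test. Stage two
    performs a genome-wide correlation analysis (GWCA): every SNP is tested,
    via genotype dichotomization and the Fisher z method, for
    genotype-dependent differences in the correlation of selected metabolite
    pairs. Conventional baselines (univariate metabolite-BMI regression with
    Benjamini-Hochberg q-values, additive single-SNP GWAS), marker quality
    control (call rate, minor allele frequency, Hardy-Weinberg equilibrium),
    and a simulation/ROC framework for validating both stages are included,
    together with a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
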