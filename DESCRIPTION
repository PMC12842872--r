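Package: endoscan
Title: Categorical ANCOVA Genome-Wide Scans for Disease Endophenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-variant analysis-of-covariance (ANCOVA) scanning of genotype
    dosages across K ordinal disease endophenotypes with covariate adjustment,
    Tukey-Kramer post-hoc contrast localization, one-vs-rest logistic
    comparison, dosage-based LD clumping, per-group minor-allele-frequency
    summaries, and a paired simulation benchmark quantifying when the joint
    F-test outperforms one-vs-rest testing. Includes a synthetic two-cohort
    generator emulating a discovery/replication endophenotype GWAS design,
    and a nested-screening elastic-net classifier that measures the optimism
    induced by in-sample feature selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
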