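Package: meqtlmr
Title: Family-Based meQTL Mapping, Mendelian Randomization and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end analysis toolkit for genome-wide methylation
    quantitative trait locus (meQTL) studies in family cohorts. Provides
    REML variance-component decomposition of CpG methylation into additive
    genetic, shared-household and residual variance; a two-step cis/trans
    meQTL scan (fast prefilter regression followed by a kinship mixed-model
    refit) with Bonferroni significance thresholds, LD pruning and genomic
    control; two-sample Mendelian randomization of CpG methylation and gene
    expression on outcome traits (inverse-variance-weighted estimation,
    Cochran heterogeneity and MR-Egger pleiotropy diagnostics, stepwise
    instrument refinement, multivariable MR); Bayesian colocalization of
    methylation and expression signals via approximate Bayes factors;
    expression quantitative trait methylation (eQTM) scanning with
    trans-meQTL hotspot detection; and hypergeometric plus MAF-matched
    permutation enrichment tests. A seed-deterministic synthetic cohort
    generator with pedigree structure, LD-patterned genotypes and recorded
    ground truth makes every stage testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
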