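Package: aneusig
Title: Aneuploidy Gene-Expression Signatures: Discovery, Scoring and Prognostic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Derives minimal gene-expression signatures that discriminate
    aneuploid from diploid tumors and evaluates their prognostic value.
    Implements two-class Significance Analysis of Microarrays (modified
    t-statistic with fudge factor and permutation-based q-values),
    cross-validated incremental support-vector-machine selection of the
    minimal discriminating prefix of the ranked gene list, a z-score based
    signature score with upper-quartile dichotomization, hierarchical
    sample clustering (complete linkage, Pearson distance), positional
    (chromosome-arm) gene-set enrichment analysis with phenotype
    permutations, and survival and association statistics (Kaplan-Meier,
    log-rank, Cox proportional hazards with interactions, logistic
    regression, chi-square/Fisher and rank tests). A synthetic-cohort
    generator with a planted chromosome 15q down-regulated block,
    ploidy-linked censored survival and a correlated hormone-receptor
    covariate makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    e1071,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
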