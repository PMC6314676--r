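Package: schoolgxe
Title: School-Level Moderation of Polygenic-Score Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether school contexts moderate associations
    between polygenic scores and life-course attainments. Implements an
    indirect test based on random-slope multilevel models with a
    cluster-permutation (randomization) test on the slope variance component,
    a direct cross-level interaction test for named school environments with
    interaction-guard covariates, construction of school-level moderators
    (school status and stratification) from student microdata, between-school
    variance decompositions for gene-environment correlation, a synthetic
    school-clustered cohort generator, and a Monte-Carlo power engine for
    both testing approaches under moderator measurement error.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
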