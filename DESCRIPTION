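Package: greymeta
Title: Grey-Literature Sensitivity Re-Analysis of Meta-Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the contribution of grey-literature studies
    (non-English reports, unpublished studies, dissertations) to the
    results of meta-analyses. Given a corpus of systematic reviews with
    study-level outcome data and grey-literature labels, each review's
    primary meta-analysis is recomputed with and without each study type
    using the original summary measure and model (inverse-variance fixed
    or DerSimonian-Laird random effects, or Mantel-Haenszel pooling for
    dichotomous outcomes). The change in the pooled point estimate and
    confidence-interval width is expressed as a magnitude-only percent
    change and classified as negligible, small, moderate, large, or
    substantial, and changes in statistical significance are flagged.
    Includes corpus-level summaries of searching and inclusion patterns,
    a seeded synthetic-corpus generator for simulation studies of
    language and publication bias, CSV/JSON corpus readers and writers,
    and reference results from 129 child-relevant Cochrane reviews.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
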