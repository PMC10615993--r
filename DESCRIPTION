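Package: dsitext
Title: Divergent Semantic Integration Scoring for Narrative Text
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes divergent semantic integration (DSI), a text-level
    creativity score defined as the mean pairwise cosine distance between the
    word embeddings of a narrative. Provides deterministic preprocessing for
    static and contextual embedding backends, readers for word2vec- and
    GloVe-style vector files, lexical covariates (word count, Flesch-Kincaid
    readability, frequency/prevalence/age-of-acquisition norms, MTLD lexical
    diversity), a text-length bias audit based on random subsection sampling,
    psychometric validation statistics (correlation confidence intervals,
    dependent and independent correlation comparisons, rater agreement, omega
    reliability, intraclass correlations, hierarchical regression, group
    comparisons), a synthetic corpus and rater generator with known ground
    truth, and batch command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
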