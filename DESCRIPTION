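Package: policytriad
Title: Three-Dimensional Policy Text Analysis: Topics, Tools, and Consistency
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative analysis of dated policy-document
    corpora along three dimensions: latent topic structure fitted by collapsed
    Gibbs sampling for latent Dirichlet allocation, with perplexity and
    topic-coherence model selection and stage-wise theme-intensity
    trajectories; policy-tool content-analysis tabulation over a
    supply/environmental/demand coding frame with Cohen's kappa inter-rater
    reliability; and Policy Modeling Consistency (PMC) index scoring of binary
    indicator sheets, including grading, ranking, surface matrices, and stage
    summaries. Synthetic-data generators with known ground truth support
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
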