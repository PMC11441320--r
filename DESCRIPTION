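Package: retrigger
Title: Relation Extraction and Unsupervised Trigger Detection for
    Protein Complex Formation
Version: 0.1.0
Authors@R:
    person("ComplexTome", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts binary Complex_formation relations between protein
    mentions from BRAT-standoff annotated documents and explains each
    positive prediction with an automatically detected trigger span.
    Candidate mention pairs are turned into marked or masked token
    windows and classified with a small trainable transformer encoder
    plus a softmax decision layer. Positive predictions are attributed
    to input tokens with layer integrated gradients or sampled Shapley
    values, filtered with post-processing heuristics, and the top-scoring
    token is emitted as the trigger. Includes a four-mode span-matching
    evaluator (left-bound, right-bound, overlap, exact), a synthetic
    standoff corpus generator with planted cues for end-to-end testing,
    and a command-line pipeline driver.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
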