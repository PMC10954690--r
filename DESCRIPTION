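Package: speechmarkers
Title: Speech Graph, Semantic Coherence and Syntactic Markers for
    Psychosis-Spectrum Research
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts automated speech markers from short transcribed
    speech excerpts and links them to psychosis-spectrum outcome
    measures. Builds non-semantic word-trajectory graphs and computes
    fourteen connectivity measures with sliding-window averaging and a
    random-shuffle null; computes smooth-inverse-frequency (SIF)
    sentence embeddings and the coherence, tangentiality, on-topic and
    repetition statistics; counts Penn-Treebank part-of-speech tag
    frequencies through a pluggable tagger backend; scores automated
    against manual transcripts with word error rate, match error rate
    and word information lost; and runs the inferential chain
    (participant-level aggregation, Spearman correlations with
    Benjamini-Hochberg correction, Mann-Whitney group tests, and
    hierarchical linear and logistic regression ladders with pseudo
    R-squared metrics). Ships a synthetic cohort generator with planted
    marker-symptom structure and a parametric transcription-noise
    channel for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
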