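Package: medmatch
Title: Deep Semantic Matching for Chinese Medical Answer Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for answer selection in Chinese medical community
    question answering, cast as semantic matching over ranking lists of one
    adopted and four distractor answers. Implements corpus construction in
    the 5-field tab-separated webMedQA dialect (cleaning, filtering,
    negative sampling, stratified 8:1:1 splitting), character- and
    word-level preprocessing with frequency-thresholded vocabularies, the
    Convolutional Semantic Clustered Representation (same-length convolution
    with overlapped windowed max pooling), the MV-LSTM and MatchPyramid deep
    matching networks trained with softmax cross-entropy and Adam, the
    classical BM25, multi-CNN and random baselines, P@1/MAP ranking
    evaluation, and a seeded synthetic corpus generator with controllable
    question-answer lexical overlap for desk-scale experimentation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
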