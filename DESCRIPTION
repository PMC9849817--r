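Package: orchardvqa
Title: Multimodal Visual Question Answering for Fruit Tree Disease Decision-Making
Version: 0.1.0
Authors@R:
    person("Orchard", "VQA Maintainers", email = "maintainers@orchardvqa.dev",
           role = c("aut", "cre"))
Description: Tools for building and evaluating multimodal visual question
    answering (VQA) models that answer natural-language questions about
    fruit-tree disease images. Implements Tucker-decomposed bilinear pooling
    with a low-rank core and an element-wise-squared image projection, stacked
    modular co-attention (self-attention and question-guided attention),
    foreground-focused image preprocessing with Otsu thresholding and
    morphological opening, the five-operator image augmentation pipeline,
    word-piece question tokenization with fixed-length padding, an
    out-of-vocabulary least-squares embedding projection, a seeded synthetic
    corpus generator producing lesion-bearing leaf images with templated
    question/answer triplets, and a training and evaluation engine with strict
    accuracy, k-fold cross-validation and confusion statistics.
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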