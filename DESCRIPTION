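Package: decoNEN
Title: Classification of Neuroendocrine Neoplasms by Transcriptomic Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step framework for characterizing pancreatic and
    gastroenteropancreatic neuroendocrine neoplasms from bulk RNA-seq data.
    Step one deconvolves bulk tumor transcriptomes into healthy-cell-type
    proportions using marker-gene signature matrices learned from single-cell
    references, via nu-support-vector regression (with a non-negative
    least-squares alternative) and permutation-based empirical p-values.
    Step two predicts clinical characteristics (binary and ternary grading,
    carcinoma-versus-tumor status, survival-risk groups) from the
    deconvolution outputs alone, without any proliferation-rate feature.
    Includes a seeded synthetic-data generator for single-cell references,
    bulk mixtures with known proportions, and clinical cohorts, so the whole
    pipeline can be validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    pracma,
    nnet,
    survival,
    Matrix,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
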