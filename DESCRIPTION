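Package: mtcascade
Title: Cascaded Shared-Private Attentive Multitask Classification of
    Temporal Orientation, Sentiment and Emotion in Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint sentence-level classification of temporal orientation
    (past/present/future), sentiment polarity and multi-label emotion
    (15 classes, up to 3 per sentence) with a shared-private attentive
    multitask network built on a bidirectional GRU encoder with word
    attention.  Subnets are cascaded by passing each task's intermediate
    representation to the next, and ablation variants (single-task,
    shared-attention-only, output cascading, no cascading) are provided
    for controlled comparison.  Includes weak-supervision labeling rules
    that derive sentiment from the primary emotion, a trainable weak
    temporal classifier, social-media-style text normalization
    (entity placeholders, hashtag segmentation, contraction expansion,
    elongation reduction), iterative multilabel-stratified k-fold
    cross-validation, multi-label evaluation metrics (mean recall,
    samples-F1, Cohen's kappa), and a seeded synthetic-corpus generator
    reproducing the label structure of annotated suicide-note corpora so
    the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
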