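Package: retmae
Title: Self-Supervised Masked Autoencoding for Multi-Source Retinal OCT
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-phase framework for binary retinal disease classification
    (normal vs. age-related macular degeneration) from optical coherence
    tomography (OCT) B-scans: masked-autoencoder self-supervised pre-training
    on fused multi-source image collections with vision-transformer, Swin, or
    SwinV2 encoder backbones, followed by supervised training of a small dense
    classification head on top of the frozen encoder. Includes a synthetic
    multi-source OCT B-scan simulator with controllable lesion morphology and
    per-source domain shift, manifest-based dataset splitting and fusion with
    strict test-set isolation, a cross-dataset evaluation harness (accuracy,
    AUC-ROC, AUC-PR, F1), an exact tie-aware Wilcoxon signed-rank test for
    paired model comparison, and baseline architecture parameter accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
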