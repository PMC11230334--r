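Package: trialmatch
Title: Siamese Dual-Encoder Patient-Trial Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts patient eligibility for clinical trials from paired
    <EHR, criteria> representations. A weight-sharing Siamese dual-encoder
    network (MLP, LSTM, GRU, bidirectional and self-attention variants, CNN,
    CNN-LSTM) is trained on pretrained-LLM style document or token embeddings
    with binary, class-weighted, or contrastive objectives, and evaluated by
    stratified k-fold cross-validation with class-wise F1. Includes an
    early-fusion single-encoder counterpart, a rule-based baseline over
    structured records (logistic regression, SVM, random forest), a synthetic
    data generator emulating the cohort structure the method assumes, and
    PCA/t-SNE cluster visualization of the learned fused representations.
    Neural components run on a small built-in reverse-mode automatic
    differentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
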