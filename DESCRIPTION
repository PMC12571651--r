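Package: radalign
Title: Parameter-Efficient Alignment of Dual-View Radiographs and Radiology Reports
Version: 0.1.0
Authors@R:
    person("Radalign", "Developers", email = "radalign@example.org", role = c("aut", "cre"))
Description: Toolkit for parameter-efficient visual-language alignment of
    chest radiographs and their free-text reports. Provides reversible
    (invertible) adapters with a closed-form inverse, bottleneck
    language/task adapters with residual connections and layer
    normalization, dual-view (frontal + lateral) image preprocessing with
    Hounsfield-unit windowing, bilinear resizing, patchification and
    exact-count random patch masking, report section extraction and
    fixed-length tokenization, global plus weighted local cosine alignment
    losses, cross-modal retrieval and classification metrics (P@k,
    accuracy, F1, AUC), a desk-scale CPU training loop over frozen toy
    encoder backbones, and a synthetic dual-view radiograph/report
    generator so the full pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
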