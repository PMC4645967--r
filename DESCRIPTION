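Package: tensorfuse
Title: Multimodal Medical Image Fusion with a Patch-Based Structure Tensor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fuses two co-registered single-channel medical images (for
    example a CT and an MR slice of the same anatomy) in the wavelet domain.
    Low-frequency sub-bands are combined by a fixed weighted average; detail
    sub-bands are combined by weights derived from the local coherence of a
    nonlocal-means-filtered (patch-based) structure tensor, so that at each
    coefficient the modality with the stronger oriented structure dominates.
    Includes the classical weighted-average and choose-gradient-max fusion
    rules as baselines, the energy-of-image-gradient sharpness metric, a
    multilevel 2-D Daubechies wavelet transform with symmetric extension and
    perfect reconstruction, a synthetic CT/MR-like phantom generator, PNG and
    TIFF image input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    stats,
    grDevices,
    graphics,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
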