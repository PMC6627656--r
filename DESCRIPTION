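Package: radusm
Title: Reverse Anisotropic Diffusion Unsharp Masking for Radiograph Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enhancement of line structures (endotracheal, feeding and
    nasogastric tubes, catheters) in low-contrast grayscale radiographs by
    unsharp masking built on reverse anisotropic diffusion: a variational
    filter whose diffusivity increases with gradient magnitude, so that it
    smooths edges while leaving flat and noisy regions nearly untouched.
    The implicit lagged-diffusivity system is solved matrix-free with a
    Jacobi-preconditioned bi-conjugate gradient method. Includes Gaussian
    and Perona-Malik smoothing baselines, the EMEE block-entropy contrast
    metric, a reproducible chest-like phantom generator, readers and
    writers for 16-bit PNG/TIFF and raw JSRT-layout images, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
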