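Package: larvatrack
Title: Background-Subtraction Tracking of Translucent Drosophila Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tracks dark, low-contrast animals such as Drosophila larvae in
    grayscale video by mean-frame background subtraction (frame averaging
    followed by subtraction then thresholding), connected-component blob
    detection with size pruning, greedy nearest-neighbour track linking, and
    kinematics extraction (Gaussian track smoothing, instantaneous speed,
    speed distributions). Removes static high-contrast objects such as
    petri-dish edges before thresholding, so a single very low threshold
    tracks larvae through arena edges where plain binary thresholding fails.
    Includes a ground-truthed synthetic movie generator emulating the
    recording conditions (dish-edge ring, dyed versus undyed larval contrast,
    mains-flicker beat, sensor noise), movie and track-table input/output,
    and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    png,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    EBImage,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
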