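Package: brainentropy
Title: Shannon Entropy of Segmented Brain Activation Component Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes image-based brain entropy (BEN) from rendered
    independent-component activation overlays: pixels are classified into
    five colour classes (background, white, grey, blue activation, red
    artifact) by nearest reference colour, red artifacts and background are
    discarded, and the Shannon entropy of the 256-bin grayscale intensity
    distribution of the retained pixels is computed and normalised to [0,1].
    Includes a seeded synthetic component-map and two-cohort generator with
    entropy calibration, the two-group statistical battery used in clinical
    comparisons (pooled t-test, Mann-Whitney U with tie-corrected normal
    approximation, Pearson chi-squared and phi coefficient on 2x2 tables,
    point-biserial correlation, Monte-Carlo power estimation), and an
    end-to-end pipeline with a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    RNifti
Config/testthat/edition: 3
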