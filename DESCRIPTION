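Package: equitherm
Title: Texture Entropy Analysis of Equine Infrared Thermograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting rider:horse bodyweight ratio effects in
    false-color infrared thermograms of the equine thoracolumbar region.
    Implements five bidimensional entropy measures (sample, fuzzy,
    permutation, dispersion and distribution entropy) computed directly on
    region-of-interest color components, the three entropy-related gray
    level co-occurrence matrix texture features used as a comparison
    baseline, a three-criterion statistical procedure that selects the most
    informative measure/component/ROI combinations, and a three-threshold
    classifier scored by sensitivity, specificity, and predictive values.
    Includes a synthetic thermogram generator emulating a crossed
    horse-by-rider pre/post-exercise study design so the full pipeline can
    be exercised without access to clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    tibble,
    dplyr,
    tidyr,
    rlang,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
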