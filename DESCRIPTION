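Package: sozdensity
Title: Electrode Density Effects on Seizure Onset Zone Delineation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how intracranial electrode density affects
    delineation of the seizure onset zone (SOZ). Implements blinded
    seizure-intensity heatmaps (line-length transform, baseline z-scoring,
    Gaussian maximum projection onto brain surfaces and omni-planar slices),
    decimation of high-density grids and depth probes to lower-density
    versions, synthetic seizure and scorer-annotation generators with known
    ground truth, pixel-wise Cohen's kappa agreement statistics, linear
    mixed-effects crossover models for annotation area and confidence, power
    and design-effect utilities, and a spatial-sampling simulation comparing
    convex-hull SOZ volume estimates across electrode spacings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    lme4,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sp,
    e1071,
    withr
Config/testthat/edition: 3
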