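Package: septune
Title: Information-Theoretic Tuning, Decoding, and Stability Analysis for Binarized Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of one-photon calcium imaging recordings from
    freely moving rodents. Converts extracted fluorescence traces to binarized
    activity, derives behavioral variables (position, head direction, velocity,
    acceleration) from pose tracks, estimates occupancy-normalized tuning maps,
    scores tuning with mutual information against circular-permutation and
    bootstrap nulls, reconstructs position with a naive-Bayes maximum a
    posteriori decoder, quantifies within-session and cross-session stability,
    and regresses the proportion of stable tuned cells along anatomical axes.
    A seedable synthetic-session generator with known ground truth supports
    calibration and end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
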