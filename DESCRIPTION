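Package: needleplace
Title: Accuracy Assessment of Image-Guided Needle Placement Relative to a
    Nerve Target
Version: 0.2.0
Authors@R:
    person("Jasper", "van der Meer", email = "j.vandermeer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify how accurately a radiofrequency needle is
    placed relative to a target nerve from segmented surface models (STL),
    as used in phantom validation studies of surgical navigation. Provides
    STL reading/writing and deterministic dense surface sampling, rigid
    landmark (Procrustes) and iterative-closest-point registration with
    propagation of the fitted transform to the needle, a three-way
    decomposition of the tip-to-nerve error into Euclidean, lateral and
    depth distances against the 5 mm effective range of pulsed
    radiofrequency, cohort statistics (median/IQR, percentage within range,
    Shapiro-Wilk gated one-sample t or Wilcoxon signed-rank tests against
    the 5 mm target), and a synthetic phantom-trial generator with known
    ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
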