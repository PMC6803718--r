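Package: apotrack
Title: Active-Shape-Model Tracking of Aponeuroses and 1D SPM of Muscle
    Thickness in Ultrasound Sequences
Version: 0.1.0
Authors@R:
    person("Apotrack", "Developers", email = "apotrack@example.org",
           role = c("aut", "cre"))
Description: Segments the superficial, middle and deep aponeurosis
    boundaries of the plantar-flexor muscles in B-mode ultrasound image
    sequences with a multiresolution active shape model (point
    distribution model built by PCA of hand-labelled landmark sets,
    Gaussian models of normalised intensity-gradient profiles, and a
    Mahalanobis-distance landmark search constrained to a plausible shape
    space).  Converts per-frame boundary fits into muscle thickness at 20
    sites, segments strides from vertical ground-reaction-force traces,
    time-normalises thickness to 200 stride-cycle nodes, subtracts a
    quiet-standing baseline, and performs one-dimensional statistical
    parametric mapping (repeated-measures ANOVA and paired-t fields with
    random-field-theory critical thresholds).  A synthetic phantom
    generator provides image sequences, ground-reaction forces and smooth
    random fields with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
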