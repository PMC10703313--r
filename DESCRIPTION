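Package: skmt
Title: Secondary-Structure-Aware Backbone Smoothing and Writhe-Based
    Protein Entanglement Measures
Version: 0.1.0
Authors@R:
    person("Structural", "Topology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the tertiary entanglement of protein
    C-alpha backbones. Implements the SKMT algorithm, a secondary-structure
    aware variant of the KMT curve-simplification scheme that reduces each
    secondary structure element to a minimal set of points while preserving
    non-local threading, together with discrete Gauss-integral writhe and
    average crossing number calculations over all backbone subsections
    (writhe fingerprints). Includes empirical entanglement bounds as a
    function of smoothed-curve length, detection of super-helical
    subsections from writhe profiles, a flexible topology-level structure
    similarity metric with coverage reporting, readers for PDB coordinate
    files and PSIPRED secondary structure assignments, synthetic curve
    generators (helices, trefoils, random walks, mock backbones) for
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
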