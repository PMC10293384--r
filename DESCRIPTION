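Package: megslow
Title: Spectral Slowing and Envelope Connectivity Analysis for Longitudinal Resting-State MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Source-space resting-state MEG analysis for longitudinal cohorts on a
    90-region parcellation (78 cortical, 12 subcortical): per-region power spectra,
    relative band power in the five canonical frequency bands, dominant-peak frequency
    in the 4-13 Hz range, leakage-corrected amplitude envelope correlation (AEC-c)
    adjacency matrices with per-region connectivity profiles, connection-level
    permutation tests with false-discovery-rate control, and longitudinal linear
    mixed-model analyses of group differences, progression, and clinical associations.
    Includes a synthetic-cohort generator (1/f background spectra with a drifting
    alpha-range peak, planted band-limited envelope coupling, three-visit designs with
    dropout, and clinical scores driven by the spectral state) so the full pipeline is
    testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
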