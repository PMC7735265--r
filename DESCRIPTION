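Package: altishift
Title: Effort-Balanced Estimation of Elevational Range Shifts from Two-Period
    Resurvey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing historical and modern biodiversity surveys
    along elevation gradients. Estimates per-species shifts in mean elevation
    of occurrence via bin-stratified balanced resampling that corrects for
    unequal sampling effort between periods, links pollinator shifts to the
    interaction-frequency-weighted shifts of the plants they visit, and
    contextualizes community change with rarefied and extrapolated species
    richness (Hill number 0), temperature lapse-rate displacement of
    isotherms, and elevation-zone land-use change tests. Includes a synthetic
    resurvey generator with known ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
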