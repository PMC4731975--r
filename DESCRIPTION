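Package: walkage
Title: Walking-Speed Growth Curves and Characteristic-Based Alpha-Ages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying physical aging measured by timed-walk speed in
    longitudinal panel surveys of older adults. Simulates ELSA-like biennial
    person-wave cohorts with refreshment samples, attrition and implausible-value
    contamination; applies the standard cleaning rules (speed plausibility floor,
    age range and consistency checks, anthropometric recodes) with a full
    exclusion ledger; fits sex-specific quadratic growth-curve models with random
    intercepts and age slopes by maximum likelihood; performs likelihood-ratio
    model building; and converts subpopulation gaps in walking speed into single
    years of age via the characteristic-based alpha-age inversion of the fitted
    trajectories.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
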