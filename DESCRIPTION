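Package: pedeval
Title: Pediatric Medication Evaluation with Multiple-Domain Matrices and
    Non-Radial DEA-Malmquist Indices
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-stage evaluation pipeline for pediatric medication systems
    in resource-constrained settings.  A multiple-domain-matrix (MDM) stage
    propagates elicited relationship matrices into per-factor global
    importance weights, medication-stage aggregates and goal-conditional
    factor rankings.  A data-envelopment-analysis stage scores productivity
    change of decision-making units over a multi-year input-output panel
    with the input-oriented non-radial Malmquist index, solved by an
    internal two-phase simplex.  Includes a synthetic panel generator with
    an analytically known constant-returns frontier for validation, and
    curated fixtures of the published provincial instance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
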