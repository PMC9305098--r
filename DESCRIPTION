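Package: focalsf
Title: Focal Structure-Function Analysis of Glaucoma from OCT-Angiography,
    RNFL Thickness and Standard Automated Perimetry
Version: 0.1.0
Authors@R:
    person("focalsf", "developers", email = "focalsf@example.org",
           role = c("aut", "cre"))
Description: Maps every 30-2 visual-field location to an individualized
    peripapillary OCT-angiography wedge and an OCT ring sector through a
    parametric nerve-fiber bundle trajectory model, extracts focal capillary
    density and focal retinal nerve fiber layer thickness, and models focal
    visual-field deviation with univariate and combined linear models,
    including AIC/likelihood-ratio model comparison and segmented
    (broken-stick) mixed-model breakpoint analysis with the Davies test.
    Includes a synthetic-cohort generator with known ground truth (damage
    fields aligned to nerve-fiber trajectories, broken-stick
    structure-function links, per-subject random intercepts) so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
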