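Package: nutrigeom
Title: Nutritional Geometry of Wild Primate Diets from Focal-Animal Feeding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating daily macronutrient and energy intakes of
    wild herbivores from food chemistry and timed focal-animal feeding bouts,
    and for analysing the results in the geometric framework for nutrition.
    Computes available protein, total non-structural carbohydrates and
    physiological-fuel-value energy densities of foods (with a substitution
    hierarchy for unassayed items), converts bout durations, intake rates and
    unit dry masses into per-focal-day intakes, represents diets on
    right-angled mixture triangles and protein versus non-protein-energy
    ("nutritional rail") plots, and summarises seasonal and inter-group
    variation with linear mixed models and descriptive tables. Includes a
    synthetic study generator that emulates a multi-group, multi-season
    observational design with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    nlme,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
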