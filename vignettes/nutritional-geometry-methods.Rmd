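---
title: "Methods: from feeding bouts to nutritional geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from feeding bouts to nutritional geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrigeom)
```

This vignette is the package's own account of its models, conventions and
design choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Food chemistry and energy

Each food is a species × plant-part record with crude protein (CP), acid
detergent-insoluble crude protein (ADICP), fat, ash and the sequential
fiber fractions NDF ≥ ADF ≥ lignin, all in % dry matter. Derived
quantities:

* **Available protein** `AP = CP − ADICP`, the digestible protein
  fraction. ADICP > CP is rejected as a data error naming the food.
* **TNC by difference** `TNC = 100 − (Fat + AP + Ash + NDF)`. Because
  assay percentages are rounded, the difference can come out marginally
  negative on real data; we clamp to zero and warn rather than error. The
  clamp breaks exact mass closure only for affected rows, and the closure
  invariant (`AP + TNC + Fat + Ash + NDF = 100`) is tested on unclamped
  records.
* **Energy density** sums physiological fuel values (16.736 kJ/g for
  protein and carbohydrate, 37.656 kJ/g for fat) plus fermentable fiber at
  12.552 kJ/g discounted by the digestibility of cellulose
  (0.3911 × (ADF − lignin)) and hemicellulose (0.5197 × (NDF − ADF)).
  Concentrations enter as g/g (percent ÷ 100), so the result is kJ per g
  dry matter; a hypothetical pure-fat food evaluates to exactly
  37.656 kJ/g, which pins down the unit convention. The implementation is
  tested against an independently summed five-term oracle at 1e-12
  relative tolerance.

**Two fiber conventions coexist deliberately.** The mixture-triangle axes
use *fiber-free* macronutrient energy (protein, fat, TNC only), because in
the motivating system only a small fraction of macronutrient energy comes
from fiber. The AP:NPE ratio, by contrast, includes fiber in the
denominator. For the fiber term of NPE we use the digestible-fiber energy
(the two discounted terms of the energy equation), not raw NDF mass at
full fuel value — the only fiber-to-kJ pathway the energy model defines.
The two conventions are exposed as distinct quantities (`rmt_coords()` /
`daily_geometry()$npe_kj`) precisely so they cannot be conflated.

**Substitution hierarchy.** Foods eaten but never assayed inherit the
unweighted mean chemistry of sampled congeners (same genus, same part);
failing that, the mean of all sampled foods of that part; failing that the
food is unresolvable and the pipeline stops, naming it. Measured records
missing only a fat assay (common for young leaves) have fat filled with
the measured mean for that part before any averaging. Ties among several
congeners are resolved by the unweighted mean — no basis for weighting
exists in the inputs. Provenance (`direct` / `congener` / `part_average`)
is carried through to the derived-composition output.

## 2. The daily-intake estimator

A focal-day is keyed by (focal animal, date); night feeding is assumed
absent (observed animals slept where they were left). For quantity *y*:

`DI_y = Σ_bouts duration_s × rate × unit_mass_g × conversion × Q`

with Q the concentration (g/g) or energy density (kJ/g). Choices:

* **Rate pooling** is duration-weighted: total units ÷ total observed
  seconds across all records of a food, pooled across individuals and
  sites. This is robust to many short observation intervals; the
  alternative (mean of per-record rates) overweights them. Records from
  counted-interval and per-item-handling protocols pool identically once
  expressed as (units, seconds).
* **Missing rates** for a food fall back to the pooled rate of all foods
  sharing its plant part, mirroring the chemistry substitution, and the
  substitution is logged. A part with no rates at all is an error.
* **Conversion factors** default to 1 and are configurable per food (they
  exist for foods whose countable unit differs from the ingested unit).
* **Soil bouts** are excluded from every nutritional sum but tallied in a
  `soil_audit` attribute so observation effort still reconciles.
* **Fruit/seed fraction** counts parts F, FSD, SD and URFSD as fruit/seed;
  buds, flowers, leaves and shoots are not.
* **Body mass** joins per focal animal; animals without a capture record
  get their group's mean mass (logged). Scaled intakes use exponents
  0.762 (energy) and 1 (protein). A zero-mass day with nonzero feeding
  time warns and reports AP:NPE as missing rather than dividing by zero.

The engine is vectorised; its agreement with a naive per-bout loop is
tested exactly, and additivity, monotonicity and scale-equivariance are
tested as properties on >1,000 generated days.

## 3. Geometry

`rmt_coords()` normalises (AP kJ, fat kJ, TNC kJ) to percentages summing
to 100; the carbohydrate axis is implicit (`z = 100 − x − y`), with
isolines `x + y = 100 − z`. The nutritional rail is a regression through
the origin, `slope = Σ(ap·npe)/Σ(ap²)` — the closed-form least-squares
solution, cross-checked in tests against a brute-force grid minimiser.
`fit_rail()` reports the implied dietary ratio (1/slope) and the spread of
perpendicular residuals as a % of mean origin distance (a unitless
"tightness of balancing" summary). The rail is fitted by default on
group × season mean intakes (the display convention for seasonal rails);
per-day fitting is available by passing daily coordinates. Converting
between "share of energy from protein" *p* and the ratio uses
`r = p/(1−p)` and its exact inverse.

Requirement thresholds translate mass-specific minima into the (AP, NPE)
plane: a vertical line at `g·kg⁻¹·day⁻¹ × mass × 16.736` kJ (displayed
rounded to the nearest kJ) and an oblique line of constant total energy at
`kJ·kg⁻⁰·⁷⁶² × mass^0.762`. For a 5-kg animal the 500 kJ·kg⁻⁰·⁷⁶² line
evaluates to 1704.5 kJ; the value 1703 sometimes quoted for the same
conversion reflects upstream rounding of 5^0.762, and we do not force
agreement (tests accept ±2 kJ there).

## 4. Aggregation and mixed models

Daily values are averaged within individual × period cells (cells
typically hold 1–5 days), and the table reports its fill
(individuals × periods vs populated cells). The model for each intake
variable is REML with fixed group, categorical period and their
interaction, and a random intercept per individual (individuals are
uniquely labelled, so the intercept is implicitly nested in group).

* **Engine.** The default delegate is `lmerTest::lmer` (Satterthwaite
  denominator df, Type III F). A heteroscedastic-residual variant
  (`method = "lme"`, per-period residual variances via `varIdent`) is
  available for fully estimable designs; it is not the default because
  designs with unsampled group × period cells make the fixed-effects
  matrix rank-deficient, which `lme` rejects while `lmer` drops the
  inestimable columns. The exact covariance bookkeeping of other software
  ("diagonal repeated" structures) is not replicated; our structure is
  documented here instead, and printed F statistics from such software are
  not expected to be reproduced.
* **Transformations.** Proportions use `asin(sqrt(p))` (the standard
  stabiliser; the inverse `sin(x)²` is applied to marginal means), and
  strictly positive skewed intakes can use the natural log. Estimated
  marginal means are always reported back on the raw scale.
* **Pairwise letters.** Group comparisons are unadjusted (LSD) at
  α = 0.05, turned into compact letter displays with an insert-and-absorb
  algorithm implemented in the package. Groups with non-estimable means
  (unsampled periods) get no letters rather than misleading ones.

The modelling stage is validated by simulation (seeded, in the test
suite): detection of a strong simulated group effect at α = 0.01 with
≥95% power over 100 replicates, type-I error near 5% on null data, and
recovery of the generating group ordering by the marginal means.

## 5. What the synthetic generator emulates

`study_config()` defaults describe the study conditions: five groups whose
basal-area disturbance proxies (0.886, 1.0, 0.389, 0.210, 0.510 of the
least-disturbed value) set abundant-season dry-mass intake through a
linear ramp with floor 0.35; 18 individuals (5/4/3/3/3); 12 periods with
seasons {1–2, 3–5, 6–8, 9–10, 11–12} and lean seasons {1, 4, 5}; two
groups with truncated sampling (one only periods 1–2, one only 3–12);
lean-season intake at 0.4 of the undisturbed abundant-season value and
identical across groups (lean-season convergence); fruit/seed mass
fractions higher in the abundant season and declining with disturbance;
and a dietary AP:NPE target of 0.105 for every group.

Mechanics: the food library draws leaf-like and fruit-like compositions
within the spans observed in wild-food chemistry (AP 0–13% etc.), always
satisfying NDF ≥ ADF ≥ lignin and mass closure, including one
zero-available-protein unripe fruit. Diet weights per group × season solve
a one-parameter exponential tilt along the foods' AP:NPE spectrum
(root-finding to machine tolerance) so the expected diet hits the
configured frugivory *and* the AP:NPE target; if a target is unattainable
for a given library the solver clamps and warns rather than silently
drifting. Bout counts are Poisson (mean 48/day), durations gamma
(shape 2), day-level mass lognormal (CV 0.3, mean-preserving), food choice
multinomial on time-share weights. Feeding time is derived from the mass
budget (≈3 h/day at the calibration anchor). With `noise = FALSE` every
stochastic element is replaced by its expectation and the pipeline output
equals the exported truth table exactly (tested at 1e-9 relative).

What it does **not** emulate: phenology, ranging and spatial structure,
plant secondary metabolites and gut-capacity mechanisms (scarcity is
encoded directly as intake multipliers), demographic change, observer
error in bout segmentation, and day-to-day autocorrelation. Passing
recovery tests therefore demonstrates the pipeline's statistical
correctness under the stated generative assumptions — not that real field
data meet those assumptions.

Randomness uses R's default Mersenne-Twister stream under a single
configured seed; identical configurations reproduce byte-identical
studies.

## 6. Aggregation conventions and degenerate inputs

* Group-level macronutrient shares and AP:NPE are computed per focal-day
  and then averaged ("mean of daily proportions", matching mean ± SD
  presentation); a ratio-of-summed-energies alternative is exposed via
  `shares_method = "ratio_of_sums"`. Coefficients of variation are
  computed on daily values by default.
* Percentages live on the 0–100 scale everywhere (files and memory);
  energy formulas divide by 100 internally. One scale end-to-end avoids
  double-conversion bugs.
* Degenerate cases: empty focal-days give all-zero records with missing
  AP:NPE; AP = 0 with positive NPE gives ratio 0, while NPE = 0 is an
  error (undefined ratio); mixture coordinates require positive total
  energy; CV requires n ≥ 2 and nonzero mean; group summaries report NA
  CV when no finite ratios exist.

## 7. Problem sizes

The test suite generates studies of roughly 200–1,100 focal-days
(10–30 × 10³ bouts) and fits 200 seeded mixed-model replicates for the
power/type-I checks; the full suite runs in a few minutes on one core.
These sizes were chosen so Monte-Carlo standard errors sit comfortably
inside the asserted tolerances (e.g. the 1,080-day rail recovery has
expected error well below the ±0.002 band asserted for the implied
ratio).

## 8. Known limitations

* The per-focal-day archive of the motivating study is not shipped;
  `reference_daily_intakes()` is an explicitly synthetic group-resolution
  reconstruction (published day counts × published group means). It
  reproduces day-weighted cross-group aggregates exactly but carries no
  within-group variance, so it cannot validate variance-sensitive
  statistics. `read_daily_intakes()` exists so the genuine archive, where
  available, can be loaded through a column-mapping layer and pushed
  through the identical stages.
* Printed food-level AP:NPE values in summary tables of field studies are
  generally computed from unrounded laboratory profiles; recomputing them
  from rounded printed concentrations does not recover them (the test
  suite demonstrates the discrepancy), except for the exact zero-protein
  case. Such printed ratios are treated as approximate cross-checks only.
* Exact replication of mixed-model F statistics from other software is out of scope (see
  §4); the modelling stage is instead validated by parameter recovery on
  simulated data.
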