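---
title: "Methods: phenotyping analysis of wheat growth under heat and drought"
author: "phenogrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotyping analysis of wheat growth under heat and drought}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogrowth)
```

## The problem

Automated greenhouse phenotyping experiments image and weigh replicated
plants of several genotypes twice a day under contrasting irrigation
regimes at high temperature. The analysis has to turn those raw streams
into genotype-level statements: which traits respond to the genotype (G),
to the environment (E), and to their interaction (G x E) on each day; how
much water each plant transpires; how much biomass it accumulates; and
how tolerant each genotype is to water deficit. `phenogrowth` implements
that pipeline end to end, together with a synthetic "virtual greenhouse"
generator that emulates the experimental design and carries ground truth
for every downstream step.

The default design is 10 genotypes x 2 treatments x 5 replicates,
measured twice daily (08:00 and 16:00 — the schedule is fixed because the
study design specifies only "twice a day") from 15 to 37 days after
sowing (DAS), with stress imposed at DAS 30: the well-watered regime
(`WW38`) is kept above 90% field capacity while the deficit regime
(`WD38`) has water withheld down to a maintained minimum of 30% field
capacity, both at high temperature. Soil-only pots under each regime
estimate non-transpirational water loss.

## The virtual greenhouse generator

Real data from such experiments are rarely deposited, so the generator is
a first-class module, not a test fixture. It emulates:

* **Growth.** Each genotype x treatment follows a bell-shaped curve
  `y(t) = a exp(-(t-b)^2 / (2 c^2))` (amplitude `a` in g fresh weight,
  peak day `b` in DAS, width `c` in days). Before stress onset all plants
  of a genotype grow on the well-watered curve; after onset the deficit
  curve takes over, rescaled so biomass is continuous at onset. Because a
  continuity-constrained bell of the same width is fully determined by
  its peak day, `default_profiles()` *solves* the deficit peak day from
  the target peak-biomass ratio (its `drought_amp`), so a genotype built
  "tolerant" realizes exactly the well-watered curve and one built
  "sensitive" realizes exactly half the well-watered peak.
* **Image geometry.** Exposed projected area is proportional to fresh
  weight (900 mm^2/g by default) and height to its cube root (160 mm per
  g^(1/3)); these allometric defaults give a 20 g plant roughly 18,000
  mm^2 of exposed area and 43 cm of height, plausible for pot-grown
  spring wheat at tillering. Pyramidal volume is `area x height / 3`.
* **Reflectance and temperature.** Leaf temperature (around 26 C) and ten
  spectral bands (365-970 nm, on a 0-100 intensity scale) carry additive
  genotype offsets, a genotype-specific smooth temporal signature (a bump
  peaking at a genotype-dependent day — without it every band would be a
  time-constant and the reproducibility filter would rightly discard it),
  and, after onset, a treatment ramp applied to the NIR bands only plus a
  genotype x treatment interaction term. Measurement noise is additive
  Gaussian, a few percent of the signal (0.3 C for leaf temperature, 1.2
  intensity units for bands, 120 mm^2 for area).
* **Gravimetrics.** Pot weight is weighed at each timepoint and the
  irrigation recorded at a timestamp is applied immediately after that
  weighing. Between weighings the pot loses
  (transpiration + soil evaporation) x elapsed time, where transpiration
  is a per-treatment coefficient (mg H2O per h per g FW; 55 under WW38,
  lower under WD38) times current fresh weight, and soil evaporation
  defaults to 200 mg/h for every pot. Irrigation restores the treatment
  target (95% of field capacity for WW38; 30% after onset for WD38, so
  deficit pots first drain, then are maintained). Pot weights track soil
  water only — the plant's own mass is excluded from the weighing — so
  that gravimetric loss is purely water and the conservation and
  soil-correction oracles are exact identities on noiseless data.
* **Artifacts.** `inject_artifacts()` adds single-cell additive outliers
  (in multiples of the trait's noise SD) and completely-at-random missing
  values, recording every position in the ground truth.

What the generator does *not* emulate: spatially correlated noise,
diurnal physiology (transpiration depends only on biomass, not time of
day), sensor drift, segmentation failures that corrupt whole images, and
any phenology beyond the vegetative window. Tests passing on generator
data therefore demonstrate the pipeline's correctness under the assumed
statistical structure, not robustness to every failure mode of real
phenotyping platforms.

## Trait quality control

The QC chain (`qc_pipeline()`) applies, in order:

1. **Grubbs screening** per replicate group (genotype x treatment x trait
   x timepoint): the most extreme value is flagged while
   `G = max|x - mean|/sd` exceeds the two-sided critical value, repeated
   until clean with `alpha = 0.05` uncorrected across iterations (the
   conventional one-at-a-time scheme; the source analysis states neither
   the alpha nor the iteration policy, so both are explicit parameters).
   With 5 replicates the statistic is bounded by `(n-1)/sqrt(n) = 1.789`
   against a critical value of 1.715, so single 8-SD outliers sit near
   the detection boundary (roughly 80% are caught) and two corruptions in
   one group mask each other — an intrinsic property of the test at this
   replication, documented rather than hidden.
2. **Imputation** of deleted and missing cells by the mean of the
   observed values in the same replicate group. A random-forest chained
   imputer would also satisfy the interface; the group-mean rule is
   preferred because it is deterministic, respects the only structure the
   generator puts in a replicate group, and recovers masked values
   exactly on noiseless data, which makes the recovery contract testable
   at machine precision.
3. **Reproducibility filtering**: a trait is kept if, in at least one
   treatment, the median over genotypes of the mean pairwise Pearson
   correlation between replicate trajectories exceeds 0.7 *and* a Welch
   test finds replicate-pair correlations significantly higher than
   correlations of random cross-genotype pairs (one-sided P < 0.05, with
   the number of random pairs matched to the number of replicate pairs to
   keep the test balanced). Replicate correlation is computed between
   per-plant trajectories over time within genotype x treatment — the
   reading consistent with comparing replicates against random plant
   pairs.
4. **Stepwise VIF removal** on the plant x timepoint wide matrix: while
   any variance inflation factor is >= 5 the worst trait is removed;
   infinite VIFs (perfect collinearity) and ties are resolved by dropping
   the lexicographically last label, which makes the trace deterministic.

The chain is idempotent: applying it twice equals applying it once.

## Variance partitioning and LOD scores

For every trait and day, the two daily measurements of each plant are
averaged (replication must come from plants, not repeated measures within
a day) and a fixed-effects two-way ANOVA `value ~ genotype * treatment`
is fitted. Days before stress onset have a single irrigation regime, so
they are fitted with the genotype-only model and E and G x E are reported
as not applicable. Raw P values are adjusted across traits within each
(day, effect) family — the family definition that matches per-day
heatmap columns — by Benjamini-Hochberg by default; Bonferroni is
available behind a flag because the source material is internally
inconsistent about which was used. Scores are `LOD = -log10(adjusted P)`
in base 10 (the genetics convention), with adjusted P floored at 1e-16 so
LOD is capped at 16.

Group displays use Duncan's multiple range test (studentized-range
critical points at protection level `1 - (1-alpha)^(p-1)` for a span of
`p` means, harmonic-mean group size when unbalanced, ranges nested in a
non-significant range protected), with the compact letter display built
from maximal homogeneous windows; two-treatment comparisons use two-sided
Welch t-tests. Heatmap ordering uses agglomerative clustering with
Euclidean distance and complete linkage, rows sorted by label first so
ties break deterministically.

## Water use

Evapotranspiration is the water loss per hour between consecutive
weighings, `weight_before + irrigation - weight_after` over the elapsed
time; negative computed losses are reported as anomalies, never clipped.
The mean rate of the soil-only pots of the same treatment and interval is
subtracted to isolate transpiration, floored at zero with the floored
count reported. `Evap.daily` is by default the summed loss per day
(g/day); a mean-rate alternative is available. Irrigation amounts are
taken from the explicit irrigation field of the gravimetric table.

Water-use efficiency over the stress window is biomass gain per water
transpired. The denominator is built from cumulative gravimetric water
*loss* minus the soil-only share, rather than from water *supplied*: in a
regime where deficit pots drain stored soil water while irrigation is
withheld, supplied water between onset and the growth peak can be near
zero and a supply-based denominator becomes non-positive, whereas the two
readings coincide (up to the storage change) when pots are maintained at
their target. `water_use_efficiency()` itself is agnostic: it divides a
biomass gain by whatever corrected water term it is given.

## Biomass prediction

Aboveground biomass at harvest is predicted from exposed area and
pyramidal volume by a linear-family suite — ordinary least squares,
ridge, lasso, elastic net (all via glmnet) and a linear support-vector
regressor (e1071) — evaluated with a stratified 70/30 plant split and
10-fold cross-validation inside the training split for hyperparameter
selection (the alternative, cross-validating on all data, conflates
selection and assessment). A model passes when `R^2 > 0.7`,
`MRSRE < 0.3` and `|mu| < 0.05`; the bias criterion is applied to the
absolute value since bias can be negative. Among passing models the one
with smallest `|mu|` (ties by MRSRE) is refitted on all harvest-day
plants and applied to every timepoint's features, yielding the predicted
biomass trajectory used for growth modelling.

## Growth modelling and tolerance indices

Seven mechanistic forms (bell, logistic, Gompertz, monomolecular,
exponential, linear, quadratic) are fitted to genotype x treatment mean
trajectories by Levenberg-Marquardt least squares on the window from DAS
24 to the forecast bound DAS 41 (per-plant fitting is available through
the same functions). Initialization matters for convergence and is fixed:
the bell starts at `a0 = max(y)`, `b0` = day of the maximum,
`c0` = window/4; sigmoids start at the data maximum and mid-window;
the exponential from a log-linear fit. Fit quality is `R^2 = 1 -
SSR/SST` and an F test against the constant-mean model with `(p-1, n-p)`
degrees of freedom; a model passes at `R^2 > 0.7` and `P < 0.05`, and
among passing fits the highest `R^2` wins (ties to fewer parameters,
then name order). `Timemax` is the argmax of the fitted curve on the
window — closed-form (clamped) for the bell, a 0.1-day grid scan for the
other forms — and `Biomass at Timemax` is the curve there. Degenerate
inputs are handled explicitly: a constant trajectory has undefined `R^2`
and P = 1; non-convergence is recorded per model, not fatal.

The growth-rate statistic is implemented exactly as defined for this
analysis, `GR = ln(B_max - B_T1) / (Timemax - T1)` with T1 the stress
onset day — the logarithm of the biomass *gain* per elapsed day. This is
dimensionally odd for something called an intrinsic growth rate, and a
conventional relative growth rate `(ln B_max - ln B_T1)/(Timemax - T1)`
is provided behind `method = "rgr"`, but the printed form is the
default; the intent behind the printed formula is not second-guessed.

Five stress-tolerance indices compare the treatments per genotype: mean
productivity `(B_WW + B_WD)/2`, biomass-reduction ratio `B_WD/B_WW`,
inflection-point stability `Timemax_WW - Timemax_WD` (days), and the
WD/WW ratios of GR and WUE. For display, each index is min-max rescaled
to [0, 1] (a constant column maps to 0.5 and is flagged) and genotypes
are clustered with the same deterministic linkage as the LOD heatmaps.

## Problem sizes and tolerances used by the checks

The package's own test and acceptance runs use: 100 simulated bell
trajectories (2% amplitude noise) for parameter recovery, judged at 5%
median relative error and 0.5 day on Timemax; 200 small null datasets
(3 genotypes x 3 replicates x 5 days, 4 traits) for type-I control of
the LOD scan, judged against 0.05 plus twice the binomial standard
error; 900 random short vectors for the Grubbs-vs-oracle equivalence;
40-plant scenarios for the biomass-criteria and end-to-end checks, the
latter over 50 seeds with a 95% separation requirement for the built
tolerant/sensitive pair. Machine-precision claims (water balance,
zero-noise recovery) are asserted at 1e-8 relative or tighter; exact
arithmetic (tolerance indices, BH on four values) at 1e-12 or
`identical()`.

## Known limitations

* Each day is analysed independently; no repeated-measures or
  mixed-model correlation structure is fitted.
* Grubbs screening at 5 replicates has bounded power (see above) and
  cannot resolve two corruptions in one replicate group.
* The generator's irrigation policy (restore to target at each weighing)
  is one admissible reading of "irrigation compensated
  evapotranspiration"; trigger-based policies would change the supplied
  water series but not the loss-based water accounting.
* Image segmentation, multispectral-to-thermal registration and the
  wet-lab assays are out of scope: traits enter as already-extracted
  numbers.
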