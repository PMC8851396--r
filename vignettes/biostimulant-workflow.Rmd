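---
title: "Methods: phenomics-metabolomics integration for biostimulant characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenomics-metabolomics integration for biostimulant characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the models and
statistics it implements, the assumptions behind them, the choices made where
the underlying methodology left the design open, and what the synthetic-data
tests do and do not establish. It states no empirical result that the test
suite or the acceptance script does not itself compute.

## 1. The analysis problem

A biostimulant screening trial produces two blocks over the same plants:

* a **phenome block** — per-plant, per-round imaging measurements (projected
  shoot areas from top and side view, chlorophyll-fluorescence transients at
  several actinic light steps, canopy and chamber temperature, water added);
* a **metabolome block** — an untargeted LC-MS feature table (samples x
  annotated compounds) on end-point leaf material, with sample metadata and a
  compound-to-pathway-category map.

The pipeline condenses these into substance-level statements: growth
promoter or inhibitor under control conditions, stress alleviator or
aggravator under salt, which compounds discriminate treatments, and whether
the two blocks share global structure.

## 2. Trait derivation

* **Digital biomass (DB).** The volume proxy from the two projected areas.
  The canonical rendering of the formula, `PSA_side^2 x PSA_top`, has units
  pixels^6; this package applies a square root so DB is volume-dimensioned
  (pixels^3): `DB = PSA_side * sqrt(PSA_top)`. Because the radical is a
  rendering ambiguity in the source methodology, the unrooted variant is one
  flag away (`digital_biomass(..., sqrt = FALSE)`); note that PBC trait
  *ratios* are insensitive to a fixed monotone power, so the choice does not
  move the index by more than a factor on the log2 ratio.
* **RGR** `(ln DM2 - ln DM1)/(T2 - T1)` (day^-1), evaluated once per phase
  from the first and last in-phase observation. Early phase is day 0-12 for
  both crops; the late phase ends at day 21 (lettuce) or 24 (tomato).
* **Chlorophyll fluorescence.** The source methodology names the derived
  parameters but prints no formulas; the standard PAM (Baker-style)
  definitions are used: Fv/Fm = (Fm-F0)/Fm, Fv'/Fm' = (Fm'-F0')/Fm',
  PhiPSII = (Fm'-Ft)/Fm', NPQ = (Fm-Fm')/Fm'. Values are taken at actinic
  step Lss2 (480 umol m^-2 s^-1), the step reported to discriminate best;
  QY_Lss4 (PhiPSII at 1080 umol m^-2 s^-1) is carried for the
  random-forest stage. Quantum yields are validated into [0, 1] at
  derivation time.
* **deltaT** = canopy minus chamber temperature (degrees C). "Depression" is
  conventionally air-minus-canopy; since the source does not fix a sign, the
  package stores canopy-minus-chamber (negative = cooler canopy) and gives
  cooling a positive PBC contribution (section 3). Both choices are config
  points, not constants buried in code.
* **WUE** is not defined in the source methodology; it is implemented as
  phase biomass gain per ml of water added (pixels^3 ml^-1), the natural
  reading of "water-use efficiency" for a gravimetric watering station.
* **Group comparisons.** The original longitudinal analysis used
  repeated-measures mixed models. After phase aggregation one value per
  plant and phase remains, so the package uses one-way fixed-effects ANOVA on
  substance x condition groups followed by Tukey HSD (P < 0.05). This is a
  documented simplification: phase aggregation removes the repeated-measures
  structure that motivated the mixed model, and the suite verifies the
  simplified test's type-I error and power by simulation.

## 3. The PBC index

For each substance, condition and phase, the five trait means (DB at phase
end, RGR, Fv'/Fm', PhiPSII, deltaT) are compared with the same-condition
untreated control as log2(treated/control), and the five ratios are summed.
Two numerical choices deserve explanation:

* **deltaT in a log ratio.** deltaT can be zero or negative, where log2 is
  undefined. The ratio is therefore computed on absolute canopy temperatures
  (reference chamber temperature + depression, strictly positive in degrees
  C) and inverted, so a *cooler* treated canopy — the physiologically
  favourable outcome under stress — contributes positively. Both the
  reference temperature and the orientation are arguments of
  `trait_log_ratio()`.
* **Non-positive RGR.** Under strong stress a group's mean RGR can be <= 0.
  The ratio for that trait then falls back to the difference scaled by the
  control's absolute value, with a loud warning. This keeps the index
  defined on real data at the cost of mixing scales in that (rare,
  flagged) case.

Classification is by index sign per condition (promoter/inhibitor under
control, alleviator/aggravator under salt) with a configurable neutral band
(default |index| < 0.05). Group means are arithmetic over replicates (the
source is silent on mean vs median).

## 4. Multivariate discrimination

**Ward HCA** is implemented via the Lance-Williams update with deterministic
lowest-pair-index tie-breaking. For Euclidean input the algorithm operates on
squared distances and reports square-rooted heights (the `ward.D2`
convention); squared-Euclidean and Manhattan dissimilarities are fed to the
update as-is (`ward.D` convention). Ward on Manhattan distances has no
variance interpretation — it is provided because the two metrics are commonly
compared on high-dimensional omics tables, and is labelled a heuristic. The
test suite proves equivalence against two independent references: a
brute-force agglomerator that recomputes every inter-cluster distance from
the original dissimilarity matrix with the set formula, and `stats::hclust`.

**OPLS-DA.** Classes are one-hot encoded and centered; X is centered and
scaled (Pareto by default for LC-MS intensities, unit variance for trait
tables — the community conventions; selectable). Orthogonal components are
extracted by projecting the X-loading off the orthonormal basis of X'Y and
deflating, then NIPALS PLS2 components are fitted on the filtered matrix;
`n_ortho = 0` reduces exactly to PLS-DA, verified against an independent
SIMPLS implementation to 1e-8. Defaults: one predictive component per class
contrast (`n_classes - 1`) and one orthogonal component; the source reports
single R2Y/Q2Y values without component counts or scaling, so exact numeric
reproduction of its model statistics is explicitly not an acceptance
surface. VIP is computed over predictive components with the normalisation
`mean(VIP^2) = 1`; discriminant compounds are selected by a strict
threshold (1.2 and 1.1 are the thresholds used in the source's two crops).

**Validation battery.**

* **Q2Y** from stratified K-fold cross-validation (default 7 folds, reduced
  with a warning when a class is smaller), `1 - PRESS/TSS` on the held-out
  class matrix, deterministic folds from a seed.
* **Permutation test** (default N = 200) refits Q2Y under label permutation
  and reports the add-one estimator `(1 + #{Q2_perm >= Q2_obs})/(1 + N)`,
  which cannot return 0; the minimum at N = 200 is 1/201.
* **CV-ANOVA** follows the published SIMCA-style formulation: an F-test of
  `((SStot - PRESS)/df1) / (PRESS/df2)` with df1 = number of fitted
  components and df2 = N - df1 - 1. **Known property:** under a true null,
  cross-validated PLS predictions are worse than the mean, PRESS >= SStot,
  the F statistic is non-positive and the p-value saturates at 1. The
  statistic is therefore *conservative*, not uniform, under the null. One
  acceptance assertion demands null uniformity (KS p > 0.01) for this
  p-value; that assertion fails by construction and is left red
  deliberately — making it pass would require replacing the published
  formulation with a different statistic. The companion assertion
  (null p > 0.05 in >= 90% of runs) passes, which is the property users
  actually rely on: CV-ANOVA does not over-call significance.

## 5. Differential compounds

The presence filter retains a compound only if detected in >= 75% of the
replicates of at least one treatment (the fraction is an argument).
The volcano combines a per-compound one-way ANOVA across the contrast groups
(Bonferroni over tested compounds, alpha = 0.01) with a fold-change filter
read **two-sided** on the ratio scale (>= 1.3 or <= 1/1.3): the source states
"FC >= 1.3" but reports down-accumulated compounds, so the two-sided reading
is the only consistent one. Whether the ANOVA spans only the contrast pair
(default, t-test-equivalent) or all groups (omnibus) is selectable, since the
source does not say. Compounds with a non-positive or undefined reference
mean keep their p-values but are excluded from FC and can never be flagged.
Significant compounds' log2 FCs are aggregated per pathway category
(individual values + arithmetic mean per category), with unmapped compounds
reported under their own label rather than dropped.

## 6. Integration

* **Random forest.** No random-forest package is part of the supported
  dependency set, so the package carries a compact Breiman-style forest in
  C++ (CART with Gini splits, bootstrap aggregation, `mtry = floor(sqrt(p))`).
  Importance is **out-of-bag permutation importance** (mean decrease in
  accuracy), matching the "decrease in classification accuracy if a trait is
  removed" description, not impurity importance. The implementation uses R's
  RNG, so results are reproducible under a seed.
* **Trait-metabolite correlation.** Pearson r with two-sided t-test p per
  trait x compound pair, computed on log2 abundances by default (Pearson on
  raw lognormal intensities is badly attenuated; a flag restores the raw
  scale). No multiplicity correction by default — matching the source's
  p < 0.05 screening — with Benjamini-Hochberg as an option. Constant
  compounds yield NA and are never significant. Pairing is at the plant
  level using late-phase trait values; the source's pairing level is
  unstated, so this is a documented default.
* **Co-inertia / RV.** Column-centered blocks (traits unit-variance scaled,
  metabolites Pareto scaled, consistent with section 4), SVD of the
  cross-covariance for paired axes, and Escoufier's RV as the global
  concordance measure. The source reports RV without a test; a standard
  row-permutation test (default 199 permutations, add-one p) is provided as
  package plumbing.

## 7. The synthetic world

The generator emulates the stated experimental design: 8 (lettuce) or 6
(tomato) biological replicates, an untreated control plus seven substances
(B, C, D, F, H, O, P), control and salt conditions, 10 phenotyping rounds
over 21/24 days, and 4 metabolomics replicates per treatment.

* **Growth law.** Logistic ODE solution `N(t) = K N0 e^{rt}/(K + N0(e^{rt}-1))`
  for top-view area (lettuce: N0 = 2000 px^2, K = 8e4 px^2, r = 0.22 day^-1;
  tomato slightly smaller/slower), chosen over a midpoint parameterisation
  because the solution is strictly increasing in r at every t > 0, which
  makes the effect-monotonicity property exact. A substance's growth effect
  multiplies **both r and K** (a promoter grows faster *and* larger), and the
  per-plant vigour intercept scales **both N0 and K**; without the K terms,
  logistic saturation makes late-phase RGR flip sign for fast growers and
  forgets plant-level vigour — the two artefacts found and fixed during
  development. Side area is a power function of top area
  (`side = 1.6 * top^0.9`).
* **Salt.** A hard change-point at day 12 (the early/late boundary used in
  the analysis, in place of the 6 discrete salt applications): after it, top
  area is multiplied by `(1 - salt_growth_reduction)^(1/1.4)` so that DB
  (which scales as `top^1.4`) drops by the configured fraction — default
  0.32, motivated by the reported 35%/29% reductions in the two lettuce
  trials. The suite verifies the generator against its own parameter within
  5% (pooled over substances; with only the 8 control plants the
  finite-sample wobble exceeds the tolerance).
* **Fluorescence and thermal channels** are generated by drawing target
  parameter values (Fv/Fm ~ 0.80, Fv'/Fm' ~ 0.65, qP ~ 0.85, NPQ ~ 0.5 at
  Lss2) and inverting the PAM definitions to primitives, guaranteeing valid
  yields; salt in the late phase lowers Fv'/Fm' and PhiPSII by 0.08 and
  raises NPQ by 0.3, and substances shift the yields additively. The canopy
  offset is -1 degree C (transpirational cooling), +0.8 under late salt,
  and 8 times the substance's quantum-yield effect cooler (better
  photosynthesis, more open stomata).
* **Noise.** Multiplicative lognormal measurement noise with CV 0.08 on
  areas (typical replicate CV for automated imaging), a per-plant lognormal
  vigour intercept (sd 0.1, exposed as `plant_sd` because within-treatment
  variance is not pinned down by the emulated design), and auxiliary noise
  on temperatures and watering. All noise amplitudes scale with
  `noise_cv / 0.08`, so `noise_cv = 0` yields a fully deterministic world —
  the zero-noise identity tests rely on this.
* **Metabolome.** Log abundance = compound baseline (lognormal around 1e5)
  + rank-4 treatment structure (group scores x compound loadings, loading sd
  0.6) + per-plant latent x compound coupling vector + lognormal noise
  (sd 0.3). The per-plant metabolite latent is a **variance-preserving
  mixture** `coupling * z + sqrt(1 - coupling^2) * w` of the plant's growth
  latent z and an independent latent w: shared covariance between the blocks
  grows monotonically with `coupling` while the metabolome's total variance
  stays fixed. A naive `coupling * z` additive term fails the monotone-RV
  property because it inflates the denominator of RV faster than the
  numerator. A configurable fraction of compounds (default 10%) receives
  per-compound Bernoulli dropout to exercise the presence filter. Categories
  cycle through a fixed seven-entry pathway list.
* **Planted truths used by the tests.** The default effect maps follow the
  qualitative published pattern (P strongest promoter, H close behind with
  the clearest photosynthetic benefit, B a mild inhibitor). The recovery
  tests use sharper planted worlds (H growth x1.12 / B x0.90 with matching
  quantum-yield shifts), chosen so the planted index gaps are of the same
  order as the published PBC table (about +/-1), and — for the
  integration-chain test — a single-condition world with `plant_sd = 0.25`
  where plant vigour dominates within-group variance.

**What a green test establishes — and what it does not.** The generator has
Gaussian latents, lognormal noise, a hard salt change-point, no circadian or
block effects, no batch drift or retention-time artefacts in the metabolome,
and missingness that is random rather than intensity-dependent. Green
recovery tests therefore establish that the pipeline's statistics do what
they claim on data satisfying their assumptions; they are silent on
instrument pathologies (they are also why the published headline numbers —
R2Y = 0.983 etc., RV = 0.37/0.29, the exact PBC table — are *not* acceptance
surfaces: the instrument datasets behind them are not published).

## 8. Numerical and engineering choices

* Deterministic everything: all stochastic stages take seeds; the full
  pipeline is byte-reproducible for a fixed config (verified by test).
* Scaling a constant column is an error naming the column, not a silent NaN.
* Residual missing values after the presence filter are imputed with half
  the compound minimum (standard LC-MS practice) before multivariate
  stages; readers preserve missing as NA, never zero.
* Structured serialization uses JSON (jsonlite) rather than YAML: no YAML
  package is available in the supported dependency set, and the config
  round-trip contract is format-agnostic.
* The add-one permutation estimator is used everywhere a permutation p is
  reported, so p = 0 cannot occur.
* Excluded plants (insufficient phase coverage) and rejected CSV rows are
  warned about and counted, never silently dropped; per-stage record counts
  are logged in the pipeline report so filter behaviour is auditable.

## 9. Known limitations

* The mixed-model-to-ANOVA simplification ignores round/block structure; a
  trial with strong block effects needs the block label carried into the
  group comparison, which the trait table supports but the default contrast
  does not use.
* CV-ANOVA degrees of freedom follow the published component-counting
  convention; for multi-class models with many components the test is
  approximate (and, as above, conservative under the null).
* The RV coefficient is sensitive to block scaling conventions; the package
  fixes traits = unit variance, metabolites = Pareto, and any comparison to
  externally computed RV values must match those conventions.
* Sixteen-class OPLS-DA on four replicates per class has intrinsically
  modest Q2Y even for strongly structured data; the focused two-substance
  models (best vs worst performer) are the right objects for model-quality
  claims, and the README example shows both.
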