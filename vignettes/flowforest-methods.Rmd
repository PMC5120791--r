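---
title: "Methods: random-forest CBF surrogates from transcranial Doppler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest CBF surrogates from transcranial Doppler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Transcranial Doppler (TCD) sonography measures blood flow *velocity* in the
middle cerebral artery (MCA); what clinicians usually want is the *perfusion*
of the MCA territory, cerebral blood flow (CBF, ml/min/100g), which arterial
spin labeling MRI (pCASL) measures directly but expensively. This package
provides the statistical machinery to ask: given TCD velocity plus ten
easily available clinical covariates (hematocrit, intracranial volume,
height, BMI, age, head length, diabetes, hypertension, gender, MCA
diameter), how well can a flexible nonparametric regressor predict
MRI-measured CBF — and, crucially, how does that answer change with how
much MRI information about *the same patient* the model is allowed to see?

Because no patient-level dataset ships with the package, every component is
exercised on synthetic cohorts whose marginal structure matches published
summary tables for a cohort of 88 older adults contributing 261 left/right
MCA measurements. All conclusions from the test suite are therefore
statements about the *method* under controlled generative assumptions, not
about any real population.

# The regression model

## Trees

A regression tree partitions the predictor space into $K$ hyper-rectangles
$\Omega_k$ and predicts the constant
$c_k = \frac{1}{|I_k|}\sum_{j \in I_k} y_j$ inside each, where $I_k$ indexes
the training rows in $\Omega_k$:
$$ y \approx T(x) = \sum_{k=1}^{K} c_k \, \chi_k(x). $$
Growth is recursive binary splitting. At a node holding rows $R$, every
candidate predictor and every admissible cut is scored by the reduction in
the within-node sum of squared errors of constant fits; the best cut splits
$R$ into two children. Numeric cuts sit at midpoints between consecutive
distinct sorted values (the canonical CART convention); categorical
predictors are split by enumerating every nonempty proper subset of their
observed levels (all clinical factors here are binary, so this enumeration
is a single candidate). A node is split only if

* it holds at least `nodemin` rows (default 5), **and**
* the best candidate split strictly reduces the SSE with two nonempty
  children.

The second condition is not part of the classic size-only stopping rule but
is required for termination on constant data and never changes the fitted
function (a zero-gain split produces two leaves with identical means).

## Forests

`rforest()` grows `ntree` trees (default 500), each on an independent
bootstrap resample of the $N$ rows, drawing `mtry` (default 3) candidate
predictors uniformly without replacement *at every node*. The prediction is
the plain tree average
$$ F(x) = \frac{1}{T}\sum_{t=1}^T T_t(x), $$
which immediately implies the hull property tested in the suite: no
prediction can leave $[\min y, \max y]$ of the training response.

Whether the `mtry` draw happens per node or per tree is a genuine design
fork; per-node is implemented, matching the standard random-forest
construction in which the variable draw sits inside the node loop.

## Determinism and tie-breaking

Reproducibility is treated as a first-class contract:

* a single master seed spawns one independent `splitmix64` stream per tree
  (bootstrap draw + node-level variable draws), so results do not depend on
  the order in which trees are built — the first $t$ trees of a $T$-tree
  forest are identical to a $t$-tree forest with the same seed;
* gain ties are broken toward the earliest predictor in schema (column)
  order, then the lowest threshold / lowest canonical level mask;
* gains must exceed $10^{-12}(\sum y_i^2 + 1)$, a round-off guard that makes
  "no split improves the fit" robust to floating-point accumulation noise on
  constant nodes.

These rules are exactly mirrored by an independent brute-force CART oracle
in the test suite, and the grown structures (split variables, thresholds,
children, leaf means) are compared for literal equality on hundreds of
random small tables.

The tree search is implemented in C++ (via Rcpp), as the field's forest
implementations are: the leave-out experiments below fit one forest per
measurement, i.e. hundreds of forests per experiment, which a pure-R
recursion would not sustain at useful ensemble sizes.

# Iterative forest imputation

Let $\xi$ be the $N \times (p+1)$ matrix of the 11 predictors plus the CBF
response. For column $s$ with missing index set $i_{mis}(s)$, write
$\zeta_{obs}(s)$/$\zeta_{mis}(s)$ for the observed/missing parts of
$\xi^{(s)}$ and $\eta_{obs}(s)$/$\eta_{mis}(s)$ for the corresponding rows
of the remaining columns. `rf_impute()`:

1. initializes missing cells by column mean (numeric) or mode
   (categorical, ties toward the first sorted level);
2. sweeps the incomplete columns in ascending order of missing count (the
   best-informed columns are re-imputed first, and their refreshed values
   feed later columns within the same sweep), fitting a forest with
   predictor $\eta_{obs}(s)$ and response $\zeta_{obs}(s)$, then overwriting
   $\zeta_{mis}(s)$ with its predictions at $\eta_{mis}(s)$;
3. repeats until the matrix stops changing.

The change statistic after each sweep is
$\Delta_{num} = \sum (curr-prev)^2 / \sum curr^2$ over originally-missing
numeric cells and the fraction of changed levels over originally-missing
categorical cells. Stopping happens when both fall below tolerance
($10^{-4}$ numeric, exactly 0 categorical), when $\Delta_{num}$ *increases*
relative to the previous sweep (the previous matrix is returned — the
established stopping rule for this scheme), or at `max_iter` (default 10;
only the first two count as convergence).

Two deliberate choices:

* **Categorical responses.** The forest is regression-only (no
  classification mode is provided anywhere in the package), so categorical
  columns are imputed by regressing their integer level codes and rounding
  each prediction to the nearest observed code. For binary factors this is
  a vote-share threshold at 1/2 and guarantees level closure (imputed
  values are always observed levels).
* **The response participates.** The CBF column is part of $\xi$ exactly as
  the scheme is written, which means a single imputation pass on the full
  matrix lets response information flow into predictor cells that later
  cross-validation treats as training input. That is the "impute once, then
  cross-validate" reading; it is the default because it matches the
  pipeline this package reimplements, but `exclude_response = TRUE`
  (and per-fold imputation, by calling `rf_impute()` inside your own loop)
  are available because the leakage is real. The default imputation
  ensemble is 100 trees rather than 500 — one forest per incomplete column
  per sweep makes the full-size ensemble wasteful, and imputation accuracy
  plateaus well below that.

Observed cells are bit-identical through the whole process (asserted
cell-exactly in the tests), and identical seeds reproduce identical imputed
matrices.

# The Poiseuille TCD estimator

Under an idealized Poiseuille (parabolic, axisymmetric, steady) velocity
profile, the centerline velocity $v$ measured by TCD at insonation angle
$\theta$ gives the flow estimate
$$ CBF_{TCD} = k \cdot \frac{\pi R^2 M v}{2 \cos\theta}, $$
with $R$ the vessel radius (mm; `D = 2R` may be supplied instead), $M$ the
territory mass (g), and $k$ a unit conversion constant. Two caveats are
documented rather than resolved:

* **Mass normalization.** The formula carries $M$ in the numerator, while a
  per-100g perfusion value requires dividing by the territory mass; the
  convention linking the two is not fixed by the formula itself. The
  default $k = 60/270^2$ makes the estimate numerically equal to the
  volumetric reading $\pi (R/10)^2 (v/\cos\theta)/2 \cdot 6000/M$
  (ml/min/100g) at the reference territory mass of 270 g, so default-cohort
  outputs land in a physiological range; `conversion` is a plain argument,
  and `unitless = TRUE` sets $k=1$ for formula-level work. The estimator is
  exactly linear in $v$ and $M$ and quadratic in $R$ (ratio-tested), so
  correlation analyses are unaffected by $k$.
* **Angle factor.** `angle_factor(theta)` returns $1/\cos\theta$ as
  written; note $1/\cos 40^\circ \approx 1.305$, a 30.5% change — angle
  uncertainty up to 40° does *not* reach a 40% velocity effect under this
  factor.

`diameter_error_propagation(delta)` evaluates $(1+\Delta)^2 - 1 =
2\Delta + \Delta^2$: the flow scales with the vessel cross-section, so a
10% diameter error contributes a 21% flow error — comparable to the entire
healthy/diseased CBF difference in the cohort tables, which is the
quantitative heart of the argument that BFV is a fragile CBF surrogate.
Non-parabolic, non-axisymmetric or time-varying profiles are *not*
modeled; the estimator should be read as the best-case idealization.

# The synthetic cohort generator

`generate_cohort()` emulates the *published summary structure* of the study
cohort; it is a study-conditions generator, not a patient simulator.

What it matches:

* 88 patients, 261 measurements; the measurement-count distribution over
  patients (1, 49, 1, 32, 1, 3, 0, 1 patients with 1..8 measurements),
  scaled by largest-remainder rounding for other cohort sizes;
* clinical group counts healthy/HTN/DM/DM-HTN = 28/41/2/17 (exact
  largest-remainder counts, randomly assigned to patients), 38/88 male;
* per-group means and SDs of the side-independent covariates and per-group,
  per-side moments of velocity, diameter and CBF, via zero-truncated normal
  draws (all quantities are positive physical measurements and only mean±sd
  is published; truncation bias is negligible at ≥9 SDs from zero);
* territory mass and insonation angle on 98 of 261 rows (mass
  $\mathcal N(270, 30^2)$ g truncated at zero — a mid-range value for an
  adult MCA territory — and angle uniform on [0°, 40°], the range
  achievable through a temporal insonation window);
* a missingness process (`inject_missingness()`) that is MCAR with a
  uniform rate $q = 1-(134/261)^{1/7} \approx 0.091$ on the seven
  continuous predictors, calibrated so the expected number of complete rows
  is exactly 134 of 261. Age, the categorical predictors and the CBF
  response stay observed (the published CBF counts cover all 261
  measurements). A user-supplied mask hook supports other mechanisms.

Dependence structure: side-dependent variables combine a patient-side
latent level (variance fraction $1-w$) with per-visit redraws (fraction
$w$, `visit_sd_fraction`, default 0.2 — repeat visits resemble each other
strongly but not perfectly, which is what makes the leave-same-visit-out
design informative). Under the null effect mode, left and right CBF
additionally share a per-patient latent term whose variance fraction is
`lr_cbf_correlation` (default 0.75: left/right perfusion of one brain is
reported as "generally correlated" without a coefficient, and 0.75 makes
the opposite side strongly but not trivially informative).

The predictor→CBF link is configurable (`effect_spec()`):

* `mode = "null"`: CBF is independent of every predictor *given clinical
  group and side*. Marginal correlations through the group (diseased
  patients have both lower CBF and, e.g., diabetes = Y) are a property of
  the published group moments, not a bug; the null-fidelity tests condition
  on group and side accordingly.
* `mode = "planted"` (default): CBF is a linear combination of standardized
  predictors plus a per-patient random offset (SD 0.5) and noise (SD 0.5 by
  default), rescaled to the configured group/side CBF moments. The default
  coefficients put the largest weight on velocity (1.0), moderate weights
  on diameter, hematocrit and age (±0.4–0.5) and small weights elsewhere —
  a deliberately optimistic world in which TCD-accessible information
  really does carry CBF, chosen once so that signal-recovery tests have a
  planted truth to find. The true relationship in any real cohort is
  unknown; nothing in the package estimates these coefficients from data.

What it does **not** emulate: measurement error structure, non-normal
tails, informative (MAR/MNAR) missingness, physiological dynamics (CO₂
reactivity, blood-pressure coupling), or any image-formation process.
Passing tests therefore demonstrate correctness and calibration of the
*pipeline* under MCAR Gaussian-latent conditions; they cannot certify
behavior on real clinical tables with structured missingness.

# The four leave-out experiments

For a complete table, `run_experiment()` fits one forest per measurement
and predicts it, with training rows chosen by design:

| design | training excludes |
|---|---|
| `exp1_measurement` | the test measurement only |
| `exp2_patient_side` | same patient *and* same side |
| `exp3_same_time` | same patient *and* same visit |
| `exp4_patient` | every row of the test patient |

"Measurements taken at the same time" is interpreted as sharing
`(patient_id, visit_id)`: a visit *is* an occasion at the clinic. The four
designs nest — training(exp4) ⊆ training(exp2), training(exp3) ⊆
training(exp1) — and both the nesting and the exclusion definitions are
asserted exhaustively for every test row on every run, so leakage from the
held-out patient/side/visit is structurally impossible rather than merely
unlikely. Moving from exp1 to exp4 removes intra-patient information; the
gap between their correlations is the package's measure of how much of the
apparent predictive skill is really "the same patient's other MRI
measurements".

Per-experiment results report each row's learning-set size (whose min–max
range depends on the test patient's measurement count), the Pearson
correlation between predicted and measured CBF, and its two-sided p-value
from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. p-values are
reported *unfloored* — the common software floor of $2.2 \times 10^{-16}$
is a printing convention, not a probability — with perfectly collinear
input clamped to the smallest positive double. A seeded permutation option
(default 10,000 permutations) exists for small-n verification of the t
approximation. One forest per test row (rather than per fold) is the
literal leave-out construction; at 261 rows and configurable `ntree` it is
affordable, and each row's forest gets its own derived seed so evaluation
order is irrelevant.

A `strata` argument restricts training to the test row's stratum (e.g.
health class), reproducing the stratified rerun variant; rows whose
response was imputed can be dropped via `response_observed`.

# Problem sizes and numerical choices in the test suite

The suite runs entirely on generated data with fixed seeds and is sized for
a desk machine: oracle-equivalence on 100+ random tables of ≤12 rows;
exhaustive leakage/nesting checks on the full 261-row default cohort; null
calibration over 10 seeds and signal recovery over 3 seeds with 100-tree
forests (the correlation estimate is insensitive to ensemble size well
below the 500-tree default used for reported analyses); imputation quality
over 10 seeds with 50-tree imputation forests. Oracle-comparison fixtures
place predictors and responses on a dyadic grid (multiples of 0.25) so that
split-gain ties are exact in double precision in both implementations and
tie-break equality is a real test of the rule, not of accumulator width.

Known limitations: no out-of-bag error, variable importance, surrogate
splits or classification mode (all out of scope by design); categorical
predictors are limited to 31 levels (bitmask subsets); imputation provides
single (not multiple) imputation and no uncertainty propagation; the
planted-effect generator is linear in standardized predictors and cannot
represent interactions or nonlinear links, so "signal recovery" results
speak to that family only.
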