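---
title: "Modelling transitions between spirometric COPD states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transitions between spirometric COPD states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirotrans)
```

## The model

`spirotrans` studies the longitudinal stability of the spirometric COPD
diagnosis. A post-bronchodilator session is mapped to one of four ordinal
states — `normal`, `gold1`, `unclassified` (preserved ratio with impaired
FEV1, also called PRISm), `gold2plus` — by crossing two dichotomies:
airflow obstruction (FEV1/FVC below the criterion cut) and low lung
function (FEV1 below 80 % of the NHANES-III predicted value). Severity is
ordinal in this order: health status and FEV1 worsen monotonically along
it, which is what justifies calling a move *down* the order beneficial.

Consecutive classifiable visits spaced 1.5 ± 0.5 years apart form
**observation units**. The transition model is deliberately simple: a
time-homogeneous first-order ("Markov-like") description in which all units
are pooled across subjects and visit indices and

$$\hat P_{se} = \frac{n(s \to e)}{n(s \cdot)}$$

is reported with its denominator. Rows with no units are undefined (`NA`),
never zero. We do not estimate continuous-time transition intensities: the
scientific object here is the empirical 18-month transition probability,
and an intensity model would assert more structure than the design gives.

Each unit gets three labels. *Beneficial*: severity decreased, or the
normal state was maintained (primary prevention counts as benefit).
*Resolution*: a diseased state returned to normal (always beneficial).
*Harmful*: severity increased, or `gold2plus` persisted. Persistence in
`gold1` or `unclassified` is neutral. Over the 16 start×end cells the
labels partition as: beneficial and harmful never co-occur, resolution
implies beneficial, and exactly `gold1→gold1` and
`unclassified→unclassified` are neutral — properties the test suite checks
against a hand-written 16-row oracle.

### Assumptions

* **First order, time homogeneous.** Pooling across unit indices assumes
  the 18-month transition law does not drift over follow-up. This matches
  the reporting convention of a single matrix; per-interval matrices are
  available by filtering units on `unit_index`.
* **No imputation.** Sessions with missing post-bronchodilator values are
  excluded (with counts); a 3-year gap is one missed visit, not two
  imputed units.
* **Units are exchangeable within subject given the start state** for the
  probability estimates; dependence is then handled at the inference stage
  (below), not the estimation stage.

## Inference for predictors

The beneficial outcome is modelled at the unit level with binomial-logit
regression — the only family consistent with reporting odds ratios. The
default correlation treatment is an independence working model with
cluster-robust (sandwich) variance by subject, because subjects contribute
2–5 units each. A hand-written GEE-style exchangeable working-correlation
option is provided for sensitivity; with independent clusters the two
coincide (tested). Wald 95 % intervals are formed on the log-odds scale and
exponentiated. Quasi-separation (boundary estimates) is flagged, not
silently dropped, and constant predictors are removed with a warning. No
multiplicity adjustment is applied, matching the presentation style of the
analyses this reproduces; interpret marginal p-values accordingly.

Interaction of start state with a predictor is tested by adding
state×predictor product terms (state as a 4-level factor) and a joint Wald
chi-square on the products with the cluster-robust covariance. If any
state×predictor cell is empty the test is reported as not estimable rather
than fitted on a defective design.

Time-varying smoking enters as current-smoking-at-unit-start, refitted per
unit; it is excluded from default multivariable models (configurable),
mirroring the usual finding that it does not predict beneficial transition.

## Tunable parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| ratio cut | 0.70 (or LLN) | fraction | fixed GOLD criterion; LLN variant for the age-fair alternative |
| %pred cut | 80 | % | GOLD low-FEV1 threshold |
| unit window | 1.5 ± 0.5 | years | protocol spacing; how off-schedule visits were handled originally is unstated, so the tolerance is explicit and configurable |
| reversibility | ≥ 12 % and ≥ 200 mL | — | standard significance rule, FEV1 and/or FVC, thresholds inclusive |
| `any_time` | `"unit"` | — | see below |
| cluster correlation | independence + robust SE | — | exchangeable option available |
| age/BMI dichotomies | 60 y, 25 kg/m² | — | conventional row labels; configurable |

**Boundary semantics.** Both staging thresholds are printed with "≥" on the
normal side, so a session at exactly ratio 0.70 and 80 % predicted is
normal; ties are never broken stochastically. The reversibility thresholds
are likewise inclusive. These conventions are frozen in tests because the
source definitions never discuss ties.

**"At any time" ambiguity.** A summary "probability of beneficial
transition at any time during follow-up" supports two readings: the pooled
per-unit conditional probability (every 18-month opportunity counts) and a
per-subject "ever" probability (a subject counts once per start state).
Both are implemented (`any_time = "unit"` / `"subject"`); the unit reading
is the default because it is the quantity the pooled transition matrix
already estimates. Neither is asserted to be the original computation.

## Reference equations

Predicted FEV1, FVC and FEV1/FVC come from the NHANES-III adult polynomial
equations (intercept, age, age², height² terms per sex × ethnicity
stratum), shipped as a versioned, checksummed delimited-text table so an
alternative reference set can be dropped in. The FEV1/FVC ratio equations
include the published lower-limit-of-normal intercepts; the FEV1/FVC
*volume* LLN intercepts are derived as predicted intercept minus
1.645 × residual SD (a homoscedastic 5th percentile, with the residual SDs
recorded in the table). Only the ratio LLN participates in staging; the
volume LLNs are carried for completeness. Cohort ethnicity labels map to
equation strata configurably (Hispanic → mexican_american,
non-Hispanic white → caucasian by convention); subjects of other/unknown
ethnicity fall back to the caucasian stratum with a warning. Ages above the
derivation range (80 y) are extrapolated with a warning rather than
rejected, since follow-up of a 75-year-old legitimately passes 80;
paediatric segments are out of scope and rejected.

Percent predicted is always computed at the session's *current* age and
height: lung function is judged against the reference for the person being
measured that day, and this matches standard practice. Whether
reversibility was assessed once or per visit is unstated in the source
design; the default carries the baseline session's reversibility forward
(configurable to per-visit).

## The synthetic cohort generator

No cohort of this kind is publicly deposited, so the generator is a
first-class module, not a test fixture. Its defaults *are* the study
conditions: 1553 subjects, ~80 % women, baseline age 56 ± 9 truncated to
40–75, ≥ 20 pack-years, visits every 1.5 years with a mean of four per
subject (range 2–6, a per-visit dropout hazard of 0.25 after the guaranteed
second visit), and a baseline state mix of 956:145:191:261.

**Latent mode.** Truth is parameterised in (FEV1 %pred, FEV1/FVC) space:
baseline values are drawn from state-conditional truncated normals matching
the cohort's baseline tables (97.4 ± 10.6 / 91.0 ± 8.9 / 72.0 ± 8.5 /
61.2 ± 14.7 %pred; ratios 78.7 ± 4.5 / 65.4 ± 3.4 / 76.4 ± 4.4 /
56.4 ± 10.1 %), truncated to the assigned state's decision region via
inverse-CDF sampling (an infeasible region raises a diagnostic error).
Truth then declines linearly with subject random slopes (30 ± 15 mL/year,
converted to %pred points at the subject's predicted FEV1; ratio
0.20 ± 0.15 points/year). Parameterising truth in %pred space is a
deliberate design choice: the reference prediction itself falls with age,
so a constant true *volume* would drift upward in %pred across visits and
a noise-free zero-decline subject could cross the 80 % line — violating the
invariant that zero noise plus zero decline means a constant state. In
%pred space that invariant is exact, and the noise-free round trip
(pipeline classification equals hidden truth at every visit) is tested at
100 %.

Measured values are truth × correlated log-normal noise:
`sdlog = sqrt(log(1 + cv²))` with a mean correction so the multiplier is
unbiased, default `cv = 0.04` and FEV1–FVC error correlation 0.7 (ratio
threshold flips depend strongly on that correlation; no noise model is
given by the source, so both are explicit knobs). In rare tail draws the
measured FEV1 is clamped to the measured FVC, reflecting the physical
constraint FEV1 ≤ FVC. Pre-bronchodilator values divide the
post-bronchodilator ones by (1 + r) with a per-subject gamma response
fraction (mean 4 %), so ~5 % of subjects show significant reversibility —
in the range of the cohort's baseline tables. SGRQ scores are
state-conditional Gaussians (17.0/17.9/25.6/31.6 ± published SDs,
truncated to 0–100) used only by reporting. The decline and noise defaults
were chosen once so that the default cohort reproduces the baseline state
mix within ±3 percentage points, which the acceptance suite verifies.

**Markov mode.** States evolve by a user-supplied row-stochastic matrix;
emitted spirometry sits at each state's region centroid so classification
recovers the chain exactly. Injected predictor effects shift the per-step
odds of a beneficial move on the logit scale, rescaling the beneficial and
non-beneficial cell groups proportionally — an exact logistic effect on the
unit-level outcome, which is what makes unbiased odds-ratio recovery a fair
test of the predictor models. In latent mode an injected odds ratio instead
shifts the decline slope by −20·log(OR) mL/year, a qualitative (not exactly
logistic) effect.

**Randomness.** Everything flows from one integer seed; per-subject
sub-seeds are drawn up front, so enlarging a cohort never perturbs existing
subjects, and equal seeds give byte-identical tables (tested).

**What the generator does not emulate.** True incident obstruction is
driven only by the slow ratio drift, so latent-mode transition
probabilities are milder than a real cohort's (the generator is calibrated
to the baseline cross-section, not to the published transition rates);
there are no exacerbations, no height loss with ageing, no within-subject
heteroscedasticity, and dropout is missing-at-random by default (a
covariate-dependent mode — younger, current-smoking, lower-function
subjects leaving earlier — is available). Passing tests therefore
demonstrate correctness of the *machinery* (staging, unit construction,
estimation, inference, calibration under a known truth), not agreement
with any particular cohort's published transition probabilities.

## Numerical choices and degenerate inputs

* Empty transition-matrix rows are `NA`, and summaries report zero
  denominators as undefined.
* Duplicate visit timestamps are deduplicated with a warning; subjects with
  fewer than two classifiable visits are dropped with a count; the
  accounting identity `subjects_in = analyzed + dropped` is asserted on
  every pipeline run.
* Logistic fits use `glm.fit`; separation is detected heuristically
  (|log-OR| > 10 or robust SE > 50) and flagged in the output.
* The exchangeable GEE iterates IRLS with a moment estimate of the
  intra-cluster correlation, clamped to [0, 0.95], and stops at a 1e-8
  step norm or 25 iterations.
* Report rendering uses fixed `sprintf` formats throughout, so repeated
  runs are byte-identical and a report can be regenerated exactly from its
  logged metadata (criterion, tolerance, seed, input fingerprint).

## Problem sizes used by the test suite

The validation suite exercises the scales the methods are designed for
while staying desk-sized: a 10,000-point staging grid against a brute-force
oracle; 44,000 two-visit subjects for matrix recovery (≥ 10,000 units per
row, every cell within 3 binomial SEs of the known matrix); 20 replicates
of 1,500-subject cohorts per noise level for the regression-to-the-mean
curve; 200 replicates of 1,500-subject cohorts for odds-ratio recovery
(pooled estimate within ±10 % of a true OR of 2, CI coverage 92–98 %); and
500 replicates of 300-subject cohorts for null calibration (uniform
p-values, ~5 % type-I error). These sizes were chosen as the smallest that
make the Monte-Carlo error negligible relative to the property being
asserted.

## Known limitations

* The four-state staging attaches equal weight to large and small
  lung-function changes near the cuts; with measurement noise this
  manufactures apparent transitions (regression to the mean). The package
  quantifies this — resolution from `unclassified` rises monotonically with
  noise even under zero true change — rather than pretending it away.
* Death and censoring are not modelled as absorbing states.
* The GOLD 2011+ symptom/exacerbation grouping and the subdivision of
  stages II–IV are out of scope (stage II+ is pooled).
* Volume LLN intercepts are a documented homoscedastic derivation, not the
  published table rows; only the ratio LLN affects staging.
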