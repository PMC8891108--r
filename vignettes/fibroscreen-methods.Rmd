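---
title: "Methods and design of the fibroscreen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the fibroscreen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroscreen)
```

`fibroscreen` implements the analysis chain of an anti-fibrotic compound
screen — plate quality control, dose–response inference, ADMET-based
candidate ranking, migration quantification, and the miRNA/panel/RNA-seq
discovery stages — together with generators that simulate every input from
known ground truth. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic data do and do not establish about real data.

## Dose–response model

All potency inference uses the four-parameter logistic (4PL) curve

$$y(d) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
        {1 + (d/\mathrm{EC50})^{\mathrm{hill}}},$$

with the inhibition sign convention `hill > 0`: the response falls from
`top` (vehicle level) to `bottom` as dose rises. Responses are first
normalized so the vehicle-control mean is 1 and the assay floor (the mean
of the full-inhibition controls) is 0 (`normalize_to_top()`).

Numerical choices in `fit_4pl()`:

* **Parameterization and bounds.** EC50 is optimized as `log10(EC50)`
  with box bounds spanning the tested doses ± 2 decades; `hill` is
  bounded to `[0.05, 20]` and `bottom` to `>= 0` by default while `top`
  is free. This stabilizes an otherwise ill-conditioned fit and matches
  the normalized floor/ceiling while tolerating overshoot. The start is
  taken from the plateau means and the dose whose mean response is
  nearest the half-maximum; a short ladder of deterministically perturbed
  fallback starts guards against rank-deficient Jacobians at the first
  guess.
* **Weighting.** Absorbance noise scales with signal, so the default is
  iteratively reweighted least squares with weights $1/\hat y^2$
  (three reweighting passes, with a floor at 5% of the largest fitted
  value to keep bottom-plateau weights finite). `weighting = "none"`
  gives plain least squares under a constant-variance assumption; with
  signal-proportional noise its intervals are anti-conservative, which is
  why relative weighting is the default.
* **Confidence intervals.** 95% intervals are asymptotic
  (curvature-based, t quantile on $n-4$ df), computed on the log10 scale
  for EC50 and back-transformed. Whether such intervals should be
  curvature-based or profile-based is genuinely open; a case bootstrap
  within dose groups (`ci = "bootstrap"`) is provided as the alternative.
* **Non-convergence is explicit.** Exactly flat data, optimizer failure,
  or an EC50 pinned to its search bound return `converged = FALSE` with a
  reason, never a silent estimate.

`ec_f()` uses the closed form
$EC_f = EC50\,(f/(100-f))^{1/\mathrm{hill}}$ — the *relative* definition,
between the fitted plateaus, so `ec_f(fit, 50)` is the fitted EC50
exactly. An absolute-scale variant (percent inhibition on the normalized
0–1 axis, solved by inverting the fitted curve) sits behind
`relative = FALSE`.

Therapeutic indices are `IC50/EC50`. When the toxicity fit did not
converge (no response in the tested range) or its IC50 exceeds the
highest tested concentration, the index is reported as the *lower bound*
`max_tested / EC50` with `censored = TRUE` — an unbounded ratio is never
fabricated.

## Plate quality control

`plate_metrics()` computes Z′, SW, S:B and S:N from the two control
populations. Which plate-map role carries the high signal is declared by
the caller (in an anti-proliferative readout the vehicle wells are the
high signal); it is never inferred from the data. SW defaults to the
replicate-adjusted definition

$$SW = \frac{|\mu_+-\mu_-| - 3(\sigma_+/\sqrt{n_+}+\sigma_-/\sqrt{n_-})}
            {\sigma_+/\sqrt{n_+}},$$

with the plain (non-$\sqrt n$) variant behind a flag, since the statistic
is named differently across the QC literature. Acceptance thresholds are
configurable and default to: reject a plate iff Z′ < 0.3 or SW < 1
(strict, so a plate at exactly 0.3 is retained), accept a screen iff the
retained-plate means satisfy Z′ ≥ 0.5 and SW ≥ 2. Rejected plates are
excluded from the screen-level averages — the alternative (including
them) would let one bad plate veto a screen twice.

Activity calling requires at least 3 biological repetitions and a summary
EC50 below 10 µM in both the primary and the validation assay. The
summary across repetitions is the geometric mean, because EC50s are
log-distributed.

## ADMET scoring and candidate selection

Each predicted parameter is scored on a 0 (worst) – 30 (optimal) scale by
a *rubric*: categorical levels map directly to scores, numeric values are
linearly interpolated between anchor points and clamped outside them.
Fixing per-parameter scores on the 0–30 scale makes the weighted total
span exactly 0–30 (the alternative — rescaling only at the category
level — would too, but leaves individual parameter scores uninterpretable
against the stated range). The prediction score is the weighted average
of category means with weights 2 (physicochemical), 3 (pharmacokinetics),
2 (drug-likeness), 1 (medicinal chemistry), 1 (bioavailability). A
default rubric for common in-silico ADMET outputs ships in
`inst/extdata/admet_rubric.yaml`, but it is deliberately a *config file*:
published analyses should pin their own, and none of the package's tests
depend on the defaults.

The working set combines potency and prediction score by the **rank
product** of the ascending-EC50 rank and the descending-score rank, ties
broken by the lower EC50 and then the compound id. A Pareto-front
alternative (`method = "pareto"`) is provided; rank product is the pinned
default because it yields a total order and is invariant to monotone
transforms of either axis.

Fingerprints are hashed linear paths: all simple paths of up to 7 atoms
in the hydrogen-suppressed graph, canonicalized as the lexicographic
minimum of the forward/reverse walk over element symbols and bond orders,
hashed onto 1024 bits with a fixed polynomial hash. This is deterministic
and invariant to atom numbering; it is a pinned, self-contained scheme,
and precomputed fingerprints from any external tool can be substituted
wherever a `fingerprint` object is accepted. Tanimoto similarity is
$|A\cap B|/|A\cup B|$, defined as 0 for two empty fingerprints.

## Migration

The migrative index is fractional scratch closure
$c(t) = 1 - \mathrm{area}(t)/\mathrm{area}(t_0)$, normalized to the mean
vehicle-control closure at the same timepoint. The exact definition in
the screening literature varies; fractional closure with control
normalization is pinned here, and the unnormalized closure is always
reported alongside so any other normalization can be applied downstream.
Areas slightly above the $t_0$ level are clamped to zero closure (a
scratch cannot widen biologically); an excess beyond 5% relative is
additionally flagged.

## Multiple testing

`bky_two_stage()` implements the two-stage adaptive step-up procedure:
stage 1 runs BH at $q' = q/(1+q)$, the rejection count estimates the
number of true nulls $m_0 = m - r_1$, and stage 2 reruns BH at
$q'\,m/m_0$ (rejecting everything when $m_0 = 0$, stopping when stage 1
rejects nothing). BH and BY go through `stats::p.adjust`; the test suite
keeps independent $O(m^2)$ step-up implementations as oracles for all
three. Ties are handled by the step-up on sorted values with results
mapped back to input order, so all procedures are permutation-equivariant.

The per-feature statistic feeding these procedures is the pooled-variance
unpaired t-test (`row_t_test()`), matching the default of the
multiple-t-test workflow in common screening software; Welch is a flag.
Features with zero variance in both groups receive $p = 1$ when the means
are equal; otherwise an epsilon variance floor keeps the statistic finite
and the feature is flagged `degenerate` rather than dropped.

## miRNA arrays (cT matrices)

Features with cT above the detection ceiling (default 32 cycles) in
*more than one* replicate of any treatment are excluded; a feature with
exactly one failing replicate per treatment is retained. Exclusion is
global as soon as any group fails ("any_group" scope) because a feature
unmeasurable in one arm cannot be compared across arms; the "all_groups"
variant is a flag. Undetected reactions should be encoded above the
ceiling before filtering. The pipeline operates on raw cT without
baseline re-thresholding, mirroring the practice of exporting cT values
directly.

Samples are then centered on their column means over the retained
features. Column-mean normalization is idempotent and shift-invariant,
but it has a known failure mode that users should understand: when
deregulation is strongly one-sided, the shifted features drag the column
mean with them and every null feature inherits a spurious opposite shift.
The synthetic preset therefore spikes both directions, as observed
deregulation typically runs both ways; on real data with strongly
asymmetric regulation an invariant-set normalization would be more
robust.

Fold-change direction follows the cT convention: lower cT means higher
expression, so `log2FC = mean(control cT) − mean(treated cT)`, one cycle
per log2 unit under ideal amplification efficiency. Whether technical
replicates should be averaged before testing is not standardized; the
default treats all six values per treatment (2 technical × 3 passages)
as test units, with `average_technical` collapsing them to biological
units first.

## Expression panels and RNA-seq counts

Reference-gene normalization divides each sample by the geometric mean of
its reference-gene counts, anchored to the across-sample mean of those
geometric means so the output stays on a count-like scale. Reference
genes with a zero count in any sample are excluded from the factor (with
a warning); the scheme is the standard published geometric-mean approach,
not a claim of identity with any proprietary implementation.

DEG calling tests `log2(normalized + 0.5)` with per-donor centering:
every donor's samples are centered on that donor's mean before the
pooled t-test, a transparent blocked alternative to covariate modelling
of the donor/lot effect (the unblocked test is a flag). A gene is a DEG
only when both gates hold — adjusted q below the level *and*
|log2FC| above the threshold — and the two criteria are recorded
separately so either gate can be audited. The panel stage uses the
two-stage adaptive adjustment at 5% with |log2FC| ≥ 1; the RNA-seq stage
uses BY at 5% with |log2FC| ≥ 1.3. The two stages deliberately pin
*different* adjustments because that is how the respective workflows are
specified, inconsistency included.

Shared-DEG logic classifies genes as consistently deregulated (same
direction in every treatment table), near-consistent (same direction in
at least `min_conditions` but not all), or conflicting (up in one table,
down in another — excluded from both sets and logged). Pathway signature
scores are mean member-gene expression per condition, centered on the
signature's across-condition mean, so normalized scores sum to zero
across conditions by construction.

CPM filtering retains genes with CPM strictly above 0.25 in at least 3
samples. TMM factors follow the original trimmed-mean-of-M-values
description: reference sample = library whose upper-quartile CPM is
closest to the mean upper quartile; per-gene log ratios doubly trimmed
(30% on M, 5% on A); inverse asymptotic-variance weights; factors
rescaled to geometric mean 1. The test suite cross-checks the factors
against an independent implementation on composition-biased mixtures.

## Synthetic data: what it emulates, and what it does not

The generators own an explicit integer seed and never touch the global
random state.

* **Screens** (`generate_screen()`): 96-well plates with vehicle controls
  in column 1, full-inhibition controls in column 12 (a conventional
  column-edge layout — real plate maps are rarely published, so this is
  an assumption), compound wells on the true 4PL at each dose, and
  mean-one multiplicative log-normal noise at a configurable CV (default
  5%; plate-reader noise scales with signal). The default design is a
  7-point 10-fold serial dilution from 10 µM with 6 technical and 3
  biological replicates, spanning the 5–500 nM potency window with both
  plateaus.
* **cT arrays** (`generate_ct_matrix()`): expressed features draw
  baselines uniformly in 18–30 cycles, unexpressed features sit at
  36 ± 1.5 cycles (above the ceiling with high probability), per-well
  Gaussian noise of 0.5 cycles, and spikes shift the treated mean by
  −log2FC cycles. The array-scale preset uses 754 features, 165
  expressed, 20 spiked at ±3 cycles.
* **Count panels** (`generate_panel_counts()`): negative-binomial counts
  with log-normal gene baselines (median ≈ 500), a shared per-donor
  multiplicative lot effect (SD 0.3 on the log scale), spiked
  treatment effects of ±2 log2 units, and dispersion 0.02 — a residual
  within-donor biological CV of ~14%, realistic for a targeted panel
  once lot effects are modelled. Reference genes carry no treatment
  effect by construction.
* **RNA-seq-like matrices** (`generate_rnaseq_counts()`): a handful of
  explicitly dominant transcripts (default shares calibrated so the top
  transcript carries ~3.3% of reads and the top six together exceed
  10%) over a log-normal tail, at NB dispersion 0.05.

What passing tests on these data establish: the *procedures* are
implemented correctly — filters decide their boundary cases exactly,
estimators recover generating parameters, FDR procedures control their
error rates at the simulated scales, and set logic matches hand-worked
cases. What they do not establish: robustness to features of real data
the generators deliberately omit — spatial plate artefacts and edge
effects, probe-specific amplification efficiencies, count outliers and
zero inflation, correlated genes, or donor-by-treatment interactions.
The problem sizes used by the validation suite (200 simulated screens per
EC50 scenario; 100 simulation seeds for the miRNA and panel recoveries;
10,000 global-null replicates at m = 754) were chosen to make
Monte-Carlo error small relative to the margins being checked.

## Known limitations

* The 4PL is monophasic; biphasic responses or five-parameter asymmetry
  are out of scope and will surface as poor fits, not warnings.
* Column-mean normalization biases null features under strongly
  one-sided deregulation (see above).
* The blocked DEG test centers out donor effects rather than modelling
  them, which discards one degree of freedom per donor and is
  conservative for very small designs.
* The shipped ADMET rubric is a convenience default, not a validated
  scoring standard.
* Fingerprints are linear paths only (no branched subtrees or ring
  closure bits); they are adequate for similarity ranking of closely
  related scaffolds, less so for diverse libraries.
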