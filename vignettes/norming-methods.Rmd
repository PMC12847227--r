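---
title: "Norming methods: T-scores, percentile ranks, crosswalks, and change thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Norming methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scorewalk)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## The problem

Raw summed scores from ordinal questionnaires are hard to interpret across
instruments and populations. Two common metrics fix that: the **T-score**
(mean 50, SD 10 in a reference group) and the **percentile rank** (PR, the
percentage of the reference group scoring below, plus half of those scoring
equal). The catch is that quality-of-life sums in general-population samples
are left-skewed — most people are satisfied — so the *linear* T
transformation `T = 10(RS - M)/SD + 50` inherits the skew and
under-states low scores. The package implements and compares three routes:
linear, rank-based inverse normal (Rankit), and IRT-based.

## Graded response model and EAP scoring

For item $j$ with discrimination $a_j > 0$ and ordered thresholds
$b_{j1} < \dots < b_{j,K-1}$, the boundary probability of responding in
category $k$ or above is logistic,
$P^*_{jk}(\theta) = \mathrm{logistic}(a_j(\theta - b_{j,k-1}))$, and category
probabilities are successive differences of boundary curves. We use the
logistic metric without the 1.702 constant throughout; the conversion of
discriminations to standardized loadings (`grm_loadings()`, used for
McDonald's omega) documents its own 1.702 rescaling, so the two are
consistent.

**Estimation** is marginal maximum likelihood via Bock–Aitkin EM on a fixed
grid of equally spaced nodes carrying normalized normal-density weights.
Item parameters are constrained equal across groups; the reference group's
latent distribution is fixed at N(0, 1) for identification and the other
groups' means and SDs are estimated (in the M-step, by directly maximizing
the expected log prior-weight, which keeps the marginal log-likelihood
monotone). The item M-step maximizes the expected complete-data
log-likelihood by BFGS with an analytic gradient on an order-preserving
reparameterization $(\log a,\ b_1,\ \log \Delta b)$, so threshold ordering
can never be violated. Because every M-step only improves its objective,
the marginal log-likelihood is non-decreasing across cycles (asserted in
the tests to 1e-8).

Tunables and defaults:

* **Quadrature**: 81 nodes on $[-8, 8]$ (spacing 0.2). A narrower $[-6, 6]$
  grid is the textbook default, but with a clinical prior near
  N(-1.15, 1.5) the EAP posterior of a floor-level respondent is centred
  near $\theta = -4$ and its tail is visibly truncated at $-6$: the
  truncation error (~3e-4) exceeds the package's own accuracy contract that
  EAP match a fine-grid integration oracle to 1e-6. Widening the support —
  same spacing — restores it. For equally spaced nodes under a smooth,
  decaying integrand this rule is spectrally accurate, so 0.2 spacing is
  far below every tolerance used.
* **Convergence**: largest absolute parameter change below 1e-4, or 500 EM
  cycles; hitting the cap flags `converged = FALSE` but still returns
  parameters (an honest flag rather than an error, since partial fits are
  diagnostically useful).
* **Starting values**: discriminations 1.0; thresholds from the
  inverse-normal of observed cumulative category proportions.

**Scoring** is expected a posteriori: posterior mean and SD of $\theta$ on
the same grid, under the respondent's own group prior, then
$T_{IRT} = 10\theta + 50$. EAP shrinks toward the prior mean, so the
reference group's $T_{IRT}$ SD lands *below* 10 — around 9.2 in the
synthetic world, and 8.86 in the normative study this package's surface is
modeled on. Tests therefore assert mean $\approx 50$ and SD $\le 10.1$, not
SD $\approx 10$.

## Rankit normalization

Ranks (ties averaged, so identical raw scores always share a T-score) map
through the plotting position $(r - k)/(n - 2k + 1)$ into `qnorm`. The
default offset is $k = 0.5$ — the true Rankit position $(r - 0.5)/n$ — with
Blom ($k = 0.375$) and van der Waerden ($k = 0$) selectable, because the
literature's naming and the common software defaults disagree and the choice
is consequential only in the extreme tails. A raw score unobserved in the
reference sample has no rank; `rankit_t()` returns `NA` for it (the
crosswalk formulas exist precisely to interpolate such scores).

## Crosswalks and conversion formulas

The crosswalk table carries, for every integer raw score, the regressed
$T_{IRT}$ (1 decimal) and integer PR columns for both reference groups,
clipped to $[0, 100]$. Choices worth stating:

* **Regression data**: per-respondent $(RS, T_{IRT})$ pairs, not unique-RS
  means — heavily populated scores should weigh more (a `collapse` flag
  switches).
* **Forms**: degree-5 polynomial for RS→T and for the clinical RS→PR; a
  Weibull-type sigmoid
  $y = L + (U-L)(1 - e^{-e^{s(\ln(RS + 10^{-4}) - \ln m)}})$ for the
  reference-group RS→PR, whose ceiling shape a polynomial tracks poorly.
* **PR source**: when reference samples are available the table's PR columns
  are empirical mid-rank percentile ranks (the fitted curves deviate by
  ±1 integer at some scores); formula-evaluated columns are available by
  flag.
* **Rounding**: half away from zero, applied only at export.
* **Monotonicity**: crosswalks must be monotone to be usable; tiny formula
  wiggles are corrected by a cumulative-maximum isotonic pass and reported.

**Reproduction limits.** Published conversion coefficients are typically
printed to 4 significant digits. Re-evaluating such a quintic reproduces a
published T column only to about ±0.2 T-points near the top of the raw-score
range, where the $RS^5$ term is large: agreement to ±0.15 everywhere is not
attainable from printed coefficients even when mid-range cells reproduce
exactly after rounding. The acceptance suite keeps the stricter band as a
documented red rather than widening it.

**Round-trip accuracy.** Respondents sharing a raw score have different
response patterns, hence different EAP scores. In the synthetic world the SD
of $T_{IRT}$ given RS is about 1.2 T-points, so roughly 90% — not 95% — of
reference-group respondents fall within 2 T-points of the crosswalk value;
clinical respondents scored through a population-fitted curve deviate more,
because their EAP uses the clinical prior. The pipeline test asserts the 90%
figure with this reasoning.

## Reliable change and clinical significance

Jacobson–Truax: $S_E = SD\sqrt{1 - r_{xx}}$, $RCI = z\sqrt{2S_E^2}$ with
$z \in \{1.282, 1.645, 1.960\}$ for 80/90/95%, and the cutoff
$CS = (sd_2 M_1 + sd_1 M_2)/(sd_1 + sd_2)$ — each mean weighted by the
*other* group's SD, i.e. the crossing point of the two normal densities.
The five outcome categories needed formalization beyond their names:

* *Recovered* requires reliable improvement **and** a pre-score on the
  dysfunctional side **and** a post-score on the functional side; reliable
  improvement from an already-functional state is *Reliably Improved*.
* *Relapsed* is the mirror image: reliable deterioration with a functional
  pre-score and a dysfunctional post-score.
* Boundary equality with the cutoff counts as functional for
  higher-is-better instruments (configurable by direction).
* Severity bands assign a score exactly on a cutpoint to the worse-severity
  side. The default band cutpoints {40, 45.7, 55, 60} are explicit package
  configuration in the PROMIS display style — 45.7 being the
  clinical-significance cutoff on the T metric — not published values, and
  are fully overridable.

Published threshold tables are not always internally consistent: printed
$S_E$ and RCI values often reflect an unrounded upstream reliability. The
package always computes from the formula and the supplied inputs rather
than hard-coding printed numbers; the tests check agreement at the printed
rounding only where it holds (e.g. RCI95 = 8.5 T-points from SD 8.86,
$r_{xx} = 0.88$).

## Agreement between scoring methods

`icc_absolute()` is fixed to the single-measurement, absolute-agreement,
two-way form ICC(A,1) — the definition that penalizes systematic offsets —
with the McGraw–Wong closed-form confidence interval; other ICC variants are
deliberately not offered, to avoid silent definition mismatches.
Bland–Altman limits are $\bar d \pm 1.96\,SD(d)$; the percentage error is
the LoA width over the reference method's grand mean (a published note
writing it as a *sum* of the bounds contradicts that source's own printed
values, which match width-over-mean; width is implemented). Exceedance
counts use inclusive bounds ($-5 \le D \le 5$ is "within") with the default
limit of 5 T-points = 0.5 SD.

## The synthetic world

`default_mansa_params()` ships 12 items with 7 categories: discriminations
1.0–1.5 (logistic metric) and per-item thresholds obtained by inverting
left-skewed (reflected-gamma) marginal targets whose means, SDs, and skews
follow the published item table of the normative sample. The clinical group
is N(-1.15, 1.5) on the latent scale. Monte Carlo at n = 50,000 puts the
population summed score at M ≈ 61.7, SD ≈ 8.9, skew ≈ -0.57 and the
clinical group at M ≈ 50.8, SD ≈ 14.6 — the published targets are
(61.72, 8.76, -0.81) and (51.14, 14.20).

Two deliberate mismatches, fixed once and not revisited:

* The published item SDs and total SD *jointly imply* Cronbach's alpha of
  about 0.84 (`k/(k-1) * (1 - 17.8/76.7)`), so a world calibrated to the
  item table cannot also show the published pooled-sample alpha of 0.88;
  ours measures ~0.83.
* The summed-score skew (-0.57) is milder than the published -0.81: the
  published per-item skews are not exactly reproducible through a
  single-factor GRM with normal latent trait, which smooths extremes.

What the generator does **not** emulate: the extreme kurtosis of the
personal-safety item, longitudinal pre/post correlation structure, and
demographic composition (the optional `age`/`gender` columns are uniform
dressing for stratification demos). A green test on this world therefore
establishes correctness of the *machinery* — estimation, transformation,
table construction, thresholds — not empirical equivalence with any real
sample.

Determinism: one master seed; per-group substreams derived as
`(seed mod 1000003) * 1009 + group_index`, kept inside the 32-bit range.
Identical configurations give bit-identical output.

## Degenerate inputs and numerical edges

* Items observed in fewer than two categories abort the GRM fit naming the
  item; all-missing response patterns abort EAP scoring.
* Constant samples flag skewness/kurtosis as undefined rather than
  propagating NaN; zero total-score variance makes alpha an error.
* Polychoric pairs with a degenerate contingency table fall back to the
  Pearson correlation of the integer scores with a warning. Bivariate
  normal rectangle probabilities use 64-node Gauss–Legendre quadrature of
  $\varphi(x)\Phi((b - \rho x)/\sqrt{1-\rho^2})$, accurate far beyond the
  optimizer's 1e-6 tolerance.
* Shapiro–Wilk W is delegated to `stats::shapiro.test()`; above its n = 5000
  validity cap a fixed-seed subsample is used and the caller's RNG state is
  restored.
* The Weibull sigmoid fit tries `nls(algorithm = "port")` with documented
  starts and falls back to Nelder–Mead least squares; non-convergence is
  flagged with best-so-far parameters, never silently dropped.
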