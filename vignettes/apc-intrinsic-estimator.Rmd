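---
title: "Age-period-cohort decomposition of mortality surfaces with the Intrinsic Estimator"
author: "apcmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-period-cohort decomposition of mortality surfaces with the Intrinsic Estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcmort)
```

## The problem

A population's mortality risk in a given calendar year mixes three
time-related components. The **age effect** $\alpha_i$ is the risk attached
to chronological age — for heart disease, a steeply rising, curvilinear
function of age. The **period effect** $\beta_j$ is attached to the calendar
year of death and moves all ages at once; it is the "true" temporal trend of
risk. The **cohort effect** $\gamma_k$ is attached to the birth year
$k = j - i$ and carries historical exposures (most prominently, cigarette
smoking) forward through life.

Crude and even directly age-standardized rates confound these components.
When a strong, steadily declining cohort effect is present — as it is for
heart disease in the United States, where cohorts born later smoked less —
the crude rate can *decline* for two decades while the underlying period
risk *rises*. This is the apparent paradox of falling heart-disease
mortality alongside rising obesity: the decline lives in the cohort
dimension, not the period dimension. This package decomposes single-year
mortality surfaces into the three effects, rebuilds the period trend as an
*age-cohort adjusted* rate series, and correlates the pieces with prevalence
series (obesity against the adjusted rates, smoking history against the
cohort effects).

## Model

For a Lexis surface of deaths $d_{ij}$ and person-years $n_{ij}$ by single
year of age $i$ and calendar year $j$, the model is a Poisson regression on
the death proportion $r_{ijk}$:

$$\log(r_{ijk}) = u + \alpha_i + \beta_j + \gamma_k, \qquad
d_{ij} \sim \mathrm{Poisson}(n_{ij}\, r_{ijk}), \qquad k = j - i,$$

with each effect block deviation-coded (sum-to-zero, last category omitted).
With $A$ ages and $P$ periods there are $C = A + P - 1$ cohorts; on the
25–84 × 1999–2018 grid that is 79 cohorts born 1915–1993, and the design has
$1 + 59 + 19 + 78 = 157$ columns. The model is fitted on the proportion
scale — the offset is $\log n_{ij}$ — and the reporting scale (per 100,000
by default) is applied only when rates are derived.

### The identification problem and the Intrinsic Estimator

Because $k = j - i$ exactly, the design matrix $X$ has a one-dimensional
null space: adding $s\,(i - \bar\imath)$ to the age effects,
$-s\,(j - \bar\jmath)$ to the period effects and $s\,(k - \bar k)$ to the
cohort effects leaves every fitted cell unchanged. All APC solutions form a
line $\hat\theta + t\,v$; individual effects are identified only up to this
shared linear trend, while *estimable functions* — fitted cell rates,
second differences of each block — are unique.

The **Intrinsic Estimator** (IE) is the solution orthogonal to $v$. The
package computes it by the principal-components route: eigendecompose
$X^\top X$, treat the single eigenvalue below $10^{-8}$ times the largest as
null (exactly one must be), run iteratively reweighted least squares in the
reduced eigenbasis, and map the coefficients back. Orthogonality to $v$
then holds by construction rather than by post-hoc projection.

`fitConstrained()` provides the classical alternative — two chosen cohort
effects set equal, fitted with `stats::glm.fit` — as an independent oracle:
it must agree with the IE on every estimable function, and the test suite
asserts exactly that (fitted log-rates and second differences to $10^{-6}$,
deviance to $10^{-8}$).

```{r fit}
design <- buildDesign(25:84, 1999:2018)
design
cfg <- SyntheticConfig()           # the package's default study conditions
truth <- generateTrueEffects(cfg)
surface <- simulateSurface(truth, cfg)
fit <- fitIntrinsicEstimator(surface, design)
fit
```

### Adjusted rates

Three series summarise a surface per calendar year:

* **crude**: $\sum_i d_{ij} / \sum_i n_{ij}$, scaled;
* **age-adjusted**: direct standardization
  $\sum_i w_i\, d_{ij}/n_{ij}$ with fixed standard weights $w$;
* **age-cohort adjusted**: the period trajectory with age and cohort frozen
  at their medians, $s_j = u + \beta_j + \mathrm{median}(\alpha) +
  \mathrm{median}(\gamma)$, mapped to a rate.

Two link variants are provided for the last mapping. The `"logit"` variant
$\mathrm{scale}\cdot e^{s_j}/(1+e^{s_j})$ is the default; the `"log"`
variant $\mathrm{scale}\cdot e^{s_j}$ is the one consistent with the
log-linear model. At death proportions below $5\times10^{-3}$ (500 per
100,000) they differ by less than 0.5% relative — with
$s = -6$ and scale $10^5$ they give 247.875 and 247.262 — so the choice is
cosmetic at these magnitudes, but it is surfaced as an explicit argument
rather than silently resolved.

```{r rates}
crude <- crudeRateSeries(surface)
adjusted <- ageCohortAdjustedSeries(fit)
round(rbind(crude = rates(crude)[c(1, 20)],
            adjusted = rates(adjusted)[c(1, 20)]), 1)
```

The crude series falls while the adjusted series rises: the paradox,
regenerated from known structure.

### Correlation stage

Sparse prevalence series are interpolated piecewise-linearly to annual
resolution (`interpolateAnnual`; knots are reproduced exactly, and
extrapolation outside the knot range is refused — the spec of the 2018
obesity anchor below). Pearson correlations with their two-sided t-tests
pair (i) a rate series with obesity prevalence, aligned by calendar year,
and (ii) cohort effects with historical smoking prevalence, pairing the
smoking rate of calendar year $Y$ with the cohort *born* in $Y$ over a
window (1965–1990 by default, 26 pairs). A `lag` argument shifts the cohort
side of that pairing; the default of zero matches the windowed design
described above, and the package deliberately does not pick a lag for the
user.

## The synthetic generator

`SyntheticConfig()` defines the study conditions under which the pipeline is
exercised and tested:

| parameter | default | meaning |
|---|---|---|
| grid | 25–84 × 1999–2018 | single-year Lexis rectangle |
| `baselineLogRate` | $\log(1.5\times10^{-3})$ | grand-mean death proportion |
| `ageCurvature`, `ageVertex` | $8\times10^{-4}$, 80 | $\alpha = -c(\mathrm{age}-80)^2$: curvilinear, rising to 80 |
| `periodBreak`, slopes | 2007; 0, 0.025/yr | flat period risk to 2007, rising after |
| `cohortSlope` | $-0.02$/yr | steadily declining cohort risk, 1.56 log units over 79 cohorts |
| `populationPerCell` | $10^6$ | constant person-years per cell (an age profile is allowed) |
| `seed` | 20220817 | one RNG stream per simulate call |
| `orthogonalize` | TRUE | project the truth off the null vector |

These shapes mirror the qualitative structure the analysis targets — a
curvilinear age effect, a period acceleration after 2007, a consistent
cohort decline — at amplitudes that keep all cell proportions in
$(10^{-4}, 10^{-2})$. Death counts are Poisson; prevalence series are
affine functions of a chosen effect block plus Gaussian noise, clamped to
$[0, 100]$ percent.

Orthogonalization matters: the IE estimates the projection of the truth
onto the orthogonal complement of the null vector, so only an
orthogonalized truth is recoverable exactly. The `orthogonalize = FALSE`
option exists to demonstrate the identification problem, not for recovery
testing.

**Recovery benchmark conditions.** Consistency is checked at $10^7$
person-years per cell with gentler amplitudes (`baselineLogRate`
$\log(3\times10^{-3})$, `ageCurvature` $1.5\times10^{-4}$, `cohortSlope`
$-0.004$), which hold every cell's death proportion in the
$\sim 10^{-3}$ decade (1.8–4.5 per 1,000). The reason is structural: the
extreme cohorts of a Lexis rectangle are observed in a single corner cell,
so their estimation error is governed by that one cell's death count
($\mathrm{SE} \approx 1/\sqrt{d}$). Keeping corner cells at $\ge 2\times10^4$
expected deaths makes per-effect errors uniformly small (observed maximum
absolute error around 0.005–0.014, per-block truth–estimate correlations
above 0.999) instead of letting the benchmark be dominated by a corner
cell's Poisson noise.

### What the synthetic data do not emulate

Real mortality surfaces have age-varying population sizes spanning orders
of magnitude, overdispersion relative to Poisson, registration artifacts,
and — in small race strata — suppressed cells. The generator models none of
these (population is constant per cell by default; suppressed cells are a
hard *input* error by design, since the estimator needs a complete
rectangle). Passing tests therefore demonstrate correctness of the
estimator and pipeline under the stated model, not robustness to
misspecification of real vital-statistics data.

## Numerical choices

* **Coding.** Deviation coding with the last category omitted; full-length
  effects recovered by the negative-sum rule, hence exactly centered. This
  is the coding under which the APC null space is one-dimensional and the
  IE is conventionally stated.
* **Null detection.** Eigenvalues of $X^\top X$ below $10^{-8}\times$ the
  largest are null; exactly one must be, otherwise the design is rejected
  (fewer than three categories per block is refused up front for the same
  reason). `nullVector()` on a raw matrix uses the SVD with the same
  relative tolerance and fixes the sign by the first nonzero entry.
* **IRLS.** Starting values $\log((d + 0.5)/n)$, robust to zero-death
  cells (zero deaths are valid data; zero or negative population is an
  error); convergence when the relative deviance change falls below `tol`
  (default $10^{-8}$, `maxIter` 100). Non-convergence returns the flagged
  fit with a warning rather than an error. Agreement checks between the IE
  and the constrained oracle tighten `tol` to $10^{-12}$ so that the
  comparison measures parameterization invariance, not stopping error.
* **Ties and medians.** Even-length effect vectors use the mean of the two
  central order statistics (`stats::median`).
* **Determinism.** Fitting is deterministic; all simulation takes an
  explicit seed and uses a single RNG stream per call.

## Design choices that were genuinely open

* **Link variant default.** The inverse-logistic form is the default for
  the age-cohort adjusted series, with the log form one argument away and
  the sub-0.5% gap documented, because the adjusted-rate formula is
  conventionally printed that way even though the fitted model is
  log-linear. Surfacing both seemed more honest than picking the
  "consistent" one silently.
* **Adjusted series span.** The series is computed for *every* fitted
  period (1999–2018 on the default grid), not a truncated subset.
* **Obesity anchoring.** Two-year survey cycles are anchored at the first
  year of the cycle when building interpolation knots; the year after the
  last knot is outside the knot range and is refused rather than
  extrapolated or carried forward.
* **Suppressed cells.** Refused with an error listing the cells — no
  imputation. An incomplete rectangle silently patched would bias the
  cohort diagonals the analysis rests on.
* **Standard population.** Always caller-supplied. The bundled
  `synthetic_standard_population.csv` is a smooth, explicitly
  non-authoritative age profile for examples and tests, not an official
  standard.
* **No uncertainty for effects.** The package reports point estimates
  only; standard errors and confidence bands for IE effects are out of
  scope, as are AP/AC submodels and multi-year age or period bins.

## Problem sizes used in the checks

The test suite and the acceptance script work on the full 60 × 20 study
grid (1,200 cells, 157 parameters — a fit takes well under a second) with
$10^6$ person-years per cell for qualitative checks and $10^7$ for the
recovery benchmark; unit tests use a 10 × 8 grid. The end-to-end paradox
check asserts signs and correlation bounds, not point values, because its
inputs are stochastic by design.

## Limitations

Beyond the synthetic-data caveats above: the IE is one resolution of an
unidentified model, not new information — its effect curves are
interpretable only through estimable functions and the orthogonality
convention; correlations between adjusted rates and prevalence series are
ecological associations across 20 annual observations, with no causal
content; and the cohort-smoking pairing matches birth-year effects to
same-year adult smoking prevalence, a deliberate simplification (the `lag`
argument exposes it).
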