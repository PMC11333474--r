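---
title: "Models and methods behind comboscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind comboscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboscreen)
```

## What the package computes

`comboscreen` implements the analysis chain of a drug-combination
viability screen built around a clinically constrained anchor compound
(the defaults describe 13-cis-retinoic acid, RA): plate normalization,
asymmetric logistic dose-response fitting with absolute IC50, drug
sensitivity scoring (DSS) with differential combination scores (dcDSS)
and hit calling, Loewe-additivity synergy analysis for 5×5 checkerboards
and fixed-ratio ray designs, and RECIST response classification adapted
to zebrafish embryo xenografts. A synthetic-data module emulates each
assay with known ground truth so every stage is testable end to end.

## Normalization and the dose-response model

Raw metabolic-activity signals are rescaled per plate against the
medians of the negative (vehicle, 0% inhibition) and positive (kill,
100%) control wells:

$$\text{inhibition} = 100\,\frac{\tilde s_{neg} - s}{\tilde s_{neg} - \tilde s_{pos}}.$$

The median (not the mean) is used because edge-well artifacts routinely
contaminate a few control wells; the source screens do not document the
statistic, so robustness decided it. Normalized values are *not* clipped
— noise legitimately produces values outside $[0, 100]$, and clipping
before fitting would bias the plateaus.

The working curve is a five-parameter logistic (5PL) on
$x = \log_{10}$ concentration:

$$y(x) = E_{min} + \frac{E_{max}-E_{min}}
  {\bigl(1 + k\,10^{\,h(\log_{10}\mathrm{EC}_{50}-x)}\bigr)^{a}},
  \qquad k = 2^{1/a}-1 .$$

The factor $k$ is the one genuinely open design choice we made in this
module and it matters: in the naive 5PL parameterization (no $k$), the
location parameter trades off almost freely against the asymmetry $a$,
and on realistic screen data (10 concentrations × 3 replicates, 5%
noise) its median recovery error was near 50% — the parameter is not
identifiable even though the fitted *curve* is excellent. Anchoring the
location at the half-maximal effect (the convention asymmetric-model
software uses) makes $\mathrm{EC}_{50}$ a stable, comparable quantity;
recovery error drops to ~6% in the same experiment. At $a = 1$ the model
is exactly the symmetric 4PL and $k = 1$.

Fitting minimizes the residual sum of squares over all individual
replicate points (replicate variance should weigh on the fit; averaging
first would hide it) by bounded quasi-Newton (`nlminb`) with analytic
gradients, from five deterministic starts spread over the tested range —
no randomness, so fits are bit-reproducible. Bounds:
$E_{min}\in[-30,30]$ (slight stimulation happens), $E_{max}\in[0,130]$
(over-killing noise), $h\in(0,10]$ (monotone by construction),
$a\in[0.2,5]$, $\log_{10}\mathrm{EC}_{50}$ within the tested range ±1
decade. All-flat responses return a non-converged flat curve rather than
an error, so screen-scale loops never die on an inactive drug.

**Absolute IC50** is the concentration where the fitted curve crosses
50% inhibition on the absolute scale — not half of the curve's own span.
If the plateau stays below 50% or the crossing lies beyond the highest
tested dose, the value is censored at that dose. **Responder
classification** asks whether fitted inhibition at the entity's
clinically achievable peak concentration reaches 50%: 7.2 µM for
neuroblastoma (serum) and 3.1 µM for CNS tumours (white-matter levels
are about half). We read "at least 50% … below $C_{max}$" as inclusive
at $C_{max}$ — the phrasing is inclusive on the inhibition side, and the
measure-zero boundary case cannot be decided from data.

## DSS, dcDSS and hits

The drug sensitivity score is the normalized area of the fitted curve
(clipped to $[0,100]$) above an activity threshold $t$ over the tested
range $[x_{min}, x_{max}]$:

$$\mathrm{DSS} = \frac{100\int_{x_{min}}^{x_{max}}
  \max\!\bigl(\min(y(x),100)-t,\,0\bigr)\,dx}
  {(100-t)(x_{max}-x_{min})}.$$

This is the canonical thresholded-area DSS with $t = 10\%$ by default
(exposed in the config); computed on the asymmetric fit it is the
DSS$_{asym}$ variant. Integration is adaptive quadrature with the
interval split at the curve's threshold crossings so the kink costs no
accuracy; scores are only comparable between arms integrated over the
same range, and `dcdss()` refuses mismatched ranges. dcDSS is the
combination-arm score minus the monotherapy score; a drug is a
combination hit when the per-drug **median** across models exceeds 2
*and* the median combination DSS exceeds 10 (both strict, matching the
published rule). Model response profiles are clustered on Euclidean
distance with Ward (`ward.D2`) linkage and a two-group cut — neither the
metric nor the linkage is documented for the original heatmap, so we
chose the standard pair and expose `k`.

## Loewe synergy

For margin curves $A$, $B$ with inverses $D_A(y)$, $D_B(y)$, the
Loewe-expected effect of a dose pair $(d_1, d_2)$ solves

$$\frac{d_1}{D_A(y)} + \frac{d_2}{D_B(y)} = 1,$$

found by bisection on $y$ (tolerance $10^{-6}$). Effects unreachable by
one drug drop that drug's term ($D_i(y)=\infty$), capping the expected
surface at the stronger drug's plateau — the standard Loewe extension
for unequal efficacy. The expected surface is computed from *fitted*
margins, never raw margin cells: the reference model needs an invertible
monotone function, and raw cells are noisy. The overall score is the
mean observed-minus-expected excess over the cells where both doses are
positive (16 of 25 in the canonical design); monotherapy cells have zero
excess by construction and would only dilute the score. Scores above +10
are read as synergistic, below −10 antagonistic, additive between. The
published overall scores cannot be reconciled cell-for-cell because the
raw matrices behind them are not deposited and the web tool's averaging
set is undocumented; sham-combination and additive-reconstruction
properties are what a green test establishes here.

## Ray designs and the interaction index

Rays fix the dose *ratio*: with mixture fraction $f$ and anchors
$\mathrm{IC50}_A$, $\mathrm{IC50}_B$, level $m$ doses
$(m f\,\mathrm{IC50}_A,\; m(1-f)\,\mathrm{IC50}_B)$; defaults are seven
equally spaced fractions $1/8 \dots 7/8$ and seven two-fold levels
centred on $m=1$ — the published design states only "seven rays anchored
on the IC50s", so equal spacing is our choice, exposed as an argument.
Along each ray a 5PL is fitted over *total* dose; at effect level $y$
(default 50%, the best-determined part of the curve) the interaction
index is

$$\tau = \frac{d_1}{D_A(y)} + \frac{d_2}{D_B(y)},$$

with $(d_1,d_2)$ the ray doses reaching $y$. $\tau=1$ under exact
additivity, $<1$ synergy, $>1$ antagonism. Confidence intervals come
from a case-resampling bootstrap within each arm (percentile 2.5/97.5,
all three curves refitted per replicate, warm-started from the full-data
fit); we preferred it over the classical delta-method interval because
it is robust to fit nonlinearity at the small per-arm $n$ typical of
these designs, and the original variance formula is not restated in our
sources. A bootstrap replicate counts as failed only when the optimizer
errors or the effect level becomes unreachable; informational `nlminb`
status codes on flat RSS valleys are not failures (treating them as such
falsely discards ~half of healthy refits). More than 20% failures abort
the interval. The call is synergy/antagonism only when the whole
interval lies on one side of 1.

## RECIST adapted to zebrafish xenografts

Relative tumour size change from baseline classifies each animal:
PR at $\le -30\%$, PD at $\ge +20\%$ (both inclusive, exactly as the
adapted criteria state), SD between. Complete response is not a separate
category — the adapted criteria name only PR/SD/PD, so total regression
maps to PR. Rates are reported rounded half-up to one decimal (the
precision of the published cohort percentages: 53.3%, 54.5%); the
disease-control rate PR+SD is always computed from integer counts, never
from rounded rates. No between-group significance test is run by
default: the test behind the published "decreased significantly" is
unspecified.

## The synthetic world

The generators state one fixed world; none of their defaults were tuned
against test outcomes:

* **Plates** — 10 log-spaced concentrations × 3 replicates,
  multiplicative log-normal signal noise at CV 5% (the standard model
  for luminescence viability readouts; no noise model is published),
  vehicle level 10000, ≥4 control wells per role.
* **Checkerboards** — 5×5 grids (zero dose first) built from true
  margins as exactly Loewe-additive, Bliss-independent, or
  potency-shifted (EC50 divided by $1+\mathrm{strength}$ inside
  combinations); noise is applied on the viability scale after surface
  construction.
* **Rays** — additive surfaces via the same Loewe solver, or a potency
  multiplier $k$ on the combined doses, which makes the true
  $\tau = 1/k$ at every reachable effect level.
* **Screens** — 16 models × 76 drugs, two model groups of 8 separated by
  a 30-point shift in combination DSS (between-model s.d. 5), and a
  designated hit subset carrying a true dcDSS of 4 with s.d. 1 on the
  arm difference.
* **Xenografts** — cohorts drawn from explicit class counts (uniform
  within PR $[-80,-30]$, SD $(-30,20)$, PD $[20,200]$ — only membership
  matters to the classifier) or from a log-normal growth ratio.

What green tests do establish: the estimators recover the generating
truth of this world at the stated noise (EC50 median error <15%,
additive $\tau$ within 2%, exact rate arithmetic, full cluster
recovery). What they do not establish: behaviour under plate spatial
artifacts, dispensing errors, non-log-normal noise, or the actual
76-drug library, whose raw data are not public.

## Numerical choices

Bisection tolerances are $10^{-6}$ on the effect scale; DSS quadrature
runs at relative tolerance $10^{-8}$ on smooth pieces; curve inversion
is closed-form. Multi-start initialization is deterministic; all
simulation randomness flows through explicit seeds and generators
restore the caller's RNG state. Ties in clustering follow input order.
Degenerate inputs (flat curves, unreachable effect levels, zero doses)
return flagged results rather than errors wherever a screen-scale loop
must survive them, and hard errors where silent continuation would
corrupt comparisons (inverted controls, mismatched DSS ranges,
non-invertible margins).

## Known limitations

Absolute IC50s and DSS values depend on the fitted plateau; with fewer
than ~6 informative concentrations the asymmetry is weakly determined
and the 4PL option is the safer fit. The Loewe solver assumes monotone
margins — biphasic responses are out of scope. Bootstrap intervals are
percentile-based and can undercover slightly below $B = 500$ replicates.
The checkerboard score averages a fixed cell set; it is not comparable
to tools that average all 25 cells or smooth the surface first.
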