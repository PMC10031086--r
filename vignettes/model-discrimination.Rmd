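---
title: "Equilibrium models of Ca2+/CaM/MLCK binding and how camnet discriminates them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equilibrium models of Ca2+/CaM/MLCK binding and how camnet discriminates them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camnet)
```

## The binding network

Calmodulin (CaM) has two lobes, each carrying a cooperative pair of
EF-hand Ca2+ sites. Following the standard treatment, each pair is
lumped into a single site, giving four Ca2+ occupancy states of CaM:
apo, N-loaded, C-loaded and fully loaded. Adding a bound/unbound axis
for myosin light chain kinase (MLCK) yields an eight-state cube.
Three mechanisms from the literature differ only in which MLCK-bound
vertices exist:

* **Model 1 (random)** keeps all eight states: MLCK can bind CaM in
  any Ca2+ state, including apo-CaM (association constant $K_9$).
* **Model 2 (partially ordered)** removes MLCK-bound states whose
  C-lobe is empty.
* **Model 3 (fully ordered)** keeps MLCK binding only for fully loaded
  CaM.

An EF-hand knockout mutant removes every state in which the mutated
lobe is Ca2+-occupied. `enumerate_states()` makes these truncations
explicit (8 states for Model 1 wild type, 6 for Model 2, 2 for Model 3
with a dead N-lobe).

Because Models 2 and 3 are *truncations*, two of their qualitative
predictions are parameter-free: only Model 1 can bind MLCK at zero
Ca2+, and only Model 3 predicts zero binding of an N-lobe-knockout CaM
at saturating Ca2+. These structural zeros are the discriminating
observables; everything quantitative rides on top of them.

## From partition function to a closed form

Free Ca2+ ($x$, uM) is *clamped*: the experiments buffer it with
EGTA-based calibration solutions, so it is an independent variable and
is never conserved. At fixed $x$ the MLCK-free CaM states carry
weights

$$w_{00} = 1,\quad w_{10} = a_N x^h,\quad w_{01} = a_C x^h,\quad
  w_{11} = a_N a_C x^{2h},$$

with $a_N, a_C$ the lumped lobe association coefficients
(uM$^{-h}$) and $h$ the number of Ca2+ ions lumped per site
($h = 2$ by default; see below). Averaging the per-state MLCK
constants $K_M(s)$ over these weights gives an effective bimolecular
constant

$$K_{\mathrm{eff}}(x) = \frac{\sum_s w_s(x)\,K_M(s)}{\sum_s w_s(x)},$$

where $K_M(s) = 0$ for states the mechanism forbids. The network then
reduces, at every $x$, to one bimolecular reaction with conserved
totals $C$ (CaM) and $M$ (MLCK), whose bound fraction has the stable
closed form

$$F = \frac{2 K C}{1 + K(C+M) + \sqrt{1 + 2K(C+M) + K^2(C-M)^2}}.$$

In the $x \to 0$ and $x \to \infty$ limits $K_{\mathrm{eff}}$
collapses to a single constant ($K_9$; $K_2$ for wild type or $K_4$
for an N-lobe knockout), so the same expression gives all the limiting
predictions — the two limits differ only in which constant is passed,
and the package tests exploit that symmetry.

`fraction_bound_numeric()` solves the same equilibrium with none of
this algebra — state concentrations from weights and free-species
concentrations, conservation of both totals, bracketed root-finding on
free MLCK polished by Newton steps — and serves as the independent
oracle; the suite holds the two routes to within $10^{-9}$ relative
over 1000 random instances.

### Parameterization by state weights

The reaction cube has 12 edges but the equilibrium has only 6 free
state weights (up to normalization). camnet therefore stores *state*
quantities — two lobe coefficients and four $K_M$ values — and treats
every edge constant as a derived ratio. Thermodynamic-cycle
consistency is then automatic, and the unprinted edge constants of the
original diagrams never need individual values. An edge-labelled
import is deliberately not offered: the printed literature values pin
only $K_9$, $K_4$, $K_2$ and the C-lobe weight, and any edge
assignment consistent with them produces the same observable
predictions.

## Parameters, units and defaults

All concentrations are uM; association constants are uM$^{-1}$
(uM$^{-h}$ for lobe weights). No unit inference is performed. The
reference set (defaults of `camnet_params()`):

| parameter | meaning | default |
|---|---|---|
| $K_9$ | MLCK on apo-CaM | 0.078 uM$^{-1}$ |
| $K_4$ | MLCK on C-loaded CaM | 16.7 uM$^{-1}$ |
| $K_2$ | MLCK on fully loaded CaM | 1000 uM$^{-1}$ |
| $K_M$(N-only) | MLCK on N-loaded CaM | 0.078 uM$^{-1}$ |
| $a_C$ | C-lobe Ca2+ weight | 0.25 uM$^{-2}$ (eff. Kd 2 uM) |
| $a_N$ | N-lobe Ca2+ weight | 0.01 uM$^{-2}$ (eff. Kd 10 uM) |
| $h$ | Ca2+ per lumped site | 2 |

$K_9$, $K_4$ and $K_2$ are the published reference values (uM$^{-1}$
assumed for the latter two, consistent with reproducing the printed
percentages). The remaining constants are not pinned by published
limits, and were chosen once as follows. $K_M$(N-only) — used only by
Model 1 — is set equal to $K_9$, reflecting that the C-lobe dominates
MLCK affinity; no headline quantity depends on it. The lobe weights
use the standard literature lobe affinities (lumped-pair Kd of about
2 uM for the C-lobe and 10 uM for the N-lobe). These give titration
curves with the observed shape: negligible predicted binding below
0.04 uM free Ca2+ and near-saturation at 39 uM, where the numeric
value tracks the analytic high-Ca limit to within 0.1 percentage
point of binding. Headline quantities at "high Ca" are evaluated at
the finite experimental condition $x = 39$ uM rather than the limit,
so the lobe weights participate.

$h$ defaults to 2 (one cooperative EF-hand pair per lumped site) and
is configurable. The choice affects mid-curve steepness only: every
limiting prediction has $x \to 0$ or $x \to \infty$, where $h$
cancels. $h=2$ gives the sharper, more cooperative rise that measured
CaM titrations show.

## The synthetic data generator

`simulate_fret()` emulates the plate-reader FRET experiment: a
14-point free-Ca2+ ladder from 0 to 39 uM containing the seven design
anchors (0, 0.038, 0.1, 0.35, 1.35, 3, 39 uM; the seven unnamed
points are filled by approximate geometric interpolation and are
configurable), per-condition replicate counts matching the study
design (15/16/8/3 for wild type and the three mutants, 13 for the
reporter-only baseline), and per-well Em480/Em535 intensities. The
emission ratio is an explicit affine proxy
$r(x) = r_0 + \Delta r \cdot F(x)$ with defaults $r_0 = \Delta r =
0.5$ in arbitrary units — explicit because the ratio is not assumed to
be 1:1 with fraction bound. Noise is multiplicative Gaussian applied
*per channel* (default CV 0.02), not to the ratio, since ratios of
noisy channels are what the instrument delivers; channel-level noise
magnitudes are not published, so the default is a stand-in at the
scale of tight plate-reader replicates. `simulate_onbead()` emulates
gel densitometry the same way: bound/unbound band intensities over a
constant background whose corrected ratio recovers the true fraction
in expectation.

The generator does **not** emulate spectral bleed-through,
photobleaching, gain drift, pipetting gradients across the plate, or
any nonlinearity of the ratio-fraction relationship. Passing
end-to-end tests on these data therefore demonstrates that the
decision logic is correct and well-powered under the assumed noise
structure — not that the assay itself is free of systematic error.

## The decision rule and falsification counts

Observed binding calls follow a two-statistic rule per (CaM variant,
regime): a one-tailed Mann-Whitney U test of the endpoint ratios
(x = 0 or x = 39 uM) against the reporter-only baseline, and a second
U test of per-replicate trapezoidal AUCs ([0, 0.038] uM for the
zero-Ca regime, the full ladder otherwise). `"B"` requires both
p-values below $\alpha = 0.05$. This mirrors the paired endpoint/AUC
comparisons reported for the original data; whether those calls used
a formal threshold is not stated, so the conjunction rule at
$\alpha = 0.05$ is this package's own stated decision. The exact U
null distribution is used for small tie-free samples, the
tie-corrected normal approximation otherwise.

A model's prediction for a condition is falsified when it disagrees
with the observed call. Counts are reported two ways, because the
field's own usage mixes them: per condition (each table row counts),
and per *claim*, where falsified conditions are grouped by (regime,
predicted call) — the random model's zero-Ca binding prediction is one
structural claim however many CaM variants it is tested on. Against
the study's observed column the claim-level counts are 2 (Model 1), 0
(Model 2) and 1 (Model 3), with Model 2 correct on all six conditions.

A 9% detection limit (the demonstrated assay sensitivity) is available
through `detection_call()` as an annotation of which non-zero
predictions are experimentally visible; it never overrides structural
zeros. The predicted 5.3% zero-Ca binding at the main-experiment
concentrations sits below that limit, which is exactly why the
zero-Ca falsification test was also run at 50-fold higher CaM, where
the prediction rises to 73.5%.

## Sensitivity analyses

`k9_sweep()` tabulates the zero-Ca prediction over $K_9 \times$ CaM
grids (monotone increasing in both). `monte_carlo_f2n()` perturbs the
two parameters the N-lobe-knockout Model 2 prediction depends on
($K_4$ and the C-lobe weight $K_6$) by independent random multipliers
from [0.01, 100] and recomputes the fraction bound at 39 uM. The
default sampling law is log-uniform: the interval spans four orders of
magnitude around a scale parameter, and "chosen at random" without a
stated law is most naturally scale-invariant; plain uniform is
available. A deterministic 100x100 log-spaced grid scan
(`grid_scan_f2n()`) provides the cross-check for the Monte-Carlo
minimum. The published distributional lower bound for this quantity
depends on the unstated sampling law, so it is treated as exploratory
rather than as a reproduction target.

## Numerical choices

* The quadratic root is evaluated in the $2KC / (1 + K(C{+}M) +
  \sqrt{\cdot})$ form, which has no subtractive cancellation for any
  admissible inputs.
* Structural zeros are returned as exact 0 (the effective-affinity
  numerator is identically zero), never as small floats, so the B/NB
  logic can test `== 0`.
* The mass-action oracle brackets free MLCK in $[0, M_{tot}]$
  (the residual is monotone, so the bracket always holds), then takes
  up to four Newton steps, reaching machine precision.
* Degenerate variants with no MLCK-competent state (e.g. the
  quadruple EF-hand knockout under Model 2) return a flagged
  structural-zero curve rather than an error.
* The 4PL Hill fit runs Levenberg-Marquardt on linear $x$ with
  $x = 0$ admissible, bounds $EC_{50} > 0$ and
  $n \in [10^{-3}, 20]$, and flags flat series as unidentifiable
  before fitting and non-convergence after.
* All generators take integer seeds and restore the caller's RNG
  state; identical seeds give identical datasets.

## Problem sizes used by the test suite

The suite verifies the closed form against the oracle on 1000 random
instances, runs the end-to-end discrimination on 100 seeded synthetic
datasets at the study's replicate counts (expecting the partially
ordered model to be the unique unfalsified mechanism in at least 95),
and uses 20,000-40,000 Monte-Carlo draws against a 100x100 grid scan.
These sizes were chosen as the smallest that make the stochastic
assertions stable across seeds.

## Known limitations

* Kinetics, MLCK catalytic activation and EGTA buffering chemistry are
  out of scope; everything is equilibrium at clamped free Ca2+.
* The ratio-fraction map is affine by assumption; real reporters may
  saturate.
* The claim-level falsification count depends on grouping falsified
  conditions by predicted call and regime; other groupings are
  defensible, which is why the per-condition count is always reported
  alongside.
* With noise CV well above ~0.1 the multiplicative-Gaussian channel
  model can clip at zero intensity; the generator is not intended for
  that regime.
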