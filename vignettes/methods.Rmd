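---
title: "Models and methods in ppkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ppkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppkinetics)
```

This vignette documents the models the package fits, the inference
procedure for each assay, the defaults and why they were chosen, what the
synthetic-data generators do and do not emulate, and the numerical
decisions a maintainer would want written down.

## Time-course models

Two models of product formation are supported.

**Single turnover** (enzyme in excess of DNA): every productive
enzyme–DNA complex turns over once, so product rises as
$[P](t) = A\,(1 - e^{-k_{obs} t})$ with amplitude $A$ (µM, ideally the
DNA concentration) and observed rate $k_{obs}$ (s⁻¹).

**Burst** (DNA in slight excess of enzyme): when product release is
slower than chemistry, a fast exponential burst is followed by a linear
steady state, $[P](t) = A\,(1 - e^{-k_{burst} t}) + A\,k_{ss}\,t$. The
steady-state term is implemented with the amplitude multiplying $k_{ss}$,
so the linear slope is $A \cdot k_{ss}$ — deliberately the literal form of
the equation as used in kinetics tables of this kind. Users who prefer
the turnover-number convention (slope $= k_{cat}[E]$) can convert by
dividing the slope by the active-enzyme concentration; the package does
not do this silently.

Fitting is Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with
all parameters bounded below by zero, no upper bounds, and convergence
tolerances of 1e-12 on both the relative function and parameter change.
Parameter errors are one standard deviation (the 68.3% confidence
convention) from the covariance at the optimum. Initial guesses are
$A_0 = \max(P)$, $k_0 = 1/t_{1/2}$ (the time at half-maximal product),
and $k_{ss,0}$ from the slope of the last third of the points divided by
$A_0$; these are robust across the fast (wild-type-like, $k \sim 0.1$
s⁻¹) and slow (mutant-like, $k \sim 10^{-3}$ s⁻¹) regimes because they
derive from the data's own time scale. A fit that does not converge
returns a first-class `fit_failure` object rather than raising, so batch
titration fitting continues past a bad curve. A burst fit whose optimum
has $k_{burst}/k_{ss} < 5$ is flagged `ill_conditioned`: the two phases
are then not statistically separable and the split between them should
not be trusted.

Temperature is carried as condition metadata only. Assay temperature
conventions vary between instruments and labs, and reconciling them is a
judgment the analyst must make; the code never adjusts rates across
temperatures.

## Titration inference

The second stage turns per-concentration exponential fits into $k_{pol}$
(maximal incorporation rate), the apparent $K_d$ of the incoming
nucleotide, and the incorporation efficiency $k_{pol}/K_d$.

Two saturation forms are provided. The default **quadratic** form is the
smaller root of $x^2 - (K_d + S + k_{pol})x + S\,k_{pol} = 0$,

$$k_{obs}(S) = \tfrac12 (K_d + S + k_{pol}) - \tfrac12
\sqrt{(K_d + S + k_{pol})^2 - 4 S k_{pol}},$$

which is 0 at $S = 0$ and saturates at $k_{pol}$. The printed sources
this functional form descends from are frequently typeset with a
dimensionally impossible left-hand side; the only self-consistent reading
— the one implemented — is with $k_{obs}$ on the left, since it is the
observed rates that are plotted against concentration. The conventional
**hyperbolic** form $k_{pol} S/(K_d+S)$ is available via `form =
"hyperbolic"`, and every result records which form produced it, because
the two forms give different $K_d$ values away from their shared limits.

Two inference **branches** exist:

- *rate branch*: fit $k_{obs}$ vs $S$ to the saturation form. Used when
  the observed rate varies with concentration.
- *amplitude branch*: when the observed rate is flat in $S$ (typical of
  very weakly incorporated analogs where chemistry, not binding, is
  saturating the signal), $k_{pol}$ is the arithmetic mean of all
  observed rates and $K_d$ comes from fitting the burst amplitudes vs $S$
  to the same quadratic form with the saturating amplitude $A_{max}$ in
  the rate position.

`branch = "auto"` chooses via an F-test comparing a constant-rate model
to the saturating model on the $k_{obs}$ values, at `alpha = 0.05` by
default. The underlying observation ("the rate did not vary with
concentration") is usually stated without a criterion; an F-test makes
the choice reproducible and parameter-free beyond the significance level.

Efficiencies are never rounded internally; the report writer
(`write_kinetics_report`) applies display rounding — two significant
figures for efficiencies, one decimal for fold differences — and always
writes a full-precision machine-readable companion file, so printed
precision can be asserted without losing exactness.

## Thermal-shift analysis

Differential scanning fluorimetry reports protein unfolding as a rise in
dye fluorescence; instrument software conventionally plots a derivative
trace in which transitions appear as local minima. `derivative_curve`
computes the smoothed negative first derivative $-dF/dT$ with a
Savitzky–Golay filter: a centered moving polynomial of order 2,
differentiated analytically, with the filter's own one-sided polynomial
fits at the ends. Estimating the derivative inside the filter spreads the
differencing across the whole window, which suppresses bin-to-bin noise
far better than smoothing followed by finite differences — with plain
central differences the derivative noise at realistic amplitude noise
levels is comparable to the transition peaks themselves, which is why
this estimator was chosen. The default window of 11 points (5.5 °C at the
standard 0.5 °C grid) is comparable to the width of a protein unfolding
transition's derivative peak; windows this size average noise down
without measurably shifting peak positions, which the noiseless-recovery
tests confirm at sub-bin accuracy.

`find_melt_transitions` accepts a local minimum as a transition only if
two relative criteria hold, both scaled to the maximum absolute
derivative inside the search range (default 25–90 °C, excluding
assay-edge artifacts): its prominence must be at least `min_prominence`
(default 0.1) of that scale, *and* its value must be at least that deep
below zero. The depth criterion is what separates genuine transitions —
which pull the trace strongly negative — from noise wiggles around the
baseline, which can be locally prominent but never deep. Because both
criteria are relative, extraction is invariant to gain and offset in the
raw fluorescence. Accepted minima are refined by parabolic interpolation
through the three bins around the minimum. There is no principled,
assumption-free threshold separating a weak second transition from noise;
the threshold is therefore exposed as a parameter, and the two-peak vs
one-peak distinction is demonstrated on synthetic data only.

`aggregate_transitions` matches transitions greedily across replicates
(within `match_tolerance`, default 1.5 °C — small enough to keep
transitions ~7 °C apart separate, large enough to absorb replicate
jitter) and reports mean ± SD per matched group; a group present in fewer
than half the replicates is flagged rather than dropped.

No thermodynamic (two-state van't Hoff) fitting is attempted: the
derivative-minimum $T_m$ is the quantity of interest.

## Cellular readouts

**Respirometry.** The eight parameters derive from four anchor
measurements resolved from the injection-phase labels — last basal cycle
(M3 in the standard 3/6/3/3 layout), last oligomycin cycle (M9), first
FCCP cycle (M10), first rotenone/antimycin A cycle (M13) — so runs with
nonstandard cycle counts remain analyzable as long as the phase order is
respected. Differences are always reported; ratios with non-positive
denominators are returned as `NA` and named in `undefined_ratios` instead
of aborting. Negative post-subtraction rates are retained and flagged,
never clipped, because clipping would bias spare capacity upward.

**mtDNA content.** Relative mitochondrial DNA content is
$2 \cdot 2^{\Delta C_T}$ with $\Delta C_T = C_T^{nuc} - C_T^{mt}$.
Technical replicates are averaged on the CT scale *before* the transform
(a geometric mean on the copy scale); the alternative order — averaging
contents — is upward-biased under CT noise, and the averaging order is
documented here precisely because protocols often leave it unstated.

**Proliferation.** MTT absorbances are background-subtracted (mean of
no-cell wells) and normalized to the untreated-control mean; per-condition
mean, SD and n of that fraction are reported.

Statistical significance testing of these readouts (e.g. one-way ANOVA
across treatment groups) is deliberately out of scope: R's own `aov` does
it, and bundling it would add nothing.

## Synthetic data: what it emulates and what it does not

Each generator produces data with the deterministic structure its
analysis stage assumes plus independent Gaussian noise, fully determined
by a seed. The noise reference scale is chosen per assay to match how
each measurement's error actually scales: a fraction of the plateau
amplitude for time courses, of the local true value for titration rates
and amplitudes, of the mean transition amplitude for melt curves, of the
phase mean for OCR cycles, and absolute (cycles) for qPCR CTs. Default
concentration grids are 8 points log-spaced from $K_d/10$ to $10 K_d$
for the rate branch, and a 0–1000 µM span for the amplitude-branch
scenario, mirroring the ranges used in practice for natural nucleotides
and weakly bound analogs respectively. Melt transitions default to
logistic width 1.2 °C (a 10–90% unfolding width of roughly 5 °C, typical
of a small protein domain by DSF).

The generators deliberately do **not** emulate: replicate-to-replicate
(biological) variance components beyond the single noise knob; drift or
photobleaching in fluorescence baselines; exonuclease contamination or
substrate depletion in time courses; well-position effects on plates; or
gel-image artifacts (band intensities enter as numbers). Passing the
recovery tests therefore shows the estimators are correct and unbiased
under the assumed error model, not that the error model captures every
feature of real instrument data.

## Numerical choices and problem sizes

- All nonlinear fits: parameters $\ge 0$, no upper bounds, LM tolerances
  1e-12, at most 500 iterations.
- Quadratic-root evaluation clamps a (provably non-negative) discriminant
  at zero to absorb floating-point rounding.
- Parabolic $T_m$ refinement falls back to the bin center when the local
  curvature is non-positive.
- Ties in the greedy transition matching resolve in replicate order;
  with transitions well separated relative to `match_tolerance` the
  result is order-independent.
- Report files use locale-independent formatting, scientific notation
  below 1e-3.

The validation suites use problem sizes chosen to make sampling error
negligible relative to the tolerances being asserted while keeping the
whole suite fast: 200 simulations for median-error properties of the
exponential fitter, 100 replicate titrations for mean-recovery checks
(standard error of the mean ≈ 0.5% at 5% per-point noise, comfortably
inside the 5% acceptance band), 6 replicate melt curves matching the
usual replication of a DSF plate, and 1000 points for noise-calibration
moment checks.

## Known limitations

- Each curve is fit independently; there is no global multi-curve fitting
  across concentrations or contexts, matching the standard per-curve
  workflow this package reproduces.
- The quadratic and hyperbolic saturation forms are both phenomenological
  here; neither is derived from an explicit kinetic scheme, and the
  apparent $K_d$ is form-dependent.
- The amplitude branch estimates $k_{pol}$ as a plain mean of observed
  rates, inheriting whatever bias the per-curve exponential fits carry at
  very low signal.
- DSF peak detection near the search-range edges is less reliable because
  prominence cannot be evaluated past the boundary.
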