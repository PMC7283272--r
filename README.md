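# ppkinetics

Analysis toolkit for pre-steady-state DNA polymerase kinetics and the
cellular readouts used in nucleotide-analog (NRTI) toxicity studies —
built around the question of how efficiently a polymerase such as human
PrimPol incorporates a chain-terminating analog like tenofovir
diphosphate (TFV-DP) compared with its natural dNTP counterpart, and what
a loss-of-function active-site mutation does to catalysis, protein
stability and mitochondrial fitness.

It is aimed at enzymologists who quantify polymerase activity from
quenched-flow or manual-mixing time courses, and at cell biologists running
the companion plate assays (thermal shift, extracellular flux, qPCR-based
mtDNA quantification, MTT proliferation).

## What it computes

**Time-course models.** Product formation is fit to the single-turnover
exponential

    [product] = A (1 − e^(−k_obs t))

or, when DNA is in slight excess of enzyme and product release is
rate-limiting, to the biphasic burst equation

    [product] = A (1 − e^(−k_burst t)) + A k_ss t

by Levenberg–Marquardt least squares, with one-standard-deviation (68.3%
confidence) parameter errors from the covariance at the optimum.

**Titration inference.** Observed rates (or, for analogs whose rate is
concentration-independent, burst amplitudes) are fit against nucleotide
concentration with the quadratic saturation form

    k_obs(S) = ½(K_d + S + k_pol) − ½√((K_d + S + k_pol)² − 4 S k_pol)

(the smaller root of x² − (K_d+S+k_pol)x + S·k_pol = 0; a conventional
hyperbola k_pol·S/(K_d+S) is available as an alternative), yielding k_pol,
the apparent K_d, the incorporation efficiency k_pol/K_d, per-context fold
differences, and the discrimination factor
efficiency_dNTP / efficiency_NRTI. An F-test decides automatically between
the rate and amplitude branches.

**Thermal shift.** Melting temperatures are extracted from differential
scanning fluorimetry curves as local minima of the smoothed −dRFU/dT trace
(Savitzky–Golay derivative, parabolic peak refinement), then matched and
averaged across replicate wells.

**Cell assays.** The eight respirometry parameters (basal, proton leak,
ATP-linked, maximal, spare capacity, coupling efficiency, respiratory
control ratio, ATP-linked/maximal) from injection-phased OCR cycles;
relative mtDNA content as 2·2^ΔCT from mitochondrial/nuclear qPCR CT
pairs; and background-subtracted, control-normalized MTT proliferation.

**Synthetic data.** Every assay has a seeded generator with the matching
noise structure, so each analysis stage is validated by parameter
recovery (`analyze(simulate(truth, noise = 0))` returns the truth
exactly).

## Worked example

```r
library(ppkinetics)

# Natural nucleotide: rates rise with concentration (rate branch)
natural <- simulate_titration(
  k_pol = 4.6, K_d = 2.9, branch = "rate",
  noise_sd = 0.05, seed = 1, nucleotide_id = "dATP", context_tag = "PreT")
fit_nat <- fit_titration(natural, branch = "auto")
fit_nat
#> <kinetic_parameters> dATP / PreT [rate branch, quadratic form]
#>   k_pol = 4.802 +/- 0.11 1/s, K_d = 3.221 +/- 0.27 uM, k_pol/K_d = 1.49 1/(uM s)

# Analog: rates are flat, binding is read from the amplitudes
analog <- simulate_titration(
  k_pol = 0.0037, K_d = 45, branch = "amplitude", A_max = 0.5,
  concentrations = c(10, 25, 50, 100, 200, 400, 700, 1000),
  noise_sd = 0.05, seed = 1, nucleotide_id = "TFV-DP", context_tag = "PreT")
fit_ana <- fit_titration(analog, branch = "auto")
fit_ana
#> <kinetic_parameters> TFV-DP / PreT [amplitude branch, quadratic form]
#>   k_pol = 0.003724 +/- 5.6e-05 1/s, K_d = 41.72 +/- 6.4 uM, k_pol/K_d = 8.93e-05 1/(uM s)

discrimination_factor(fit_nat$efficiency, fit_ana$efficiency)
#> [1] 16699.38
```

The automatic branch choice classified the analog's rates as
concentration-independent (F-test), averaged them for k_pol and read K_d
from the amplitudes; the recovered parameters sit within noise of the
generating values, and the polymerase discriminates against the analog by
roughly 2 × 10⁴-fold in this favored sequence context.

```r
# Thermal shift: six replicate melt curves with two unfolding transitions
reps <- lapply(1:6, function(i) {
  mc <- simulate_melt_curve(
    data.frame(Tm = c(40.17, 47.17), amplitude = c(1, 1), width = c(1.2, 1.2)),
    noise_sd = 0.02, seed = i)
  melt_transitions(mc)
})
aggregate_transitions(reps)
#> <melt_transitions> 2 transition(s): Tm = 40.15, 47.02 degC
#>    mean_Tm    sd_Tm n flagged
#> 1 40.15256 0.110776 6   FALSE
#> 2 47.01873 0.187653 6   FALSE
```

Both melting temperatures are recovered to within 0.2 °C of the
generating values at 2% amplitude noise.

A thin command-line wrapper for batch work lives at
`inst/scripts/ppkin.R` (subcommands `fit-timecourse`, `fit-titration`,
`meltcurve`).

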