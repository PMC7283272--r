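# Shared fixture builders. All synthetic; seeds fixed by the caller.

# Time grid spanning both burst phases for wild-type-like rates
# (k_burst ~ 0.15/s, steady state out to ~200 s).
burst_times <- function() c(seq(0.5, 20, by = 0.5), seq(25, 200, by = 5))

exp_times <- function() seq(0.5, 30, by = 0.5)

# Two-transition (wild-type-like) melt curve; Tm values near the upper and
# lower unfolding transitions seen for the wild-type protein.
wt_melt <- function(seed = NULL, noise_sd = 0) {
  simulate_melt_curve(
    data.frame(Tm = c(40.17, 47.17), amplitude = c(1, 1),
               width = c(1.2, 1.2)),
    noise_sd = noise_sd, seed = seed
  )
}

# Single-transition (destabilized-mutant-like) melt curve.
mut_melt <- function(seed = NULL, noise_sd = 0) {
  simulate_melt_curve(
    data.frame(Tm = 40.17, amplitude = 1, width = 1.2),
    noise_sd = noise_sd, seed = seed
  )
}

# Standard 3/6/3/3 flux run whose anchors are exactly the given values.
flux_from_anchors <- function(m3, m9, m10, m13) {
  flux_run(
    1:15,
    rep(c("basal", "oligomycin", "fccp", "rot_aa"), c(3, 6, 3, 3)),
    c(m3, m3, m3, m9, m9, m9, m9, m9, m9, m10, m10, m10, m13, m13, m13)
  )
}
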