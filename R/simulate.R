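#' @name simulate
#' @title Seeded synthetic-data generators
#'
#' @description
#' Generators that emulate the statistical structure of each assay stage, for
#' validating the analysis functions by parameter recovery. Each generator is
#' a pure function of its arguments once `seed` is given: identical calls
#' yield identical data, and `noise_sd = 0` reproduces the corresponding
#' model evaluation exactly, so `analyze(simulate(truth, noise = 0))`
#' round-trips to the truth.
#'
#' Noise is Gaussian and independent per observation. The reference scale of
#' the noise fraction differs per assay, matching how each instrument's error
#' actually scales: time courses use the plateau amplitude, titrations the
#' local true value, melt curves the total transition amplitude, flux runs
#' the phase mean; qPCR noise is absolute, in CT cycles.
NULL

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()))
    }
    set.seed(seed)
  }
  expr
}

#' Simulate a product-formation time course
#'
#' Evaluates the single-turnover exponential or the biphasic burst model and
#' adds Gaussian noise with standard deviation `noise_sd * A` (a fraction of
#' the plateau amplitude). Negative noisy values are clamped at 0, as a gel
#' quantification cannot go below zero product. By default the amplitude is
#' taken from the condition: the DNA concentration under single-turnover
#' conditions (enzyme excess) and the active-enzyme concentration under burst
#' conditions.
#'
#' @param regime `"single_turnover"` or `"burst"`.
#' @param times sampling times in seconds.
#' @param k_obs observed rate (single-turnover regime), 1/s.
#' @param k_burst,k_ss burst and steady-state rates (burst regime), 1/s.
#' @param A amplitude in uM; defaults to `dna_conc` (single turnover) or
#'   `enzyme_conc` (burst).
#' @param enzyme_conc,dna_conc,nucleotide_id,nucleotide_conc,context_tag,temperature,label
#'   condition metadata, stored on the result.
#' @param noise_sd Gaussian noise SD as a fraction of `A` (default 0).
#' @param seed integer seed; fixes all randomness.
#' @return A [time_course()].
#' @export
simulate_timecourse <- function(regime = c("single_turnover", "burst"),
                                times,
                                k_obs = NULL, k_burst = NULL, k_ss = NULL,
                                A = NULL,
                                enzyme_conc = NA_real_, dna_conc = NA_real_,
                                nucleotide_id = NA_character_,
                                nucleotide_conc = NA_real_,
                                context_tag = "none",
                                temperature = NA_real_, label = "",
                                noise_sd = 0, seed = NULL) {
  regime <- match.arg(regime)
  if (is.null(A)) {
    A <- if (regime == "single_turnover") dna_conc else enzyme_conc
  }
  if (!is.finite(A) || A <= 0) {
    stop("amplitude A must be positive (set A or the relevant concentration)",
         call. = FALSE)
  }
  model <- if (regime == "single_turnover") {
    eval_single_exponential(times, A, k_obs)
  } else {
    eval_burst(times, A, k_burst, k_ss)
  }
  product <- with_seed(seed, {
    pmax(model + stats::rnorm(length(times), sd = noise_sd * A), 0)
  })
  time_course(times, product,
              enzyme_conc = enzyme_conc, dna_conc = dna_conc,
              nucleotide_id = nucleotide_id,
              nucleotide_conc = nucleotide_conc,
              context_tag = context_tag, temperature = temperature,
              label = label)
}

#' Default titration concentration grid
#'
#' Eight points log-spaced from `K_d / 10` to `10 K_d`, bracketing the
#' binding constant by a decade on each side.
#'
#' @param K_d apparent binding constant in uM.
#' @param n number of concentrations (default 8).
#' @return numeric vector of concentrations in uM.
#' @export
default_conc_grid <- function(K_d, n = 8) {
  exp(seq(log(K_d / 10), log(10 * K_d), length.out = n))
}

#' Simulate a nucleotide titration series
#'
#' Rate branch: the observed rate at each concentration follows the chosen
#' saturation form with multiplicative Gaussian noise
#' (`sd = noise_sd * true value`). Amplitude branch (the path for analogs
#' whose rate is concentration-independent): the rate is constant at `k_pol`
#' plus noise, while the amplitude follows [quadratic_amplitude()] plus
#' noise.
#'
#' @param k_pol true maximal rate, 1/s.
#' @param K_d true apparent binding constant, uM.
#' @param concentrations nucleotide concentrations in uM; defaults to
#'   [default_conc_grid()] of `K_d`.
#' @param branch `"rate"` or `"amplitude"`.
#' @param form saturation form for the rate branch.
#' @param A_max saturating amplitude in uM (amplitude branch).
#' @param noise_sd Gaussian noise SD as a fraction of each true value.
#' @param seed integer seed.
#' @param nucleotide_id,context_tag metadata for the series.
#' @return A [titration_series()].
#' @export
simulate_titration <- function(k_pol, K_d, concentrations = NULL,
                               branch = c("rate", "amplitude"),
                               form = c("quadratic", "hyperbolic"),
                               A_max = 0.5, noise_sd = 0, seed = NULL,
                               nucleotide_id = NA_character_,
                               context_tag = "none") {
  branch <- match.arg(branch)
  form <- match.arg(form)
  if (is.null(concentrations)) concentrations <- default_conc_grid(K_d)
  S <- sort(concentrations)
  with_seed(seed, {
    if (branch == "rate") {
      true_k <- if (form == "quadratic") quadratic_rate(S, k_pol, K_d)
                else hyperbolic_rate(S, k_pol, K_d)
      k <- pmax(true_k + stats::rnorm(length(S), sd = noise_sd * true_k), 0)
      titration_series(S, k, nucleotide_id = nucleotide_id,
                       context_tag = context_tag)
    } else {
      k <- pmax(k_pol + stats::rnorm(length(S), sd = noise_sd * k_pol), 0)
      true_a <- quadratic_amplitude(S, A_max, K_d)
      a <- pmax(true_a + stats::rnorm(length(S), sd = noise_sd * true_a), 0)
      titration_series(S, k, amplitude = a, nucleotide_id = nucleotide_id,
                       context_tag = context_tag)
    }
  })
}

#' Simulate a differential scanning fluorimetry melt curve
#'
#' Sum of ascending logistic unfolding transitions,
#' `amplitude / (1 + exp(-(T - Tm)/width))`, over a linear baseline, plus
#' Gaussian noise whose SD is `noise_sd` times the mean transition amplitude
#' (the natural scale of the signal of interest). The analytic minimum of
#' `-dRFU/dT` of each logistic sits exactly at its `Tm`.
#'
#' @param transitions data frame with columns `Tm` (degC), `amplitude` (RFU)
#'   and `width` (degC, > 0); one row per transition. Zero-amplitude rows
#'   produce a flat contribution.
#' @param grid list or numeric vector `c(start, stop, step)` in degC;
#'   default 25 to 95 in 0.5 degC steps, the usual instrument ramp.
#' @param baseline length-2 numeric `c(intercept, slope)` of the linear
#'   background RFU (default flat 0).
#' @param noise_sd Gaussian noise SD as a fraction of the mean transition
#'   amplitude.
#' @param seed integer seed.
#' @param well_id,condition metadata labels.
#' @return A [melt_curve()].
#' @export
simulate_melt_curve <- function(transitions,
                                grid = c(25, 95, 0.5),
                                baseline = c(0, 0),
                                noise_sd = 0, seed = NULL,
                                well_id = "", condition = "") {
  stopifnot(all(c("Tm", "amplitude", "width") %in% names(transitions)))
  if (any(transitions$width <= 0)) stop("widths must be > 0", call. = FALSE)
  if (grid[3] <= 0) stop("grid step must be > 0", call. = FALSE)
  temp <- seq(grid[1], grid[2], by = grid[3])
  rfu <- baseline[1] + baseline[2] * temp
  for (i in seq_len(nrow(transitions))) {
    rfu <- rfu + transitions$amplitude[i] /
      (1 + exp(-(temp - transitions$Tm[i]) / transitions$width[i]))
  }
  amp_scale <- mean(abs(transitions$amplitude))
  rfu <- with_seed(seed, {
    rfu + stats::rnorm(length(temp), sd = noise_sd * amp_scale)
  })
  melt_curve(temp, rfu, well_id = well_id, condition = condition)
}

#' Simulate an extracellular-flux (OCR) run
#'
#' Each measurement cycle's OCR is its phase mean plus Gaussian noise
#' (`sd = noise_sd * phase mean`).
#'
#' @param phase_means named numeric: `basal`, `oligomycin`, `fccp`, `rot_aa`
#'   mean OCR in pmol O2/min.
#' @param cycle_counts named integer vector of cycles per phase; the default
#'   `c(basal = 3, oligomycin = 6, fccp = 3, rot_aa = 3)` reproduces the
#'   standard 3/6/3/3 injection protocol.
#' @param noise_sd Gaussian noise SD as a fraction of each phase mean.
#' @param seed integer seed.
#' @param well_id,condition metadata labels.
#' @return A [flux_run()].
#' @export
simulate_flux_run <- function(phase_means,
                              cycle_counts = c(basal = 3, oligomycin = 6,
                                               fccp = 3, rot_aa = 3),
                              noise_sd = 0, seed = NULL,
                              well_id = "", condition = "") {
  phases <- c("basal", "oligomycin", "fccp", "rot_aa")
  stopifnot(all(phases %in% names(phase_means)),
            all(phases %in% names(cycle_counts)))
  phase_vec <- rep(phases, times = cycle_counts[phases])
  means <- phase_means[phase_vec]
  values <- with_seed(seed, {
    means + stats::rnorm(length(means), sd = noise_sd * abs(means))
  })
  flux_run(seq_along(values), phase_vec, values,
           well_id = well_id, condition = condition)
}

#' Simulate qPCR CT pairs for relative mtDNA quantification
#'
#' Inverts the `2 * 2^dCT` transform: for a true relative content `c`, the
#' mitochondrial CT sits `log2(c / 2)` cycles below the nuclear CT. Gaussian
#' noise (absolute, in cycles) is added independently to each CT.
#'
#' @param true_relative_content true relative mtDNA content (dimensionless).
#' @param ct_nuc_base nuclear-target threshold cycle (cycles).
#' @param replicates number of replicate pairs.
#' @param sd_ct Gaussian CT noise in cycles (default 0).
#' @param seed integer seed.
#' @param sample sample label.
#' @return data frame with columns `sample`, `replicate`, `ct_mt`, `ct_nuc`.
#' @export
simulate_qpcr <- function(true_relative_content, ct_nuc_base = 25,
                          replicates = 3, sd_ct = 0, seed = NULL,
                          sample = "sample") {
  stopifnot(true_relative_content > 0)
  ct_mt_true <- ct_nuc_base - log2(true_relative_content / 2)
  with_seed(seed, {
    data.frame(
      sample = sample,
      replicate = seq_len(replicates),
      ct_mt = ct_mt_true + stats::rnorm(replicates, sd = sd_ct),
      ct_nuc = ct_nuc_base + stats::rnorm(replicates, sd = sd_ct)
    )
  })
}
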