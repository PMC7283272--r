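#' Time course of product formation
#'
#' Container for a single reaction condition: product concentration measured
#' over time, plus the condition metadata (enzyme and DNA concentrations, the
#' incoming nucleotide and its concentration, the preceding-nucleotide context
#' of the primer terminus, and temperature). Temperature is carried as
#' metadata only; no temperature correction is ever applied.
#'
#' @param times numeric, seconds; non-negative and strictly increasing.
#' @param product numeric, product concentration in uM, one per time point.
#' @param enzyme_conc,dna_conc,nucleotide_conc concentrations in uM (metadata).
#' @param nucleotide_id e.g. `"dATP"`, `"TFV-DP"` (metadata).
#' @param context_tag preceding-nucleotide context, one of
#'   `"PreA"`, `"PreC"`, `"PreG"`, `"PreT"`, `"none"`.
#' @param temperature degrees C (metadata).
#' @param label free-text label.
#' @return An object of class `time_course`: a list with a `data` data frame
#'   (`times`, `product`) and a `condition` list.
#' @export
time_course <- function(times, product,
                        enzyme_conc = NA_real_, dna_conc = NA_real_,
                        nucleotide_id = NA_character_,
                        nucleotide_conc = NA_real_,
                        context_tag = "none",
                        temperature = NA_real_, label = "") {
  times <- as.numeric(times)
  product <- as.numeric(product)
  if (length(times) != length(product)) {
    stop("times and product must have equal length", call. = FALSE)
  }
  if (length(times) < 4) stop("need at least 4 time points", call. = FALSE)
  if (!all(is.finite(times)) || !all(is.finite(product))) {
    stop("times and product must be finite", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(product < 0)) stop("product must be >= 0", call. = FALSE)
  context_tag <- match.arg(context_tag,
                           c("PreA", "PreC", "PreG", "PreT", "none"))
  structure(
    list(
      data = data.frame(times = times, product = product),
      condition = list(
        enzyme_conc = enzyme_conc, dna_conc = dna_conc,
        nucleotide_id = nucleotide_id, nucleotide_conc = nucleotide_conc,
        context_tag = context_tag, temperature = temperature, label = label
      )
    ),
    class = "time_course"
  )
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course> ", nrow(x$data), " points, t = ",
      min(x$data$times), "-", max(x$data$times), " s",
      if (!is.na(x$condition$nucleotide_id))
        paste0(", ", x$condition$nucleotide_id,
               " [", x$condition$nucleotide_conc, " uM]"),
      if (x$condition$context_tag != "none")
        paste0(", ", x$condition$context_tag),
      "\n", sep = "")
  invisible(x)
}

#' Single-turnover exponential model
#'
#' Product formation under single-turnover conditions (enzyme in excess of
#' DNA): `[product] = A (1 - exp(-k_obs t))`, rising from 0 at `t = 0` to the
#' amplitude `A` as `t -> Inf`.
#'
#' @param t time in seconds, vectorized; `t >= 0`.
#' @param A amplitude in uM; `A > 0`.
#' @param k_obs observed single-exponential rate in 1/s; `k_obs > 0`.
#' @return product concentration in uM.
#' @export
eval_single_exponential <- function(t, A, k_obs) {
  check_finite(t, A, k_obs, .names = c("t", "A", "k_obs"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (A <= 0 || k_obs <= 0) stop("A and k_obs must be > 0", call. = FALSE)
  A * (1 - exp(-k_obs * t))
}

#' Biphasic burst model
#'
#' Product formation under burst conditions (DNA in slight excess of enzyme):
#' a fast exponential burst followed by a linear steady state,
#' `[product] = A (1 - exp(-k_burst t)) + A k_ss t`. The steady-state slope is
#' `A * k_ss` exactly as the model is written: users converting `k_ss` to a
#' per-enzyme turnover number should divide the slope by the active-enzyme
#' concentration themselves.
#'
#' @param t time in seconds, vectorized; `t >= 0`.
#' @param A burst amplitude in uM; `A > 0`.
#' @param k_burst exponential (burst) rate in 1/s; `k_burst > 0`.
#' @param k_ss steady-state rate in 1/s; `k_ss >= 0`. With `k_ss = 0` the
#'   model reduces to [eval_single_exponential()].
#' @return product concentration in uM.
#' @export
eval_burst <- function(t, A, k_burst, k_ss) {
  check_finite(t, A, k_burst, k_ss, .names = c("t", "A", "k_burst", "k_ss"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (A <= 0 || k_burst <= 0) stop("A and k_burst must be > 0", call. = FALSE)
  if (k_ss < 0) stop("k_ss must be >= 0", call. = FALSE)
  A * (1 - exp(-k_burst * t)) + A * k_ss * t
}

# Default initial guesses, robust for both fast (wild-type) and slow (mutant)
# regimes: A from the largest observed product, k from the reciprocal of the
# time at half-maximal product.
default_exp_init <- function(times, product) {
  A0 <- max(product)
  if (A0 <= 0) A0 <- 1e-6
  i_half <- which(product >= A0 / 2)[1]
  t_half <- times[i_half]
  k0 <- if (is.na(t_half) || t_half <= 0) 1 / max(times) else 1 / t_half
  list(A = A0, k_obs = k0)
}

#' Fit the single-turnover exponential model
#'
#' Least-squares fit of `A (1 - exp(-k_obs t))` to a time course, with
#' one-standard-deviation parameter errors (68.3% confidence) from the
#' estimated covariance at the optimum.
#'
#' @param tc a [time_course()] with at least 4 points and at least one
#'   positive product value.
#' @param init optional list with starting values `A` and `k_obs`; by default
#'   `A = max(product)` and `k_obs` = reciprocal of the time at half-maximal
#'   product.
#' @return An object of class `exponential_fit` with fields `amplitude_A`,
#'   `k_obs`, `se_A`, `se_kobs`, `rss`, `n_points`, `fitted`; or a
#'   [fit_failure()] if the optimizer does not converge.
#' @export
fit_single_exponential <- function(tc, init = NULL) {
  stopifnot(inherits(tc, "time_course"))
  d <- tc$data
  if (!any(d$product > 0)) {
    stop("need at least one point with product > 0", call. = FALSE)
  }
  if (is.null(init)) init <- default_exp_init(d$times, d$product)
  fit <- lm_fit(product ~ A * (1 - exp(-k_obs * times)), data = d,
                start = list(A = init$A, k_obs = init$k_obs),
                stage = "fit_single_exponential")
  if (is_fit_failure(fit)) return(fit)
  cf <- stats::coef(fit)
  se <- param_se(fit)
  res <- d$product - eval_single_exponential(d$times, cf[["A"]], cf[["k_obs"]])
  structure(
    list(
      amplitude_A = cf[["A"]], k_obs = cf[["k_obs"]],
      se_A = unname(se["A"]), se_kobs = unname(se["k_obs"]),
      rss = sum(res^2), n_points = nrow(d),
      fitted = stats::fitted(fit), condition = tc$condition
    ),
    class = "exponential_fit"
  )
}

#' @export
print.exponential_fit <- function(x, ...) {
  cat(sprintf(
    "<exponential_fit> A = %.4g +/- %.2g uM, k_obs = %.4g +/- %.2g 1/s (n = %d, RSS = %.3g)\n",
    x$amplitude_A, x$se_A, x$k_obs, x$se_kobs, x$n_points, x$rss))
  invisible(x)
}

#' Fit the biphasic burst model
#'
#' Least-squares fit of `A (1 - exp(-k_burst t)) + A k_ss t`. The fit is
#' flagged ill-conditioned when the two phases are not separable
#' (`k_burst / k_ss < 5` at the optimum); the parameter estimates are still
#' returned so ratios between two fits stay computable.
#'
#' @param tc a [time_course()] with at least 6 points spanning both phases.
#' @param init optional list with starting values `A`, `k_burst`, `k_ss`; the
#'   default seeds `k_ss` from the slope of the last third of the points
#'   divided by the amplitude guess.
#' @return An object of class `burst_fit` with fields `amplitude_A`,
#'   `k_burst`, `k_ss`, their standard errors, `rss`, `n_points`,
#'   `ill_conditioned`; or a [fit_failure()].
#' @export
fit_burst <- function(tc, init = NULL) {
  stopifnot(inherits(tc, "time_course"))
  d <- tc$data
  if (nrow(d) < 6) stop("burst fit needs at least 6 points", call. = FALSE)
  if (!any(d$product > 0)) {
    stop("need at least one point with product > 0", call. = FALSE)
  }
  if (is.null(init)) {
    e0 <- default_exp_init(d$times, d$product)
    tail_i <- seq.int(ceiling(2 * nrow(d) / 3), nrow(d))
    slope <- if (length(tail_i) >= 2) {
      stats::coef(stats::lm(product ~ times, data = d[tail_i, ]))[["times"]]
    } else 0
    init <- list(A = e0$A, k_burst = e0$k_obs,
                 k_ss = max(slope, 0) / e0$A)
  }
  fit <- lm_fit(
    product ~ A * (1 - exp(-k_burst * times)) + A * k_ss * times, data = d,
    start = list(A = init$A, k_burst = init$k_burst, k_ss = init$k_ss),
    stage = "fit_burst")
  if (is_fit_failure(fit)) return(fit)
  cf <- stats::coef(fit)
  se <- param_se(fit)
  res <- d$product -
    eval_burst(d$times, cf[["A"]], cf[["k_burst"]], cf[["k_ss"]])
  structure(
    list(
      amplitude_A = cf[["A"]], k_burst = cf[["k_burst"]], k_ss = cf[["k_ss"]],
      se_A = unname(se["A"]), se_kburst = unname(se["k_burst"]),
      se_kss = unname(se["k_ss"]),
      rss = sum(res^2), n_points = nrow(d),
      ill_conditioned = cf[["k_ss"]] > 0 && cf[["k_burst"]] / cf[["k_ss"]] < 5,
      condition = tc$condition
    ),
    class = "burst_fit"
  )
}

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf(
    "<burst_fit> A = %.4g +/- %.2g uM, k_burst = %.4g +/- %.2g 1/s, k_ss = %.4g +/- %.2g 1/s%s\n",
    x$amplitude_A, x$se_A, x$k_burst, x$se_kburst, x$k_ss, x$se_kss,
    if (isTRUE(x$ill_conditioned)) "  [ill-conditioned: phases not separable]"
    else ""))
  invisible(x)
}

#' Convert gel band intensities to product concentration
#'
#' Standard intensity-to-concentration conversion for quantified gel lanes:
#' the product fraction of total lane intensity times the substrate
#' concentration. Band intensities arrive as numbers; no image processing is
#' done here.
#'
#' @param intensity_product,intensity_unextended band intensities (arbitrary
#'   units, `>= 0`, not both zero). Vectorized.
#' @param substrate_conc substrate concentration in uM.
#' @return product concentration in uM.
#' @export
band_fraction_to_product <- function(intensity_product, intensity_unextended,
                                     substrate_conc) {
  check_finite(intensity_product, intensity_unextended, substrate_conc,
               .names = c("intensity_product", "intensity_unextended",
                          "substrate_conc"))
  if (any(intensity_product < 0) || any(intensity_unextended < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  total <- intensity_product + intensity_unextended
  if (any(total == 0)) {
    stop("product and unextended intensities are both zero", call. = FALSE)
  }
  substrate_conc * intensity_product / total
}
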