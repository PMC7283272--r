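#' Nucleotide titration series
#'
#' Per-concentration single-exponential fit results for one nucleotide in one
#' preceding-nucleotide context: the observed rates (and amplitudes) at each
#' nucleotide concentration, ready for the second-stage saturation fit.
#'
#' @param conc nucleotide concentrations in uM; `>= 0`, strictly increasing,
#'   at least 4 distinct values.
#' @param k_obs observed single-exponential rates in 1/s, one per
#'   concentration.
#' @param amplitude optional fitted amplitudes in uM (needed for the
#'   amplitude branch).
#' @param se_kobs,se_amp optional one-SD errors.
#' @param nucleotide_id e.g. `"dATP"`, `"TFV-DP"`.
#' @param context_tag preceding-nucleotide context
#'   (`"PreA"`, `"PreC"`, `"PreG"`, `"PreT"`, `"none"`).
#' @return An object of class `titration_series` wrapping a data frame.
#' @export
titration_series <- function(conc, k_obs, amplitude = NULL,
                             se_kobs = NULL, se_amp = NULL,
                             nucleotide_id = NA_character_,
                             context_tag = "none") {
  conc <- as.numeric(conc)
  k_obs <- as.numeric(k_obs)
  if (length(conc) < 4) {
    stop("need at least 4 concentrations", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(diff(conc) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (length(k_obs) != length(conc)) {
    stop("k_obs must have one value per concentration", call. = FALSE)
  }
  context_tag <- match.arg(context_tag,
                           c("PreA", "PreC", "PreG", "PreT", "none"))
  d <- data.frame(conc = conc, k_obs = k_obs)
  d$amplitude <- if (is.null(amplitude)) NA_real_ else as.numeric(amplitude)
  d$se_kobs <- if (is.null(se_kobs)) NA_real_ else as.numeric(se_kobs)
  d$se_amp <- if (is.null(se_amp)) NA_real_ else as.numeric(se_amp)
  structure(
    list(data = d, nucleotide_id = nucleotide_id, context_tag = context_tag),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series> ", x$nucleotide_id, " / ", x$context_tag, ": ",
      nrow(x$data), " concentrations (",
      min(x$data$conc), "-", max(x$data$conc), " uM)\n", sep = "")
  invisible(x)
}

#' Hyperbolic saturation model
#'
#' Conventional Michaelis-type saturation of the observed rate with
#' nucleotide concentration: `k_obs = k_pol S / (K_d + S)`.
#'
#' @param S nucleotide concentration in uM, vectorized; `S >= 0`.
#' @param k_pol maximal incorporation rate in 1/s.
#' @param K_d apparent nucleotide binding constant in uM.
#' @return observed rate in 1/s.
#' @export
hyperbolic_rate <- function(S, k_pol, K_d) {
  if (any(S < 0)) stop("S must be >= 0", call. = FALSE)
  if (k_pol < 0 || K_d < 0) stop("parameters must be >= 0", call. = FALSE)
  k_pol * S / (K_d + S)
}

#' Quadratic saturation model
#'
#' The smaller root of `x^2 - (K_d + S + k_pol) x + S k_pol = 0`, i.e.
#' `0.5 (K_d + S + k_pol) - 0.5 sqrt((K_d + S + k_pol)^2 - 4 S k_pol)`,
#' read as the observed rate at nucleotide concentration `S`. It is 0 at
#' `S = 0` and saturates at `k_pol` as `S -> Inf`, like the hyperbola but with
#' a sharper approach to saturation.
#'
#' @inheritParams hyperbolic_rate
#' @return observed rate in 1/s.
#' @export
quadratic_rate <- function(S, k_pol, K_d) {
  if (any(S < 0)) stop("S must be >= 0", call. = FALSE)
  if (k_pol < 0 || K_d < 0) stop("parameters must be >= 0", call. = FALSE)
  b <- K_d + S + k_pol
  disc <- b^2 - 4 * S * k_pol
  # the smaller root always has a non-negative discriminant; clamp rounding
  0.5 * b - 0.5 * sqrt(pmax(disc, 0))
}

#' Quadratic amplitude model
#'
#' Same functional form as [quadratic_rate()] with the saturating amplitude
#' `A_max` (uM) in the rate position: used when the observed rate is
#' concentration-independent and binding is instead read out of the burst
#' amplitude.
#'
#' @param S nucleotide concentration in uM, vectorized.
#' @param A_max saturating amplitude in uM.
#' @param K_d apparent binding constant in uM.
#' @return amplitude in uM.
#' @export
quadratic_amplitude <- function(S, A_max, K_d) {
  quadratic_rate(S, A_max, K_d)
}

#' Test whether observed rates depend on nucleotide concentration
#'
#' F-test comparing a constant-rate model against the saturating model on the
#' `k_obs` values of a titration. "independent" means the saturating model
#' does not significantly reduce the residual sum of squares at level
#' `alpha`; this is the criterion the automatic branch of [fit_titration()]
#' uses to decide between the rate and amplitude inference paths.
#'
#' @param series a [titration_series()] with at least 4 concentrations.
#' @param alpha significance level (default 0.05).
#' @param form saturation form used for the alternative model.
#' @return A list with `classification` (`"dependent"` or `"independent"`),
#'   `p_value`, `f_statistic`, `rss_constant`, `rss_saturating`.
#' @export
test_rate_concentration_dependence <- function(series, alpha = 0.05,
                                               form = c("quadratic",
                                                        "hyperbolic")) {
  stopifnot(inherits(series, "titration_series"))
  form <- match.arg(form)
  d <- series$data
  n <- nrow(d)
  if (n < 4) stop("need at least 4 concentrations", call. = FALSE)
  rss0 <- sum((d$k_obs - mean(d$k_obs))^2)
  if (rss0 == 0) {
    # all rates identical: trivially concentration-independent
    return(list(classification = "independent", p_value = 1,
                f_statistic = 0, rss_constant = 0, rss_saturating = 0))
  }
  sat <- fit_saturation(d$conc, d$k_obs, form, stage = "rate_dependence")
  if (is_fit_failure(sat)) {
    return(list(classification = "independent", p_value = NA_real_,
                f_statistic = NA_real_, rss_constant = rss0,
                rss_saturating = NA_real_))
  }
  rss1 <- sum(stats::resid(sat)^2)
  f <- ((rss0 - rss1) / 1) / (rss1 / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  list(
    classification = if (is.finite(p) && p < alpha) "dependent"
                     else "independent",
    p_value = p, f_statistic = f,
    rss_constant = rss0, rss_saturating = rss1
  )
}

# Saturation fit of y against concentration S for either form; initial K_d
# from the concentration at half-maximal response.
fit_saturation <- function(S, y, form, stage = "fit_titration") {
  ymax <- max(y)
  i_half <- which(y >= ymax / 2)[1]
  Kd0 <- S[i_half]
  if (is.na(Kd0) || Kd0 <= 0) Kd0 <- stats::median(S[S > 0])
  d <- data.frame(S = S, y = y)
  frm <- if (form == "quadratic") {
    y ~ quadratic_rate(S, vmax, Kd)
  } else {
    y ~ hyperbolic_rate(S, vmax, Kd)
  }
  lm_fit(frm, data = d, start = list(vmax = ymax, Kd = Kd0), stage = stage)
}

#' Infer kpol and apparent Kd from a titration
#'
#' Second inference stage. In the rate branch the per-concentration observed
#' rates are fit to the chosen saturation form, giving `k_pol` (plateau) and
#' apparent `K_d`. In the amplitude branch -- used when the observed rate does
#' not vary with concentration, as for weakly incorporated analogs -- `k_pol`
#' is the arithmetic mean of all observed rates and `K_d` comes from fitting
#' the amplitudes against concentration with [quadratic_amplitude()].
#' `branch = "auto"` chooses using
#' [test_rate_concentration_dependence()].
#'
#' @param series a [titration_series()].
#' @param form saturation form, `"quadratic"` (default) or `"hyperbolic"`.
#' @param branch `"auto"`, `"rate"` or `"amplitude"`.
#' @param alpha significance level for the automatic branch choice.
#' @return An object of class `kinetic_parameters` with fields `k_pol`, `K_d`,
#'   `efficiency` (`= k_pol / K_d`, unrounded), `se_kpol`, `se_Kd`, `branch`,
#'   `form`, `nucleotide_id`, `context_tag`; or a [fit_failure()].
#' @export
fit_titration <- function(series, form = c("quadratic", "hyperbolic"),
                          branch = c("auto", "rate", "amplitude"),
                          alpha = 0.05) {
  stopifnot(inherits(series, "titration_series"))
  form <- match.arg(form)
  branch <- match.arg(branch)
  d <- series$data
  if (branch == "auto") {
    dep <- test_rate_concentration_dependence(series, alpha = alpha,
                                              form = form)
    branch <- if (dep$classification == "dependent") "rate" else "amplitude"
  }
  if (branch == "rate") {
    keep <- d$conc > 0 | d$k_obs > 0
    fit <- fit_saturation(d$conc[keep], d$k_obs[keep], form,
                          stage = "fit_titration(rate)")
    if (is_fit_failure(fit)) return(fit)
    cf <- stats::coef(fit)
    se <- param_se(fit)
    k_pol <- cf[["vmax"]]; K_d <- cf[["Kd"]]
    se_kpol <- unname(se["vmax"]); se_Kd <- unname(se["Kd"])
  } else {
    if (all(is.na(d$amplitude))) {
      stop("amplitude branch requires amplitudes in the series",
           call. = FALSE)
    }
    k_pol <- mean(d$k_obs)
    se_kpol <- stats::sd(d$k_obs) / sqrt(nrow(d))
    amax0 <- max(d$amplitude)
    i_half <- which(d$amplitude >= amax0 / 2)[1]
    Kd0 <- d$conc[i_half]
    if (is.na(Kd0) || Kd0 <= 0) Kd0 <- stats::median(d$conc[d$conc > 0])
    fit <- lm_fit(amplitude ~ quadratic_amplitude(conc, Amax, Kd), data = d,
                  start = list(Amax = amax0, Kd = Kd0),
                  stage = "fit_titration(amplitude)")
    if (is_fit_failure(fit)) return(fit)
    cf <- stats::coef(fit)
    se <- param_se(fit)
    K_d <- cf[["Kd"]]
    se_Kd <- unname(se["Kd"])
  }
  structure(
    list(
      k_pol = k_pol, K_d = K_d,
      efficiency = k_pol / K_d,
      se_kpol = se_kpol, se_Kd = se_Kd,
      branch = branch, form = form,
      nucleotide_id = series$nucleotide_id,
      context_tag = series$context_tag
    ),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat(sprintf(
    "<kinetic_parameters> %s / %s [%s branch, %s form]\n  k_pol = %.4g +/- %.2g 1/s, K_d = %.4g +/- %.2g uM, k_pol/K_d = %.3g 1/(uM s)\n",
    x$nucleotide_id, x$context_tag, x$branch, x$form,
    x$k_pol, x$se_kpol, x$K_d, x$se_Kd, x$efficiency))
  invisible(x)
}

#' Incorporation efficiency
#'
#' `k_pol / K_d`, the overall efficiency of nucleotide incorporation in
#' 1/(uM s).
#'
#' @param k_pol maximal incorporation rate, 1/s.
#' @param K_d apparent binding constant, uM; `> 0`.
#' @return efficiency in 1/(uM s).
#' @export
incorporation_efficiency <- function(k_pol, K_d) {
  if (any(K_d <= 0)) stop("K_d must be > 0", call. = FALSE)
  k_pol / K_d
}

#' Fold differences in efficiency across sequence contexts
#'
#' Divides each context's incorporation efficiency by the efficiency in the
#' reference context, so the reference maps to exactly 1.
#'
#' @param effs named numeric vector of efficiencies (names are context tags);
#'   all `> 0`.
#' @param reference name of the reference context, present in `effs`.
#' @return named numeric vector of fold differences.
#' @export
fold_difference_table <- function(effs, reference) {
  if (!reference %in% names(effs)) {
    stop("reference context '", reference, "' not present", call. = FALSE)
  }
  if (any(effs <= 0)) stop("efficiencies must be > 0", call. = FALSE)
  effs / effs[[reference]]
}

#' Discrimination factor against a nucleotide analog
#'
#' Ratio of incorporation efficiencies, natural nucleotide over analog
#' (`efficiency_dNTP / efficiency_NRTI`): how many-fold the polymerase favors
#' the natural substrate.
#'
#' @param eff_natural,eff_analog incorporation efficiencies in 1/(uM s),
#'   both `> 0`.
#' @return dimensionless discrimination factor.
#' @export
discrimination_factor <- function(eff_natural, eff_analog) {
  if (any(eff_natural <= 0) || any(eff_analog <= 0)) {
    stop("efficiencies must be > 0", call. = FALSE)
  }
  eff_natural / eff_analog
}
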