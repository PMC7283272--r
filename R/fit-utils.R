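#' Fit-failure result
#'
#' Nonlinear fits that do not converge return a first-class failure object
#' instead of raising, so batch workflows (e.g. fitting every concentration of
#' a titration) can proceed and report which curves failed.
#'
#' @param stage character, which operation failed (e.g. `"fit_burst"`).
#' @param message diagnostic message from the optimizer.
#' @param data optional data that was being fit, kept for inspection.
#' @return An object of class `fit_failure`.
#' @export
fit_failure <- function(stage, message, data = NULL) {
  structure(
    list(stage = stage, message = message, data = data),
    class = "fit_failure"
  )
}

#' Test whether a fit result is a failure
#' @param x object returned by a fitting function.
#' @return logical.
#' @export
is_fit_failure <- function(x) inherits(x, "fit_failure")

#' @export
print.fit_failure <- function(x, ...) {
  cat("<fit failure> in", x$stage, "\n  ", x$message, "\n")
  invisible(x)
}

# Shared Levenberg-Marquardt wrapper. Returns the nlsLM object or a
# fit_failure; never raises for optimizer problems. Bounds default to >= 0 for
# every parameter (rates, amplitudes and binding constants are physical
# quantities), no upper bound.
lm_fit <- function(formula, data, start, lower = NULL, stage = "fit") {
  if (is.null(lower)) lower <- rep(0, length(start))
  tryCatch(
    minpack.lm::nlsLM(
      formula, data = data, start = start, lower = lower,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-12, ptol = 1e-12
      )
    ),
    error = function(e) fit_failure(stage, conditionMessage(e), data)
  )
}

# One-standard-deviation parameter errors (68.3% confidence convention) from
# the estimated covariance at the optimum.
param_se <- function(fit) {
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(co)) {
    se <- rep(NA_real_, length(stats::coef(fit)))
    names(se) <- names(stats::coef(fit))
    return(se)
  }
  se <- co[, "Std. Error"]
  names(se) <- rownames(co)
  se
}

check_finite <- function(..., .names = NULL) {
  vals <- list(...)
  if (is.null(.names)) .names <- as.character(substitute(list(...)))[-1]
  for (i in seq_along(vals)) {
    if (!all(is.finite(vals[[i]]))) {
      stop("non-finite value in '", .names[[i]], "'", call. = FALSE)
    }
  }
  invisible(TRUE)
}
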