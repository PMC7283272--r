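#' Differential scanning fluorimetry melt curve
#'
#' One well's fluorescence-vs-temperature trace on a uniform temperature grid
#' (typically 0.5 degC steps).
#'
#' @param temperature degrees C, strictly increasing, uniform step; at least
#'   20 points.
#' @param rfu relative fluorescence units, one per temperature.
#' @param well_id,condition metadata labels.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperature, rfu, well_id = "", condition = "") {
  temperature <- as.numeric(temperature)
  rfu <- as.numeric(rfu)
  if (length(temperature) < 20) stop("need at least 20 points", call. = FALSE)
  if (length(rfu) != length(temperature)) {
    stop("temperature and rfu must have equal length", call. = FALSE)
  }
  steps <- diff(temperature)
  if (any(steps <= 0)) {
    stop("temperature must be strictly increasing", call. = FALSE)
  }
  if (max(steps) - min(steps) > 1e-6) {
    stop("temperature step must be uniform", call. = FALSE)
  }
  structure(
    list(data = data.frame(temperature = temperature, rfu = rfu),
         step = mean(steps), well_id = well_id, condition = condition),
    class = "melt_curve"
  )
}

#' @export
print.melt_curve <- function(x, ...) {
  cat("<melt_curve> ", nrow(x$data), " points, ",
      min(x$data$temperature), "-", max(x$data$temperature),
      " degC (step ", x$step, ")",
      if (nzchar(x$well_id)) paste0(", well ", x$well_id), "\n", sep = "")
  invisible(x)
}

#' Smoothed derivative of a melt curve
#'
#' Returns the smoothed negative first derivative `-dRFU/dT` of the
#' fluorescence trace, so that unfolding transitions of an ascending melt
#' curve appear as local minima, matching the convention of
#' instrument-software derivative plots. The derivative is estimated by a
#' Savitzky-Golay filter (centered moving polynomial of order 2,
#' differentiated analytically), which spreads the differencing over the
#' whole window and so suppresses bin-to-bin noise far better than smoothing
#' followed by finite differences; endpoints use the filter's one-sided
#' polynomial fits.
#'
#' @param curve a [melt_curve()].
#' @param smooth_window window in points; odd, `>= 5`, smaller than the
#'   number of points. Default 11 (5.5 degC at the usual 0.5 degC step),
#'   comparable to the width of a protein unfolding transition's derivative
#'   peak, which keeps peak positions unshifted while averaging down
#'   single-bin noise.
#' @param convention `"negative"` (default, minima at transitions) or
#'   `"positive"` for data exported with the opposite sign convention.
#' @return An object of class `derivative_curve`: data frame `temperature`,
#'   `deriv` (RFU per degC) plus the grid step.
#' @export
derivative_curve <- function(curve, smooth_window = 11,
                             convention = c("negative", "positive")) {
  stopifnot(inherits(curve, "melt_curve"))
  convention <- match.arg(convention)
  n <- nrow(curve$data)
  if (smooth_window %% 2 == 0 || smooth_window < 5 || smooth_window >= n) {
    stop("smooth_window must be odd, >= 5 and < number of points",
         call. = FALSE)
  }
  d <- signal::sgolayfilt(curve$data$rfu, p = 2, n = smooth_window,
                          m = 1, ts = curve$step)
  if (convention == "negative") d <- -d
  structure(
    list(data = data.frame(temperature = curve$data$temperature, deriv = d),
         step = curve$step, well_id = curve$well_id,
         condition = curve$condition),
    class = "derivative_curve"
  )
}

# Prominence of a local minimum at index i: walk outward on each side until a
# point lower than the minimum (or the boundary), track the highest value
# reached; prominence is the smaller rise of the two sides.
min_prominence_at <- function(y, i) {
  val <- y[i]
  rise <- c(left = 0, right = 0)
  for (side in c(-1L, 1L)) {
    j <- i
    top <- val
    repeat {
      j <- j + side
      if (j < 1 || j > length(y) || y[j] < val) break
      if (y[j] > top) top <- y[j]
    }
    rise[[if (side < 0) "left" else "right"]] <- top - val
  }
  min(rise)
}

#' Find melting transitions as derivative minima
#'
#' Locates local minima of the `-dRFU/dT` trace and refines each by
#' parabolic interpolation through the three bins around it. A candidate
#' minimum must satisfy two relative criteria, both scaled to the maximum
#' absolute derivative within the search range: its prominence must be at
#' least `min_prominence` of that scale, and its value must be at least that
#' deep below zero (a genuine unfolding transition pulls the trace strongly
#' negative, while noise wiggles hover near the baseline). A flat curve
#' yields an empty result, not an error.
#'
#' @param deriv a [derivative_curve()].
#' @param min_prominence prominence/depth threshold as a fraction of the
#'   maximum absolute derivative in range (default 0.1). Being relative,
#'   extraction is invariant to gain/offset transforms of the raw
#'   fluorescence.
#' @param search_range numeric length 2, degrees C; default `c(25, 90)` to
#'   exclude assay-edge artifacts.
#' @return An object of class `melt_transitions`: data frame `transitions`
#'   with columns `Tm` (degC) and `prominence` (RFU per degC), sorted by Tm.
#' @export
find_melt_transitions <- function(deriv, min_prominence = 0.1,
                                  search_range = c(25, 90)) {
  stopifnot(inherits(deriv, "derivative_curve"))
  d <- deriv$data
  if (search_range[1] < min(d$temperature) - 1e-9 ||
      search_range[2] > max(d$temperature) + 1e-9) {
    stop("search_range must lie within the data", call. = FALSE)
  }
  in_range <- d$temperature >= search_range[1] &
    d$temperature <= search_range[2]
  y <- d$deriv
  scale <- max(abs(y[in_range]))
  out <- data.frame(Tm = numeric(0), prominence = numeric(0))
  if (scale > 0) {
    thr <- min_prominence * scale
    idx <- which(in_range)
    idx <- idx[idx > 1 & idx < length(y)]
    for (i in idx) {
      if (y[i] < y[i - 1] && y[i] <= y[i + 1] && y[i] <= -thr) {
        prom <- min_prominence_at(y, i)
        if (prom >= thr) {
          # parabolic refinement around the minimum bin
          denom <- y[i - 1] - 2 * y[i] + y[i + 1]
          offset <- if (denom > 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
          tm <- d$temperature[i] + offset * deriv$step
          out <- rbind(out, data.frame(Tm = tm, prominence = prom))
        }
      }
    }
  }
  out <- out[order(out$Tm), , drop = FALSE]
  rownames(out) <- NULL
  structure(
    list(transitions = out, summary = NULL,
         well_id = deriv$well_id, condition = deriv$condition),
    class = "melt_transitions"
  )
}

#' @export
print.melt_transitions <- function(x, ...) {
  n <- nrow(x$transitions)
  cat("<melt_transitions> ", n, " transition(s)",
      if (n > 0) paste0(": Tm = ",
                        paste(sprintf("%.2f", x$transitions$Tm),
                              collapse = ", "), " degC"),
      "\n", sep = "")
  if (!is.null(x$summary)) {
    print(x$summary)
  }
  invisible(x)
}

#' Aggregate melting transitions across replicates
#'
#' Matches transitions greedily across replicate wells (transitions within
#' `match_tolerance` of a group's running mean join that group) and reports
#' per-group mean, standard deviation and replicate count. Groups observed in
#' fewer than half the replicates are flagged, which is how a transition
#' present in some wells but absent in others (e.g. a destabilized species)
#' surfaces.
#'
#' @param replicates list of [find_melt_transitions()] results, length >= 1.
#' @param match_tolerance degrees C; transitions closer than this to a group
#'   mean are considered the same transition (default 1.5).
#' @return An object of class `melt_transitions` whose `summary` data frame
#'   has columns `mean_Tm`, `sd_Tm`, `n`, `flagged`.
#' @export
aggregate_transitions <- function(replicates, match_tolerance = 1.5) {
  stopifnot(length(replicates) >= 1,
            all(vapply(replicates, inherits, TRUE, "melt_transitions")))
  groups <- list()  # each: list(tms = numeric, reps = integer)
  for (r in seq_along(replicates)) {
    for (tm in replicates[[r]]$transitions$Tm) {
      placed <- FALSE
      for (g in seq_along(groups)) {
        if (abs(mean(groups[[g]]$tms) - tm) <= match_tolerance) {
          groups[[g]]$tms <- c(groups[[g]]$tms, tm)
          groups[[g]]$reps <- union(groups[[g]]$reps, r)
          placed <- TRUE
          break
        }
      }
      if (!placed) groups[[length(groups) + 1]] <- list(tms = tm, reps = r)
    }
  }
  n_rep <- length(replicates)
  summ <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      mean_Tm = mean(g$tms),
      sd_Tm = if (length(g$tms) > 1) stats::sd(g$tms) else 0,
      n = length(g$reps),
      flagged = length(g$reps) < n_rep / 2
    )
  }))
  if (is.null(summ)) {
    summ <- data.frame(mean_Tm = numeric(0), sd_Tm = numeric(0),
                       n = integer(0), flagged = logical(0))
  }
  summ <- summ[order(summ$mean_Tm), , drop = FALSE]
  rownames(summ) <- NULL
  structure(
    list(
      transitions = data.frame(Tm = summ$mean_Tm,
                               prominence = NA_real_),
      summary = summ, well_id = "", condition = ""
    ),
    class = "melt_transitions"
  )
}

#' Extract melting transitions from a raw melt curve
#'
#' Convenience wrapper: [derivative_curve()] then [find_melt_transitions()].
#'
#' @inheritParams derivative_curve
#' @inheritParams find_melt_transitions
#' @return A `melt_transitions` object.
#' @export
melt_transitions <- function(curve, smooth_window = 11,
                             convention = "negative",
                             min_prominence = 0.1, search_range = c(25, 90)) {
  find_melt_transitions(
    derivative_curve(curve, smooth_window, convention),
    min_prominence = min_prominence, search_range = search_range
  )
}
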