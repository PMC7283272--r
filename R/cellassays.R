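#' Extracellular-flux (OCR) run for one well
#'
#' Ordered oxygen-consumption-rate measurement cycles with their injection
#' phase. The standard protocol measures three basal cycles, injects
#' oligomycin (six cycles), then FCCP (three cycles), then
#' rotenone/antimycin A (three cycles); nonstandard cycle counts are accepted
#' as long as the phase order is respected, since the anchor measurements are
#' resolved from the phase labels rather than hard-coded indices.
#'
#' @param index 1-based measurement cycle indices, strictly increasing.
#' @param phase one of `"basal"`, `"oligomycin"`, `"fccp"`, `"rot_aa"` per
#'   cycle; phases must appear in that order and each must be non-empty.
#' @param value OCR in pmol O2/min per cycle.
#' @param well_id,condition metadata labels.
#' @return An object of class `flux_run`.
#' @export
flux_run <- function(index, phase, value, well_id = "", condition = "") {
  index <- as.integer(index)
  value <- as.numeric(value)
  phase <- as.character(phase)
  phases <- c("basal", "oligomycin", "fccp", "rot_aa")
  if (!all(phase %in% phases)) {
    stop("phase must be one of ", paste(phases, collapse = ", "),
         call. = FALSE)
  }
  if (length(index) != length(phase) || length(index) != length(value)) {
    stop("index, phase and value must have equal length", call. = FALSE)
  }
  if (any(diff(index) <= 0)) {
    stop("index must be strictly increasing", call. = FALSE)
  }
  runs <- rle(phase)$values
  if (!identical(runs, phases[phases %in% phase]) ||
      !setequal(phase, phases)) {
    stop("phases must appear once each in the order basal, oligomycin, ",
         "fccp, rot_aa", call. = FALSE)
  }
  structure(
    list(data = data.frame(index = index, phase = phase, value = value),
         well_id = well_id, condition = condition),
    class = "flux_run"
  )
}

#' @export
print.flux_run <- function(x, ...) {
  counts <- table(factor(x$data$phase,
                         c("basal", "oligomycin", "fccp", "rot_aa")))
  cat("<flux_run> cycles ", paste(counts, collapse = "/"),
      if (nzchar(x$well_id)) paste0(", well ", x$well_id), "\n", sep = "")
  invisible(x)
}

#' Respirometry parameters from an OCR run
#'
#' Derives the eight standard respiration parameters from the four anchor
#' measurements: M3 (last basal cycle, immediately before oligomycin), M9
#' (last oligomycin cycle), M10 (first FCCP cycle) and M13 (first
#' rotenone/antimycin A cycle, the non-mitochondrial baseline):
#' \itemize{
#'   \item basal = M3 - M13
#'   \item proton_leak = M9 - M13
#'   \item atp_linked = basal - proton_leak
#'   \item maximal = M10 - M13
#'   \item spare_capacity = maximal - basal
#'   \item coupling_efficiency = 100 * atp_linked / basal (percent)
#'   \item respiratory_control_ratio = maximal / proton_leak
#'   \item atp_over_maximal = atp_linked / maximal
#' }
#' Differences are always reported; a ratio whose denominator is <= 0 is
#' reported as `NA` and listed in `undefined_ratios`. Negative differences
#' are retained, not clipped (clipping would bias spare capacity), and noted
#' in `negative_rates`.
#'
#' @param run a [flux_run()].
#' @return An object of class `respiration_parameters`.
#' @export
respiration_parameters <- function(run) {
  stopifnot(inherits(run, "flux_run"))
  d <- run$data
  m3 <- d$value[max(which(d$phase == "basal"))]
  m9 <- d$value[max(which(d$phase == "oligomycin"))]
  m10 <- d$value[min(which(d$phase == "fccp"))]
  m13 <- d$value[min(which(d$phase == "rot_aa"))]
  basal <- m3 - m13
  proton_leak <- m9 - m13
  atp_linked <- basal - proton_leak
  maximal <- m10 - m13
  spare_capacity <- maximal - basal
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  coupling_efficiency <- ratio(100 * atp_linked, basal)
  respiratory_control_ratio <- ratio(maximal, proton_leak)
  atp_over_maximal <- ratio(atp_linked, maximal)
  undefined <- c("coupling_efficiency", "respiratory_control_ratio",
                 "atp_over_maximal")[c(basal <= 0, proton_leak <= 0,
                                       maximal <= 0)]
  diffs <- c(basal = basal, proton_leak = proton_leak,
             atp_linked = atp_linked, maximal = maximal,
             spare_capacity = spare_capacity)
  structure(
    list(
      basal = basal, proton_leak = proton_leak, atp_linked = atp_linked,
      maximal = maximal, spare_capacity = spare_capacity,
      coupling_efficiency = coupling_efficiency,
      respiratory_control_ratio = respiratory_control_ratio,
      atp_over_maximal = atp_over_maximal,
      anchors = c(M3 = m3, M9 = m9, M10 = m10, M13 = m13),
      undefined_ratios = undefined,
      negative_rates = names(diffs)[diffs < 0],
      well_id = run$well_id, condition = run$condition
    ),
    class = "respiration_parameters"
  )
}

#' @export
print.respiration_parameters <- function(x, ...) {
  cat("<respiration_parameters> (pmol O2/min)\n")
  cat(sprintf("  basal %.4g, proton leak %.4g, ATP-linked %.4g, maximal %.4g, spare %.4g\n",
              x$basal, x$proton_leak, x$atp_linked, x$maximal,
              x$spare_capacity))
  cat(sprintf("  coupling %.4g%%, RCR %.4g, ATP/maximal %.4g\n",
              x$coupling_efficiency, x$respiratory_control_ratio,
              x$atp_over_maximal))
  if (length(x$undefined_ratios)) {
    cat("  undefined ratios:", paste(x$undefined_ratios, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Relative mitochondrial DNA content from a qPCR CT pair
#'
#' `2 * 2^(ct_nuc - ct_mt)`: the delta-CT between a nuclear single-copy
#' target (e.g. B2-microglobulin) and a mitochondrial target (e.g.
#' tRNA-Leu(UUR)), on the copy scale, times two for the diploid nuclear
#' genome. Strictly increasing in `ct_nuc`, strictly decreasing in `ct_mt`.
#'
#' @param ct_mt,ct_nuc threshold cycles in (0, 50], vectorized.
#' @return relative mtDNA content (dimensionless).
#' @export
relative_mtdna <- function(ct_mt, ct_nuc) {
  if (any(ct_mt <= 0 | ct_mt > 50) || any(ct_nuc <= 0 | ct_nuc > 50)) {
    stop("CT values must be in (0, 50]", call. = FALSE)
  }
  2 * 2^(ct_nuc - ct_mt)
}

#' Relative mtDNA content per sample with technical replicates
#'
#' Technical replicate CT values are averaged on the CT scale before the
#' `2 * 2^dCT` transform (equivalent to a geometric mean on the copy scale),
#' then optionally normalized to an untreated control sample.
#'
#' @param data data frame with columns `sample`, `ct_mt`, `ct_nuc` (one row
#'   per technical replicate).
#' @param control optional sample label; when given, contents are divided by
#'   the control sample's content.
#' @return data frame with columns `sample`, `content` and, when `control`
#'   is given, `relative_to_control`.
#' @export
summarize_mtdna <- function(data, control = NULL) {
  stopifnot(all(c("sample", "ct_mt", "ct_nuc") %in% names(data)))
  ag <- stats::aggregate(cbind(ct_mt, ct_nuc) ~ sample, data = data, FUN = mean)
  ag$content <- relative_mtdna(ag$ct_mt, ag$ct_nuc)
  out <- ag[, c("sample", "content")]
  if (!is.null(control)) {
    if (!control %in% out$sample) {
      stop("control sample '", control, "' not present", call. = FALSE)
    }
    out$relative_to_control <- normalize_to_control(
      out$content, out$content[out$sample == control])
  }
  out
}

#' Normalize values to the mean of a control group
#'
#' @param values numeric vector.
#' @param control_values numeric vector of control measurements; non-empty,
#'   with mean `> 0`.
#' @return `values / mean(control_values)`.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0 || mean(control_values) <= 0) {
    stop("control values must be non-empty with positive mean",
         call. = FALSE)
  }
  values / mean(control_values)
}

#' Normalize a proliferation (MTT) plate
#'
#' Subtracts the mean of the no-cell background wells from every well, then
#' expresses each condition as a fraction of the untreated control mean.
#' Returns per-condition mean, SD and n of that fraction.
#'
#' @param plate data frame with columns `well`, `condition`, `absorbance`
#'   (590 nm).
#' @param control condition label of the untreated cells.
#' @param background condition label of the no-cell background wells.
#' @return data frame with columns `condition`, `mean_fraction`, `sd`, `n`.
#' @export
normalize_mtt <- function(plate, control = "untreated",
                          background = "background") {
  stopifnot(all(c("well", "condition", "absorbance") %in% names(plate)))
  if (!background %in% plate$condition) {
    stop("no background wells labeled '", background, "'", call. = FALSE)
  }
  if (!control %in% plate$condition) {
    stop("no control wells labeled '", control, "'", call. = FALSE)
  }
  bg <- mean(plate$absorbance[plate$condition == background])
  corrected <- plate$absorbance - bg
  ctrl_mean <- mean(corrected[plate$condition == control])
  if (ctrl_mean <= 0) {
    stop("untreated control mean is <= 0 after background subtraction",
         call. = FALSE)
  }
  frac <- corrected / ctrl_mean
  keep <- plate$condition != background
  ag <- stats::aggregate(
    frac[keep],
    by = list(condition = plate$condition[keep]),
    FUN = function(v) c(mean = mean(v),
                        sd = if (length(v) > 1) stats::sd(v) else 0,
                        n = length(v))
  )
  out <- data.frame(
    condition = ag$condition,
    mean_fraction = ag$x[, "mean"],
    sd = ag$x[, "sd"],
    n = as.integer(ag$x[, "n"])
  )
  out[order(out$condition), , drop = FALSE]
}
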