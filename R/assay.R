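## Exactly-specified assay arithmetic: complex-IV respiration, kinetic
## background subtraction, COX-1 fold change, and the fluorescence-ratio
## exogenous-mitochondria estimator.

#' Complex IV-dependent respiration
#'
#' The azide-insensitive component of TMPD/ascorbate-driven oxygen
#' consumption: the OCR measured with the complex-IV substrate pair
#' minus the residual OCR under sodium-azide inhibition. A negative result
#' (substrate signal below the inhibited baseline, e.g. instrument drift)
#' is returned as-is with a warning, never clamped.
#'
#' @param ocr_tmpd_asc OCR with TMPD/ascorbate (pmol O2/min).
#' @param ocr_azide OCR under sodium azide (pmol O2/min).
#' @return Complex IV-dependent respiration (pmol O2/min).
#' @export
civ_respiration <- function(ocr_tmpd_asc, ocr_azide) {
  stopifnot(is.finite(ocr_tmpd_asc), is.finite(ocr_azide))
  out <- ocr_tmpd_asc - ocr_azide
  if (out < 0)
    warning("low signal: TMPD/ASC OCR below azide-inhibited OCR")
  out
}

#' Background-subtract a kinetic absorbance trace
#'
#' Pointwise subtraction of a matched no-substrate background trace from a
#' kinetic OD-590 reading. Negative corrected values are flagged with a
#' warning but retained.
#'
#' @param absorbance Numeric OD readings per timepoint.
#' @param background Matched no-substrate trace (same length).
#' @param timepoints Optional strictly increasing timepoints (minutes);
#'   validated when supplied.
#' @return Numeric corrected absorbances.
#' @export
background_subtract <- function(absorbance, background, timepoints = NULL) {
  if (length(absorbance) != length(background))
    stop("shape error: absorbance and background lengths differ")
  if (!is.null(timepoints)) {
    if (length(timepoints) != length(absorbance))
      stop("shape error: timepoints length differs from absorbance")
    if (any(diff(timepoints) <= 0))
      stop("timepoints must be strictly increasing")
  }
  out <- absorbance - background
  if (any(out < 0))
    warning(sum(out < 0), " corrected value(s) below zero")
  out
}

#' COX-1 fold change normalized to cell number
#'
#' Each condition's COX-1 ELISA signal is first normalized to its Janus
#' green staining (a cell-number proxy); the fold change is the ratio of
#' the normalized signals, treated over control.
#'
#' @param treated_cox1,treated_janus Treated-condition COX-1 and Janus OD.
#' @param control_cox1,control_janus Control-condition COX-1 and Janus OD.
#' @return Fold change (dimensionless).
#' @export
cox1_fold_change <- function(treated_cox1, treated_janus,
                             control_cox1, control_janus) {
  if (treated_janus <= 0 || control_janus <= 0)
    stop("invalid parameter: Janus green signal must be > 0")
  if (control_cox1 <= 0)
    stop("invalid parameter: control COX-1 signal must be > 0")
  (treated_cox1 / treated_janus) / (control_cox1 / control_janus)
}

#' Exogenous fraction of mitochondrial content from fluorescence
#'
#' Estimates what share of a recipient cell's mitochondrial content is
#' exogenous from a two-channel panel: the Dendra2 channel reports labeled
#' (exogenous) mitochondria, the MitoTracker channel total mitochondria.
#' The unknown channel gain is calibrated as the median Dendra2/MitoTracker
#' ratio over fully-exogenous control cells; each recipient cell's
#' fraction is then `(dendra2 / gain) / mitotracker`, and the estimate is
#' 100 x the median across recipient cells (medians are robust to the
#' lognormal tails such panels show), with a percentile bootstrap
#' confidence interval.
#'
#' @param panel A `fluorescence_panel` data.frame (needs >= 10 calibration
#'   and >= 10 recipient cells).
#' @param n_boot Bootstrap replicates for the CI (default 200).
#' @param conf_level CI level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `exo_fraction` with fields `percent`, `ci`,
#'   `n_cells`, `n_calibration`, `gain`.
#' @export
exo_mito_fraction <- function(panel, n_boot = 200L, conf_level = 0.95,
                              seed = 1L) {
  stopifnot(is.data.frame(panel))
  if (nrow(panel) == 0L) stop("empty fluorescence panel")
  cal <- panel[panel$is_calibration, , drop = FALSE]
  rec <- panel[!panel$is_calibration, , drop = FALSE]
  if (nrow(cal) == 0L)
    stop("calibration error: no fully-exogenous control cells in panel")
  if (nrow(cal) < 10L || nrow(rec) < 10L)
    stop("calibration error: need >= 10 calibration and >= 10 recipient cells")
  if (any(panel$dendra2_intensity < 0) ||
      any(panel$mitotracker_intensity <= 0))
    stop("invalid intensities: need dendra2 >= 0 and mitotracker > 0")
  gain <- stats::median(cal$dendra2_intensity / cal$mitotracker_intensity)
  if (gain <= 0) stop("calibration error: non-positive estimated gain")
  frac <- (rec$dendra2_intensity / gain) / rec$mitotracker_intensity
  pct <- 100 * stats::median(frac)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      g <- stats::median(sample(cal$dendra2_intensity /
                                  cal$mitotracker_intensity,
                                nrow(cal), replace = TRUE))
      100 * stats::median(sample(frac * gain / g, nrow(rec),
                                 replace = TRUE))
    }, numeric(1L))
  })
  alpha <- (1 - conf_level) / 2
  structure(list(percent = pct,
                 ci = unname(stats::quantile(boots, c(alpha, 1 - alpha))),
                 conf_level = conf_level,
                 n_cells = nrow(rec), n_calibration = nrow(cal),
                 gain = gain),
            class = "exo_fraction")
}

#' @export
print.exo_fraction <- function(x, ...) {
  cat(sprintf(
    "Exogenous mitochondrial content: %.2f%% of total (%.0f%% CI %.2f-%.2f)\n",
    x$percent, 100 * x$conf_level, x$ci[1L], x$ci[2L]))
  cat(sprintf("  %d recipient cells, %d calibration cells, gain %.3f\n",
              x$n_cells, x$n_calibration, x$gain))
  invisible(x)
}
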