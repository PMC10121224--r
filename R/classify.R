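# Curve-quality classification.
#
# A well-behaved concentration-response curve (i) sits near zero at low
# concentration, (ii) rises with concentration, (iii) has its inflection
# (AC50) inside the tested range, and (iv) reaches a well-defined plateau
# at the top of the range. These qualitative criteria are operationalized
# with explicit numeric thresholds, all configurable and recorded with the
# results.

CURVE_CLASSES <- c("ACTIVE_FULL", "ACTIVE_PARTIAL", "INCONCLUSIVE", "INACTIVE")

#' Thresholds for curve classification
#'
#' @param baseline_max Maximum `|A0|` (percent) for the near-zero-baseline
#'   criterion.
#' @param amplitude_min Minimum rise `Ainf - A0` (percent) for a curve to
#'   count as responding.
#' @param plateau_max Maximum gap (percent) between the response at the top
#'   tested concentration and `Ainf` for a well-defined plateau.
#' @param r2_min Minimum coefficient of determination.
#' @return Named list of class `classify_thresholds`.
#' @export
classify_thresholds <- function(baseline_max = 20, amplitude_min = 20,
                                plateau_max = 10, r2_min = 0.7) {
  stopifnot(baseline_max >= 0, amplitude_min >= 0, plateau_max >= 0,
            r2_min <= 1)
  structure(list(baseline_max = baseline_max, amplitude_min = amplitude_min,
                 plateau_max = plateau_max, r2_min = r2_min),
            class = "classify_thresholds")
}

#' Classify a fitted concentration-response curve
#'
#' Evaluates the four curve-behavior criteria plus fit quality and data
#' sufficiency, and maps the failure pattern to one of four classes:
#'
#' * `ACTIVE_FULL` — every criterion passes;
#' * `ACTIVE_PARTIAL` — the only failures are a missing top plateau and/or
#'   a midpoint above the tested range (a real but unsaturated response);
#' * `INACTIVE` — the fitted amplitude `|Ainf - A0|` is below
#'   `amplitude_min`, or the curve clearly decreases (inhibition-shaped
#'   responses are not what this screen calls active);
#' * `INCONCLUSIVE` — anything else (unconverged, too few concentrations,
#'   poor fit, aberrant baseline, midpoint below the range).
#'
#' @param fit A `hill_fit` from [fit_hill()].
#' @param points Optional data frame `conc, score`; defaults to the data
#'   stored in the fit (used for the tested concentration range).
#' @param thresholds A [classify_thresholds()].
#' @return List of class `curve_class` with `value` and `reasons`
#'   (character vector of failed-criterion tags among `BASELINE`,
#'   `MONOTONE`, `INFLECTION`, `PLATEAU`, `FIT_QUALITY`, `DATA`).
#' @export
classify_curve <- function(fit, points = fit$data,
                           thresholds = classify_thresholds()) {
  stopifnot(inherits(fit, "hill_fit"))
  reasons <- character()
  if (fit$n_conc < 4L || !fit$converged) {
    return(structure(list(value = "INCONCLUSIVE", reasons = "DATA"),
                     class = "curve_class"))
  }
  p <- fit$params
  lg_range <- range(log10(points$conc))
  amp <- p$ainf - p$a0
  if (abs(p$a0) > thresholds$baseline_max) reasons <- c(reasons, "BASELINE")
  if (amp < thresholds$amplitude_min) reasons <- c(reasons, "MONOTONE")
  above_range <- p$log_ac50 > lg_range[2]
  below_range <- p$log_ac50 < lg_range[1]
  if (above_range || below_range) reasons <- c(reasons, "INFLECTION")
  top <- hill_response(p, 10^lg_range[2])
  if (abs(top - p$ainf) > thresholds$plateau_max) reasons <- c(reasons, "PLATEAU")
  if (!is.na(fit$r2) && fit$r2 < thresholds$r2_min) {
    reasons <- c(reasons, "FIT_QUALITY")
  }
  value <- if (!length(reasons)) {
    "ACTIVE_FULL"
  } else if ("MONOTONE" %in% reasons &&
             (abs(amp) < thresholds$amplitude_min ||
              amp <= -thresholds$amplitude_min)) {
    "INACTIVE"
  } else if (all(reasons %in% c("PLATEAU", "INFLECTION")) && !below_range) {
    "ACTIVE_PARTIAL"
  } else {
    "INCONCLUSIVE"
  }
  structure(list(value = value, reasons = reasons), class = "curve_class")
}
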