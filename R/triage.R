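# Hit triage: combine each compound's efficacy, toxicity and fluorescence
# curve fits into a verdict mirroring the screen funnel — primary activity,
# removal of toxic and autofluorescent false positives, then ranking by
# efficacy.
#
# A desirable compound has a potent, high-amplitude efficacy curve and
# counter-activities that are much less potent:
#
#   EC50_toxicity     / EC50_efficacy >> 1
#   EC50_fluorescence / EC50_efficacy >> 1
#   Ainf_efficacy high
#
# ">> 1" is operationalized as a selectivity ratio of at least `ratio_min`
# (default 10, the conventional selectivity-index margin; a permissive
# preset uses 3). A counter-activity whose curve is classed INACTIVE
# contributes an infinite ratio, i.e. passes.

VERDICTS <- c("HIT", "TOXIC", "AUTOFLUORESCENT", "INACTIVE", "INCONCLUSIVE")

#' Thresholds for hit triage
#'
#' @param ratio_min Minimum selectivity ratio (counter-activity EC50 over
#'   efficacy EC50) for a clean hit.
#' @param ainf_min Minimum fitted efficacy plateau, percent of the WT-RD16
#'   window.
#' @param preset `"default"` (ratio 10) or `"permissive"` (ratio 3).
#' @return Named list of class `triage_thresholds`.
#' @export
triage_thresholds <- function(ratio_min = NULL, ainf_min = 30,
                              preset = c("default", "permissive")) {
  preset <- match.arg(preset)
  ratio_min <- ratio_min %||% switch(preset, default = 10, permissive = 3)
  stopifnot(ratio_min > 0, ainf_min >= 0)
  structure(list(ratio_min = ratio_min, ainf_min = ainf_min),
            class = "triage_thresholds")
}

# A counter-activity contributes a finite selectivity ratio when it
# registered a response: its curve is classed active, or the raw data rose
# by at least the registration margin between the bottom and top of the
# tested range (model-free, so a counter signal whose fit is pathological
# still cannot clear a compound). Flat counter assays pass with an
# infinite ratio; a registering counter with no converged fit yields NA,
# which triage treats as uninterpretable.
counter_ratio <- function(counter_row, eff_ac50, amplitude_min = 20) {
  if (is.null(counter_row) || nrow(counter_row) == 0) return(Inf)
  # the counter response must actually reach a meaningful level at the top
  # of the tested range; drifting baselines that never get there are not
  # toxicity or autofluorescence
  if (!isTRUE(counter_row$resp_high >= amplitude_min)) return(Inf)
  registered <- isTRUE(counter_row$resp_high - counter_row$resp_low >=
                         amplitude_min)
  active <- isTRUE(counter_row$converged) &&
    counter_row$curve_class %in% c("ACTIVE_FULL", "ACTIVE_PARTIAL")
  if (!active && !registered) return(Inf)
  if (!isTRUE(counter_row$converged)) return(NA_real_)
  10^counter_row$log_ac50 / eff_ac50
}

#' Triage one compound from its three curve fits
#'
#' @param fits One-compound slice of a [fit_campaign()] table (rows for
#'   score types `EFFICACY`, optionally `TOXICITY` and `FLUORESCENCE`).
#' @param thresholds A [triage_thresholds()].
#' @return One-row tibble: `compound_id, ratio_tox, ratio_fluor,`
#'   `ainf_efficacy, ac50_efficacy, efficacy_class, verdict`.
#' @export
triage_compound <- function(fits, thresholds = triage_thresholds()) {
  fits <- as_tibble(fits)
  if (anyDuplicated(fits$score_type)) {
    abort(paste0("compound ", fits$compound_id[1],
                 ": duplicate fits per score type"))
  }
  eff <- fits[fits$score_type == "EFFICACY", ]
  tox <- fits[fits$score_type == "TOXICITY", ]
  fluor <- fits[fits$score_type == "FLUORESCENCE", ]
  cid <- fits$compound_id[1]
  row <- tibble(compound_id = cid, ratio_tox = NA_real_,
                ratio_fluor = NA_real_, ainf_efficacy = NA_real_,
                ac50_efficacy = NA_real_,
                efficacy_class = NA_character_, verdict = NA_character_)
  if (nrow(eff) == 0 || eff$curve_class == "INCONCLUSIVE") {
    row$efficacy_class <- if (nrow(eff)) eff$curve_class else NA_character_
    row$verdict <- "INCONCLUSIVE"
    return(row)
  }
  row$efficacy_class <- eff$curve_class
  if (eff$curve_class == "INACTIVE") {
    row$verdict <- "INACTIVE"
    return(row)
  }
  # active efficacy curve from here on
  eff_ac50 <- 10^eff$log_ac50
  row$ainf_efficacy <- eff$ainf
  row$ac50_efficacy <- eff_ac50
  row$ratio_tox <- counter_ratio(tox, eff_ac50)
  row$ratio_fluor <- counter_ratio(fluor, eff_ac50)
  row$verdict <- if (eff$ainf < thresholds$ainf_min) {
    "INACTIVE"                      # real but too-shallow rescue
  } else if (is.na(row$ratio_tox) || is.na(row$ratio_fluor)) {
    "INCONCLUSIVE"                  # counter registered but unfittable
  } else if (row$ratio_tox < thresholds$ratio_min) {
    "TOXIC"                         # toxicity checked before fluorescence
  } else if (row$ratio_fluor < thresholds$ratio_min) {
    "AUTOFLUORESCENT"
  } else {
    "HIT"
  }
  row
}

#' Triage a whole campaign and rank its hits
#'
#' @param fits A [fit_campaign()] table.
#' @param thresholds A [triage_thresholds()].
#' @return List with `verdicts` (one row per compound, ordered by
#'   compound_id) and `hits` (verdict == HIT, ranked by fitted efficacy
#'   plateau descending, then efficacy AC50 ascending, then compound_id).
#' @examples
#' sim <- simulate_campaign(sim_config(n_compounds = 40, seed = 2))
#' scores <- normalize_campaign(sim$plates)
#' fits <- fit_campaign(scores)
#' triage_campaign(fits)$hits
#' @export
triage_campaign <- function(fits, thresholds = triage_thresholds()) {
  verdicts <- split(as_tibble(fits), fits$compound_id) %>%
    purrr::map(triage_compound, thresholds = thresholds) %>%
    bind_rows() %>%
    arrange(.data$compound_id)
  hits <- verdicts %>%
    filter(.data$verdict == "HIT") %>%
    arrange(desc(.data$ainf_efficacy), .data$ac50_efficacy, .data$compound_id)
  list(verdicts = verdicts, hits = hits)
}
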