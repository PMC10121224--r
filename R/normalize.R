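# Intra-plate percent normalization.
#
# Raw intensities become three percent scores anchored on each plate's own
# DMSO controls:
#
#   efficacy     = 100 * (GFP_c  - mean GFP RD16+DMSO) /
#                        (mean GFP WT+DMSO - mean GFP RD16+DMSO)
#   toxicity     = -100 * (DAPI_c - mean DAPI RD16+DMSO) / mean DAPI RD16+DMSO
#   fluorescence = 100 * (GFP_parental_c - mean GFP Parental+DMSO) /
#                        (mean GFP WT+DMSO - mean GFP Parental+DMSO)
#
# so a vehicle-level well scores 0 and a WT-level well scores 100 (efficacy
# and fluorescence), and full loss of nuclei signal scores 100 (toxicity).
# Scores are deliberately not clipped to [0, 100]: noise and super-WT
# rescue legitimately exceed the anchors and clipping would bias curve fits.

#' Per-plate DMSO control statistics
#'
#' Arithmetic means of the unmasked DMSO control wells, per plate and cell
#' line. Counter-screen plates, which carry no WT wells, borrow the WT+DMSO
#' GFP mean from the other plates of the same replicate (the campaign's
#' designated positive-control wells).
#'
#' @param plates A [plate_set()] tibble.
#' @param trim Trim fraction for the control mean (default 0, the plain
#'   arithmetic mean).
#' @return Tibble with one row per plate: group means, group sizes, and the
#'   plate's assay kind and replicate.
#' @export
control_stats <- function(plates, trim = 0) {
  validate_wells(plates)
  ctrl <- plates %>% filter(.data$treatment == "DMSO", !.data$masked)
  agg <- ctrl %>%
    group_by(.data$plate_id, .data$assay_kind, .data$replicate, .data$cell_line) %>%
    summarise(mean_gfp = mean(.data$gfp, trim = trim),
              mean_dapi = mean(.data$dapi, trim = trim),
              n = dplyr::n(), .groups = "drop")
  wide <- tidyr::pivot_wider(
    agg, id_cols = c("plate_id", "assay_kind", "replicate"),
    names_from = "cell_line",
    values_from = c("mean_gfp", "mean_dapi", "n"),
    values_fill = list(n = 0L))
  for (col in c("mean_gfp_WT", "mean_gfp_RD16", "mean_dapi_RD16",
                "mean_gfp_PARENTAL", "n_WT", "n_RD16", "n_PARENTAL")) {
    if (!col %in% names(wide)) {
      wide[[col]] <- if (startsWith(col, "n_")) 0L else NA_real_
    }
  }
  # replicate-level WT mean backs plates with no WT wells of their own
  wt_pool <- ctrl %>%
    filter(.data$cell_line == "WT") %>%
    group_by(.data$replicate) %>%
    summarise(pool_wt = mean(.data$gfp, trim = trim), .groups = "drop")
  wide <- left_join(wide, wt_pool, by = "replicate") %>%
    mutate(mean_gfp_wt_dmso = ifelse(.data$n_WT > 0, .data$mean_gfp_WT,
                                     .data$pool_wt)) %>%
    rename(mean_gfp_rd16_dmso = "mean_gfp_RD16",
           mean_dapi_rd16_dmso = "mean_dapi_RD16",
           mean_gfp_parental_dmso = "mean_gfp_PARENTAL",
           n_wt = "n_WT", n_rd16 = "n_RD16", n_parental = "n_PARENTAL") %>%
    select("plate_id", "assay_kind", "replicate", "mean_gfp_wt_dmso",
           "mean_gfp_rd16_dmso", "mean_dapi_rd16_dmso",
           "mean_gfp_parental_dmso", "n_wt", "n_rd16", "n_parental")
  bad <- wide$assay_kind == "DISEASE_ASSAY" &
    (wide$n_rd16 == 0 | is.na(wide$mean_gfp_wt_dmso))
  if (any(bad)) {
    abort(paste0("plate ", wide$plate_id[bad][1],
                 ": no unmasked DMSO control wells for a required group ",
                 "(RD16 on-plate, WT on-plate or in the same replicate)"))
  }
  degen <- wide$assay_kind == "DISEASE_ASSAY" &
    wide$mean_gfp_wt_dmso <= wide$mean_gfp_rd16_dmso
  if (any(degen, na.rm = TRUE)) {
    abort(paste0("plate ", wide$plate_id[degen][1],
                 ": degenerate normalization window ",
                 "(WT+DMSO GFP mean <= RD16+DMSO GFP mean)"))
  }
  zero_dapi <- wide$assay_kind == "DISEASE_ASSAY" & wide$n_rd16 > 0 &
    wide$mean_dapi_rd16_dmso <= 0
  if (any(zero_dapi, na.rm = TRUE)) {
    abort(paste0("plate ", wide$plate_id[zero_dapi][1],
                 ": RD16+DMSO DAPI control mean is zero"))
  }
  wide
}

#' Efficacy percent score
#'
#' Percent position of a disease-line compound well's GFP intensity within
#' the WT-minus-disease control window: 0 at the RD16+DMSO mean, 100 at the
#' WT+DMSO mean.
#'
#' @param gfp_c GFP intensity (vectorized) of RD16 compound wells.
#' @param stats A one-row slice of [control_stats()] for the well's plate
#'   (any list with `mean_gfp_rd16_dmso` and `mean_gfp_wt_dmso`).
#' @return Percent efficacy.
#' @examples
#' efficacy_score(80, list(mean_gfp_rd16_dmso = 40, mean_gfp_wt_dmso = 120))
#' @export
efficacy_score <- function(gfp_c, stats) {
  window <- stats$mean_gfp_wt_dmso - stats$mean_gfp_rd16_dmso
  if (any(!is.finite(window)) || any(window <= 0)) {
    abort("degenerate efficacy window: WT+DMSO mean must exceed RD16+DMSO mean")
  }
  100 * (gfp_c - stats$mean_gfp_rd16_dmso) / window
}

#' Toxicity percent score
#'
#' Percent loss of nuclei (DAPI) signal relative to vehicle-treated disease
#' cells; cell loss is positive, growth negative.
#'
#' @param dapi_c DAPI intensity (vectorized) of RD16 compound wells.
#' @param stats A one-row slice of [control_stats()] (needs
#'   `mean_dapi_rd16_dmso` > 0).
#' @return Percent toxicity.
#' @examples
#' toxicity_score(50, list(mean_dapi_rd16_dmso = 100))
#' @export
toxicity_score <- function(dapi_c, stats) {
  m <- stats$mean_dapi_rd16_dmso
  if (any(!is.finite(m)) || any(m <= 0)) {
    abort("RD16+DMSO DAPI control mean must be positive")
  }
  # + 0 normalizes IEEE negative zero for wells exactly at the control mean
  -100 * (dapi_c - m) / m + 0
}

#' Autofluorescence percent score
#'
#' Compound fluorescence measured in the GFP-negative parental line, on the
#' same percent scale as efficacy: 0 at the Parental+DMSO mean, 100 when a
#' parental well is as bright as the WT+DMSO mean.
#'
#' @param gfp_parental_c GFP intensity (vectorized) of parental compound wells.
#' @param stats A one-row slice of [control_stats()] (needs
#'   `mean_gfp_parental_dmso` and a borrowed `mean_gfp_wt_dmso`).
#' @return Percent fluorescence.
#' @export
fluorescence_score <- function(gfp_parental_c, stats) {
  window <- stats$mean_gfp_wt_dmso - stats$mean_gfp_parental_dmso
  if (any(!is.finite(window)) || any(window <= 0)) {
    abort("degenerate fluorescence window: WT mean must exceed parental mean")
  }
  100 * (gfp_parental_c - stats$mean_gfp_parental_dmso) / window
}

#' Normalize a whole campaign to score triples
#'
#' Applies the three percent normalizations to every unmasked compound
#' well, using each plate's own control statistics, and joins the disease
#' assay (efficacy, toxicity) to the counter-screen (fluorescence) by
#' compound, concentration and replicate. Apply QC masking first.
#'
#' @param plates A [plate_set()] tibble (disease plates, optionally
#'   counter-screen plates).
#' @param stats Optional precomputed [control_stats()].
#' @return Tibble `compound_id, concentration_molar, replicate, efficacy,`
#'   `toxicity, fluorescence`, ordered by compound then descending
#'   concentration. Fluorescence is `NA` where no counter-screen well
#'   exists; a compound seen only in the counter-screen yields a row with
#'   `efficacy = NA` and a warning.
#' @export
normalize_campaign <- function(plates, stats = control_stats(plates)) {
  validate_wells(plates)
  cmp <- plates %>%
    filter(.data$treatment == "COMPOUND", !.data$masked) %>%
    left_join(stats %>% select(-"assay_kind", -"replicate"), by = "plate_id")
  dis <- cmp %>% filter(.data$assay_kind == "DISEASE_ASSAY")
  ctr <- cmp %>% filter(.data$assay_kind == "COUNTER_SCREEN")
  dis_scores <- dis %>%
    mutate(efficacy = efficacy_score(.data$gfp, dis),
           toxicity = toxicity_score(.data$dapi, dis)) %>%
    select("compound_id", concentration_molar = "concentration",
           replicate = "replicate", "efficacy", "toxicity")
  out <- dis_scores
  if (nrow(ctr)) {
    ok <- is.finite(ctr$mean_gfp_parental_dmso) &
      is.finite(ctr$mean_gfp_wt_dmso) &
      ctr$mean_gfp_wt_dmso > ctr$mean_gfp_parental_dmso
    if (!all(ok)) {
      warn("counter-screen plate lacks usable Parental/WT controls; fluorescence set to NA for its wells")
      ctr <- ctr[ok, ]
    }
    ctr_scores <- ctr %>%
      mutate(fluorescence = fluorescence_score(.data$gfp, ctr)) %>%
      select("compound_id", concentration_molar = "concentration",
             replicate = "replicate", "fluorescence")
    out <- dplyr::full_join(
      dis_scores, ctr_scores,
      by = c("compound_id", "concentration_molar", "replicate"))
    orphans <- is.na(out$efficacy) & !is.na(out$fluorescence)
    if (any(orphans)) {
      warn(paste0(sum(orphans), " counter-screen observation(s) have no ",
                  "disease-assay counterpart; efficacy left NA and excluded ",
                  "from fitting"))
    }
  } else {
    out$fluorescence <- NA_real_
  }
  out %>%
    arrange(.data$compound_id, desc(.data$concentration_molar), .data$replicate)
}
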