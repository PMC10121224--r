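# Ground-truth-labelled synthetic screening campaigns.
#
# The generator emulates the statistical structure the analysis assumes:
# a disease line (RD16) with reduced viability and reduced reporter signal
# relative to WT, a GFP-negative parental counter-screen line, compound
# effects entering through Hill concentration-response terms, multiplicative
# lognormal well noise, and additive plate gradients / edge offsets.

#' Configuration for the synthetic screen generator
#'
#' Defaults encode the disease phenotype the screen is built around: the
#' disease line retains `rd16_viability_fraction` (default 0.5, i.e. 50%
#' lower viability) of WT nuclei signal and `rd16_gfp_fraction` (default
#' 0.4, i.e. 60% fewer reporter-positive rods) of WT reporter signal.
#'
#' @param n_compounds Number of compounds in the campaign.
#' @param class_probabilities Named probabilities over the six generative
#'   compound classes `inactive`, `efficacious`, `toxic`, `autofluorescent`,
#'   `efficacious_toxic`, `efficacious_autofluorescent`; must sum to 1.
#' @param wt_gfp_mean,wt_dapi_mean WT baseline intensities (arbitrary
#'   units, channels 488 / 405).
#' @param parental_gfp_mean GFP background of the reporter-negative
#'   parental line.
#' @param rd16_gfp_fraction,rd16_viability_fraction Disease-line GFP and
#'   DAPI baselines as fractions of WT, in (0, 1].
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   per-well noise (both channels).
#' @param gradient_amplitude Amplitude of the additive separable row+column
#'   linear gradient, as a fraction of the channel's WT baseline.
#' @param edge_amplitude Additive offset on edge rows/columns, as a fraction
#'   of the channel's WT baseline.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   campaign.
#' @param preset Dilution-series preset: `"primary-7pt"` (seven 1:3 points
#'   from 10 mM, single plate) or `"confirmatory-11pt-x3"` (eleven 1:3
#'   points from 10 mM, triplicate).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_compounds = 600L,
                       class_probabilities = c(
                         inactive = 0.70, efficacious = 0.12, toxic = 0.08,
                         autofluorescent = 0.05, efficacious_toxic = 0.03,
                         efficacious_autofluorescent = 0.02),
                       wt_gfp_mean = 1000, wt_dapi_mean = 1000,
                       parental_gfp_mean = 40,
                       rd16_gfp_fraction = 0.4,
                       rd16_viability_fraction = 0.5,
                       noise_cv = 0.10,
                       gradient_amplitude = 0.02,
                       edge_amplitude = 0.02,
                       seed = 1L,
                       preset = c("primary-7pt", "confirmatory-11pt-x3")) {
  preset <- match.arg(preset)
  classes <- c("inactive", "efficacious", "toxic", "autofluorescent",
               "efficacious_toxic", "efficacious_autofluorescent")
  if (!setequal(names(class_probabilities), classes)) {
    abort(paste0("class_probabilities must be named over: ",
                 paste(classes, collapse = ", ")))
  }
  class_probabilities <- class_probabilities[classes]
  if (abs(sum(class_probabilities) - 1) > 1e-9) {
    abort("class_probabilities must sum to 1 (tolerance 1e-9)")
  }
  if (any(class_probabilities < 0)) abort("class probabilities must be >= 0")
  frac_ok <- function(x) is.numeric(x) && x > 0 && x <= 1
  if (!frac_ok(rd16_gfp_fraction) || !frac_ok(rd16_viability_fraction)) {
    abort("rd16 fractions must lie in (0, 1]")
  }
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  series <- switch(preset,
    "primary-7pt" = list(stock = 1e-2, factor = 3, n_points = 7L, replicates = 1L),
    "confirmatory-11pt-x3" = list(stock = 1e-2, factor = 3, n_points = 11L,
                                  replicates = 3L))
  structure(list(
    n_compounds = as.integer(n_compounds),
    class_probabilities = class_probabilities,
    wt_gfp_mean = wt_gfp_mean, wt_dapi_mean = wt_dapi_mean,
    parental_gfp_mean = parental_gfp_mean,
    rd16_gfp_fraction = rd16_gfp_fraction,
    rd16_viability_fraction = rd16_viability_fraction,
    noise_cv = noise_cv,
    gradient_amplitude = gradient_amplitude,
    edge_amplitude = edge_amplitude,
    seed = as.integer(seed), preset = preset, series = series
  ), class = "sim_config")
}

# fractional Hill occupancy in (0,1): 1 / (1 + (ac50/c)^n) in log10 form
hill_fraction <- function(conc, ac50, n) {
  1 / (1 + 10^(n * (log10(ac50) - log10(conc))))
}

# draw ground-truth effect parameters for one compound class
draw_truth <- function(ids, classes, series) {
  n <- length(ids)
  conc <- dilution_series(series$stock, series$factor, series$n_points)
  lo <- log10(min(conc))
  hi <- log10(max(conc))
  is_eff <- classes %in% c("efficacious", "efficacious_toxic",
                           "efficacious_autofluorescent")
  is_tox <- classes %in% c("toxic", "efficacious_toxic")
  is_fluor <- classes %in% c("autofluorescent", "efficacious_autofluorescent")
  # efficacy AC50 comfortably inside the tested window; toxicity skewed
  # toward high concentrations; autofluorescence anywhere in-window
  tt <- tibble(
    compound_id = ids,
    class = classes,
    is_efficacious = is_eff, is_toxic = is_tox, is_autofluorescent = is_fluor,
    ainf_e = ifelse(is_eff, runif(n, 0.5, 1.0), NA_real_),
    ac50_e = ifelse(is_eff, 10^runif(n, lo + 1.0, hi - 1.0), NA_real_),
    n_e = ifelse(is_eff, runif(n, 0.8, 2.0), NA_real_),
    max_kill = ifelse(is_tox, runif(n, 0.5, 1.0), NA_real_),
    ac50_t = ifelse(is_tox, 10^runif(n, hi - 2.5, hi + 0.5), NA_real_),
    n_t = ifelse(is_tox, runif(n, 0.8, 2.0), NA_real_),
    added_gfp = ifelse(is_fluor, runif(n, 300, 900), NA_real_),
    ac50_f = ifelse(is_fluor, 10^runif(n, lo + 1.0, hi - 1.0), NA_real_),
    n_f = ifelse(is_fluor, runif(n, 0.8, 2.0), NA_real_)
  )
  tt
}

# deterministic plate layout in the usual qHTS arrangement: every plate
# carries a single concentration of every compound (the titration spans
# plates), with col 0 = own-line DMSO, col 1 = WT+DMSO on disease plates /
# own-line DMSO elsewhere, and compounds filling cols 2..47 column-major.
# One concentration per plate also means a compound's series is never a
# spatially contiguous block, so genuine activity does not mimic the
# localized clusters the QC masker removes.
layout_assay <- function(truth, config, assay, replicate) {
  series <- config$series
  conc <- dilution_series(series$stock, series$factor, series$n_points)
  line <- if (assay == "DISEASE_ASSAY") "RD16" else "PARENTAL"
  per_plate <- PLATE_ROWS * (PLATE_COLS - 2L)
  n_chunks <- ceiling(nrow(truth) / per_plate)
  out <- list()
  for (j in seq_len(series$n_points)) {
    for (p in seq_len(n_chunks)) {
      ids <- truth$compound_id[((p - 1L) * per_plate + 1L):
                                 min(p * per_plate, nrow(truth))]
      plate_id <- sprintf("%s_R%d_C%02d_P%02d",
                          if (assay == "DISEASE_ASSAY") "DIS" else "CTR",
                          replicate, j, p)
      ctrl_line2 <- if (assay == "DISEASE_ASSAY") "WT" else line
      ctrl <- tibble(
        plate_id = plate_id,
        row = rep(0:(PLATE_ROWS - 1L), 2L),
        col = rep(c(0L, 1L), each = PLATE_ROWS),
        cell_line = rep(c(line, ctrl_line2), each = PLATE_ROWS),
        treatment = "DMSO", compound_id = NA_character_,
        concentration = NA_real_
      )
      idx <- seq_along(ids) - 1L
      cmp <- tibble(
        plate_id = plate_id,
        row = idx %% PLATE_ROWS,
        col = 2L + idx %/% PLATE_ROWS,
        cell_line = line, treatment = "COMPOUND",
        compound_id = ids,
        concentration = conc[j]
      )
      out[[plate_id]] <- bind_rows(ctrl, cmp)
    }
  }
  bind_rows(out) %>%
    mutate(assay_kind = assay, replicate = as.integer(replicate))
}

# noiseless expected intensities for every well, given the ground truth
expected_intensities <- function(wells, truth, config) {
  tt <- truth[match(wells$compound_id, truth$compound_id), ]
  conc <- wells$concentration
  eff <- ifelse(!is.na(tt$ac50_e) & !is.na(conc),
                tt$ainf_e * hill_fraction(conc, tt$ac50_e, tt$n_e), 0)
  kill <- ifelse(!is.na(tt$ac50_t) & !is.na(conc),
                 tt$max_kill * hill_fraction(conc, tt$ac50_t, tt$n_t), 0)
  fluor <- ifelse(!is.na(tt$ac50_f) & !is.na(conc),
                  tt$added_gfp * hill_fraction(conc, tt$ac50_f, tt$n_f), 0)
  base_gfp <- c(WT = config$wt_gfp_mean,
                RD16 = config$wt_gfp_mean * config$rd16_gfp_fraction,
                PARENTAL = config$parental_gfp_mean)[wells$cell_line]
  base_dapi <- c(WT = config$wt_dapi_mean,
                 RD16 = config$wt_dapi_mean * config$rd16_viability_fraction,
                 PARENTAL = config$wt_dapi_mean)[wells$cell_line]
  # efficacy rescues disease GFP toward the WT baseline; a killed fraction
  # removes reporter and nuclei signal alike; autofluorescence adds to GFP
  # in every line, which is exactly what the parental retest detects
  rescue <- ifelse(wells$cell_line == "RD16",
                   eff * (config$wt_gfp_mean - base_gfp), 0)
  gfp <- (unname(base_gfp) + rescue) * (1 - kill) + fluor
  dapi <- unname(base_dapi) * (1 - kill)
  list(gfp = gfp, dapi = dapi)
}

apply_plate_artifacts <- function(wells, gfp, dapi, config) {
  rowc <- (wells$row - (PLATE_ROWS - 1) / 2) / (PLATE_ROWS - 1)
  colc <- (wells$col - (PLATE_COLS - 1) / 2) / (PLATE_COLS - 1)
  grad <- config$gradient_amplitude * (rowc + colc)
  edge <- config$edge_amplitude *
    (wells$row %in% c(0L, PLATE_ROWS - 1L) | wells$col %in% c(0L, PLATE_COLS - 1L))
  list(gfp = gfp + (grad + edge) * config$wt_gfp_mean,
       dapi = dapi + (grad + edge) * config$wt_dapi_mean)
}

#' Simulate a screening campaign with known ground truth
#'
#' Generates a disease assay (RD16 line) and an autofluorescence
#' counter-screen (GFP-negative parental line) for `config$n_compounds`
#' compounds, each tested as a serial-dilution series, together with the
#' generating parameters of every compound. Deterministic for a fixed
#' config (including its seed).
#'
#' @param config A [sim_config()].
#' @param truth Optional ground-truth table (same columns as the one
#'   returned); when supplied the generator uses these compound parameters
#'   instead of drawing them, so tests can simulate compounds with known,
#'   fixed effects.
#' @return A list with elements `plates` (a [plate_set()] tibble covering
#'   both assays and all replicates) and `truth` (one row per compound:
#'   class flags and Hill parameters of each simulated effect).
#' @examples
#' sim <- simulate_campaign(sim_config(n_compounds = 20, seed = 7))
#' dplyr::count(sim$truth, class)
#' @export
simulate_campaign <- function(config = sim_config(), truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    if (is.null(truth)) {
      ids <- sprintf("C%04d", seq_len(config$n_compounds))
      classes <- sample(names(config$class_probabilities), config$n_compounds,
                        replace = TRUE, prob = config$class_probabilities)
      truth <- draw_truth(ids, classes, config$series)
    } else {
      truth <- as_tibble(truth)
      config$n_compounds <- nrow(truth)
    }
    wells <- bind_rows(lapply(seq_len(config$series$replicates) - 1L, function(r) {
      bind_rows(layout_assay(truth, config, "DISEASE_ASSAY", r),
                layout_assay(truth, config, "COUNTER_SCREEN", r))
    }))
    exp_int <- expected_intensities(wells, truth, config)
    art <- apply_plate_artifacts(wells, exp_int$gfp, exp_int$dapi, config)
    gfp <- art$gfp
    dapi <- art$dapi
    if (config$noise_cv > 0) {
      sdlog <- sqrt(log1p(config$noise_cv^2))
      # mean-one lognormal so expected intensities match the noiseless model
      gfp <- gfp * rlnorm(length(gfp), -sdlog^2 / 2, sdlog)
      dapi <- dapi * rlnorm(length(dapi), -sdlog^2 / 2, sdlog)
    }
    wells$gfp <- pmax(gfp, 0)
    wells$dapi <- pmax(dapi, 0)
    wells$masked <- FALSE
    list(plates = plate_set(wells), truth = truth)
  })
}

#' Expected triage calls from generator ground truth
#'
#' Maps each simulated compound's generating parameters to the verdict an
#' ideal analyst would reach under the triage thresholds, analytically and
#' without any curve fitting — the oracle for confusion-matrix scoring of
#' the fitted funnel.
#'
#' The oracle evaluates the *noiseless* percent-score curves implied by the
#' generative model over the tested concentrations. This matters because
#' the channels couple: a killed cell fraction removes reporter signal too,
#' so strong toxicity inside the tested range bells the observable efficacy
#' curve, and autofluorescence inflates disease-plate GFP exactly as it
#' inflates the counter-screen. A compound is an expected hit when its
#' noiseless efficacy curve is a clean rise (baseline near zero, no bell,
#' top response clearing the efficacy threshold) and every counter-activity
#' strong enough to register is at least `ratio_min`-fold less potent.
#'
#' @param truth Truth tibble from [simulate_campaign()].
#' @param config The [sim_config()] used (fixes the tested range and
#'   baselines).
#' @param thresholds A [triage_thresholds()].
#' @param classify A [classify_thresholds()] supplying the baseline,
#'   amplitude and plateau margins used to judge the noiseless curves.
#' @return Tibble `compound_id, expected_verdict, expected_hit`.
#' @export
truth_to_expected_calls <- function(truth, config,
                                    thresholds = triage_thresholds(),
                                    classify = classify_thresholds()) {
  conc <- dilution_series(config$series$stock, config$series$factor,
                          config$series$n_points)
  conc <- sort(conc)
  window <- config$wt_gfp_mean * (1 - config$rd16_gfp_fraction)
  fl_window <- config$wt_gfp_mean - config$parental_gfp_mean
  per <- function(tt) {
    eff <- if (tt$is_efficacious) {
      tt$ainf_e * hill_fraction(conc, tt$ac50_e, tt$n_e)
    } else 0
    kill <- if (tt$is_toxic) {
      tt$max_kill * hill_fraction(conc, tt$ac50_t, tt$n_t)
    } else 0
    fluor <- if (tt$is_autofluorescent) {
      tt$added_gfp * hill_fraction(conc, tt$ac50_f, tt$n_f)
    } else 0
    rd16 <- config$wt_gfp_mean * config$rd16_gfp_fraction
    e <- 100 * ((rd16 + eff * window) * (1 - kill) + fluor - rd16) / window
    tox_pct <- 100 * kill
    fluor_pct <- 100 * fluor / fl_window
    top <- e[length(e)]
    clean_rise <- abs(e[1]) <= classify$baseline_max &&          # baseline
      top - e[1] >= classify$amplitude_min &&                    # rises
      max(e) - top <= classify$plateau_max &&                    # no bell
      top >= thresholds$ainf_min                                 # high enough
    if (clean_rise) {
      # potency of the apparent efficacy: where the noiseless curve first
      # crosses half its top response (log-linear interpolation)
      half <- top / 2
      i <- which(e >= half)[1]
      eff_ac50 <- if (i == 1) conc[1] else {
        10^(log10(conc[i - 1]) + (half - e[i - 1]) / (e[i] - e[i - 1]) *
              (log10(conc[i]) - log10(conc[i - 1])))
      }
      # a counter-activity registers when its full amplitude clears the
      # classifier's margin; whether its rise is visible in-range is what
      # the ratio test resolves (an out-of-range AC50 gives a huge ratio)
      tox_active <- tt$is_toxic && 100 * tt$max_kill >= classify$amplitude_min
      fluor_active <- tt$is_autofluorescent &&
        100 * tt$added_gfp / fl_window >= classify$amplitude_min
      if (tox_active && tt$ac50_t / eff_ac50 < thresholds$ratio_min) {
        return("TOXIC")
      }
      if (fluor_active && tt$ac50_f / eff_ac50 < thresholds$ratio_min) {
        return("AUTOFLUORESCENT")
      }
      return("HIT")
    }
    if (tt$is_toxic && max(e) - top > classify$plateau_max) return("TOXIC")
    if (tt$is_autofluorescent && max(fluor_pct) >= classify$amplitude_min) {
      return("AUTOFLUORESCENT")
    }
    "INACTIVE"
  }
  tibble(
    compound_id = truth$compound_id,
    expected_verdict = vapply(seq_len(nrow(truth)),
                              function(i) per(truth[i, ]), character(1))
  ) %>%
    mutate(expected_hit = .data$expected_verdict == "HIT")
}
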