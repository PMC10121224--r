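# Independent oracles used across tests. These deliberately do not share
# code with the package's own implementation paths.

# Exhaustive grid search for the best Hill SSE over the bounded parameter
# box: lattice in (log_ac50, n) at the given steps, with the asymptotes
# profiled out exactly (the model is linear in a0, ainf given the logistic
# shape) and clamped back into the box.
grid_hill_best_sse <- function(conc, score, bounds = qhtscreen::hill_bounds(conc),
                               la_step = 0.01, n_step = 0.1) {
  las <- seq(bounds$lower[["log_ac50"]], bounds$upper[["log_ac50"]], by = la_step)
  ns <- seq(n_step, bounds$upper[["n"]], by = n_step)
  grid <- expand.grid(la = las, n = ns)
  lg <- log10(conc)
  best <- Inf
  # chunk the grid to bound memory
  chunk <- 20000L
  a_lo <- bounds$lower[["a0"]]; a_hi <- bounds$upper[["a0"]]
  for (s in seq(1L, nrow(grid), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(grid))
    f <- 1 / (1 + 10^(outer(grid$n[idx] * grid$la[idx], rep(1, length(lg))) -
                        outer(grid$n[idx], lg)))
    one_f <- 1 - f
    s11 <- rowSums(one_f^2); s12 <- rowSums(one_f * f); s22 <- rowSums(f^2)
    b1 <- as.vector(one_f %*% score); b2 <- as.vector(f %*% score)
    det <- s11 * s22 - s12^2
    a0 <- ifelse(det > 1e-12, (b1 * s22 - b2 * s12) / det, mean(score))
    ai <- ifelse(det > 1e-12, (b2 * s11 - b1 * s12) / det, mean(score))
    a0 <- pmin(pmax(a0, a_lo), a_hi)
    ai <- pmin(pmax(ai, a_lo), a_hi)
    pred <- a0 * one_f + ai * f
    sse <- rowSums((matrix(score, nrow(f), length(score), byrow = TRUE) - pred)^2)
    best <- min(best, min(sse))
  }
  best
}

# Literal well-by-well transcription of the three percent normalizations,
# computed straight from plate means with base R only.
oracle_scores <- function(plates) {
  plates <- as.data.frame(plates)
  out <- list()
  wt_by_rep <- tapply(
    plates$gfp[plates$cell_line == "WT" & plates$treatment == "DMSO" & !plates$masked],
    plates$replicate[plates$cell_line == "WT" & plates$treatment == "DMSO" & !plates$masked],
    mean)
  for (pid in unique(plates$plate_id)) {
    pw <- plates[plates$plate_id == pid, ]
    rep_i <- pw$replicate[1]
    dm <- pw[pw$treatment == "DMSO" & !pw$masked, ]
    m <- function(line, ch) mean(dm[[ch]][dm$cell_line == line])
    wt_gfp <- if (any(dm$cell_line == "WT")) m("WT", "gfp") else
      wt_by_rep[[as.character(rep_i)]]
    cw <- pw[pw$treatment == "COMPOUND" & !pw$masked, ]
    if (!nrow(cw)) next
    if (pw$assay_kind[1] == "DISEASE_ASSAY") {
      out[[pid]] <- data.frame(
        compound_id = cw$compound_id, concentration_molar = cw$concentration,
        replicate = rep_i,
        efficacy = 100 * (cw$gfp - m("RD16", "gfp")) / (wt_gfp - m("RD16", "gfp")),
        toxicity = -100 * (cw$dapi - m("RD16", "dapi")) / m("RD16", "dapi"))
    } else if (pw$assay_kind[1] == "COUNTER_SCREEN") {
      out[[pid]] <- data.frame(
        compound_id = cw$compound_id, concentration_molar = cw$concentration,
        replicate = rep_i,
        fluorescence = 100 * (cw$gfp - m("PARENTAL", "gfp")) /
          (wt_gfp - m("PARENTAL", "gfp")))
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  dis <- out[vapply(out, function(x) "efficacy" %in% names(x), logical(1))]
  ctr <- out[vapply(out, function(x) "fluorescence" %in% names(x), logical(1))]
  dis <- if (length(dis)) do.call(rbind, dis) else NULL
  ctr <- if (length(ctr)) do.call(rbind, ctr) else NULL
  if (is.null(dis)) return(ctr)
  if (is.null(ctr)) return(dis)
  merge(dis, ctr, by = c("compound_id", "concentration_molar", "replicate"),
        all = TRUE)
}

# small handmade plate set: one disease plate + one counter plate with
# controls and a few compound wells
toy_plate_set <- function(gfp_compound = c(80, 60), conc = c(1e-5, 1e-6),
                          compound = "CPD1") {
  n <- length(gfp_compound)
  dis <- tibble::tibble(
    plate_id = "D1",
    row = c(0:3, 10:(9 + n)), col = c(0, 0, 1, 1, rep(5, n)),
    cell_line = c("RD16", "RD16", "WT", "WT", rep("RD16", n)),
    treatment = c(rep("DMSO", 4), rep("COMPOUND", n)),
    compound_id = c(rep(NA, 4), rep(compound, n)),
    concentration = c(rep(NA, 4), conc),
    gfp = c(38, 42, 110, 130, gfp_compound),
    dapi = c(480, 520, 1000, 1000, rep(500, n)),
    masked = FALSE)
  ctr <- tibble::tibble(
    plate_id = "P1",
    row = c(0:1, 10:(9 + n)), col = c(0, 0, rep(5, n)),
    cell_line = "PARENTAL",
    treatment = c(rep("DMSO", 2), rep("COMPOUND", n)),
    compound_id = c(rep(NA, 2), rep(compound, n)),
    concentration = c(rep(NA, 2), conc),
    gfp = c(8, 12, rep(10, n)),
    dapi = 1000, masked = FALSE)
  qhtscreen::plate_set(dplyr::bind_rows(dis, ctr))
}
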