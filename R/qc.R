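# Automated plate quality control: masking localized groups of aberrant
# wells before normalization. The rule is a reproducible surrogate for the
# visual inspection used on the original screens: a well is flagged when
# its robust z-score against its spatial neighborhood (same-treatment wells
# only) exceeds a threshold in either channel, and flagged wells are masked
# only when they form a 4-connected cluster — "localized groupings" — of at
# least `min_cluster` wells.

#' Mask localized intensity artifacts on each plate
#'
#' For every unmasked well and each channel, computes a robust z-score
#' `(x - median) / (1.4826 * MAD)` over the `window` x `window` spatial
#' neighborhood restricted to unmasked wells with the same treatment
#' (compound wells are compared to compound wells, DMSO to DMSO; the well
#' itself is excluded). The MAD is floored at `1e-9` so constant
#' neighborhoods yield a zero z-score rather than a division by zero.
#' Wells with `|z| > z_threshold` in either channel are masked when they
#' form a 4-connected, sign-consistent cluster of at least `min_cluster`
#' wells. Wells already masked on input are reported with reason `MANUAL`
#' and never unmasked.
#'
#' @param plates A [plate_set()] tibble.
#' @param window Odd neighborhood side length, >= 3.
#' @param z_threshold Robust z-score threshold, > 0.
#' @param min_cluster Minimum cluster size to mask, >= 1.
#' @return A list with `plates` (the plate set with `masked` updated) and
#'   `report` (tibble `plate_id,row,col,reason` with reason `LOCAL_HIGH`,
#'   `LOCAL_LOW` or `MANUAL`; attribute `n_masked` per plate via
#'   `dplyr::count()`).
#' @examples
#' sim <- simulate_campaign(sim_config(n_compounds = 30, seed = 3))
#' qc <- mask_local_artifacts(sim$plates)
#' nrow(qc$report)
#' @export
mask_local_artifacts <- function(plates, window = 5L, z_threshold = 5,
                                 min_cluster = 3L) {
  validate_wells(plates)
  if (window < 3L || window %% 2L == 0L) abort("window must be odd and >= 3")
  if (z_threshold <= 0) abort("z_threshold must be > 0")
  if (min_cluster < 1L) abort("min_cluster must be >= 1")
  out <- plates
  reports <- list()
  for (pid in unique(plates$plate_id)) {
    idx <- which(plates$plate_id == pid)
    pw <- plates[idx, ]
    manual <- pw$masked
    if (sum(!manual) > 0 && sum(!manual) < 3L) {
      abort(paste0("plate ", pid,
                   " has too few unmasked wells for neighborhood statistics"))
    }
    zg <- neighborhood_z(pw, pw$gfp, window)
    zd <- neighborhood_z(pw, pw$dapi, window)
    # flag on the channel with the larger excursion; sign follows it
    z <- ifelse(abs(zg) >= abs(zd), zg, zd)
    flagged <- !manual & abs(z) > z_threshold
    keep <- cluster_filter(pw$row, pw$col, flagged, sign(z), min_cluster)
    rep_rows <- bind_rows(
      tibble(plate_id = pid, row = pw$row[manual], col = pw$col[manual],
             reason = rep("MANUAL", sum(manual))),
      tibble(plate_id = pid, row = pw$row[keep], col = pw$col[keep],
             reason = c("LOCAL_LOW", "LOCAL_HIGH")[(z[keep] > 0) + 1L])
    )
    out$masked[idx] <- manual | keep
    reports[[pid]] <- rep_rows
  }
  report <- bind_rows(reports)
  if (nrow(report)) report <- arrange(report, .data$plate_id, .data$row, .data$col)
  list(plates = out, report = report)
}

# robust z per well against its window neighborhood (same treatment and
# cell line — the only wells exchangeable with it — unmasked, self
# excluded); falls back to plate-wide same-group stats when the window
# holds fewer than 3 usable neighbors
neighborhood_z <- function(pw, x, window) {
  half <- (window - 1L) %/% 2L
  n <- nrow(pw)
  z <- numeric(n)
  usable <- !pw$masked
  grid <- matrix(NA_integer_, PLATE_ROWS, PLATE_COLS)
  grid[cbind(pw$row + 1L, pw$col + 1L)] <- seq_len(n)
  for (i in seq_len(n)) {
    if (!usable[i]) next
    rr <- max(0L, pw$row[i] - half):min(PLATE_ROWS - 1L, pw$row[i] + half)
    cc <- max(0L, pw$col[i] - half):min(PLATE_COLS - 1L, pw$col[i] + half)
    nb <- grid[rr + 1L, cc + 1L]
    nb <- nb[!is.na(nb)]
    same <- function(j) pw$treatment[j] == pw$treatment[i] &
      pw$cell_line[j] == pw$cell_line[i]
    nb <- nb[nb != i & usable[nb] & same(nb)]
    if (length(nb) < 3L) {
      nb <- which(usable & same(seq_len(n)))
      nb <- nb[nb != i]
    }
    if (length(nb) < 3L) {
      abort(paste0("plate ", pw$plate_id[1],
                   " has too few unmasked wells for neighborhood statistics"))
    }
    med <- median(x[nb])
    mad_ <- max(stats::mad(x[nb], center = med), 1e-9)
    z[i] <- (x[i] - med) / mad_
  }
  z
}

# keep flagged wells belonging to a 4-connected component (within the same
# excursion sign) of size >= min_cluster
cluster_filter <- function(row, col, flagged, sgn, min_cluster) {
  keep <- logical(length(row))
  if (!any(flagged)) return(keep)
  for (s in c(-1, 1)) {
    idx <- which(flagged & sgn == s)
    if (!length(idx)) next
    key <- row[idx] * PLATE_COLS + col[idx]
    lookup <- setNames(seq_along(idx), key)
    comp <- seq_along(idx)          # union-find over flagged wells
    find <- function(a) { while (comp[a] != a) { comp[a] <<- comp[comp[a]]; a <- comp[a] }; a }
    for (j in seq_along(idx)) {
      for (d in list(c(1L, 0L), c(0L, 1L))) {
        nk <- as.character((row[idx[j]] + d[1]) * PLATE_COLS + col[idx[j]] + d[2])
        k <- unname(lookup[nk])
        if (!is.na(k)) comp[find(j)] <- find(k)
      }
    }
    roots <- vapply(seq_along(idx), find, integer(1))
    sizes <- table(roots)
    keep[idx[sizes[as.character(roots)] >= min_cluster]] <- TRUE
  }
  keep
}
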