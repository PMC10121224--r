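# End-to-end pipeline: qc -> normalize -> fit -> classify -> triage, with
# every intermediate table written as CSV stamped with a hash of the
# configuration, so a rerun with the same config and inputs reproduces the
# same bytes (timings live only in the run log).

#' Pipeline configuration
#'
#' A single declarative object covering every stage. Inputs come either
#' from CSV paths (`plate_table`, `layout`, read with [read_plate_table()])
#' or from an in-memory [plate_set()] via `plates`.
#'
#' @param plates Optional [plate_set()] tibble (takes precedence over paths).
#' @param plate_table,layout,compound_map Optional input CSV paths.
#' @param out_dir Output directory for the report bundle.
#' @param qc List of [mask_local_artifacts()] arguments.
#' @param normalization List; `trim` for [control_stats()].
#' @param fit List; `multistart` and `seed` for [fit_campaign()].
#' @param classify A [classify_thresholds()].
#' @param triage A [triage_thresholds()].
#' @param save_plots Write concentration-response plots for the top hits.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(plates = NULL, plate_table = NULL, layout = NULL,
                            compound_map = NULL, out_dir = tempfile("qhts_"),
                            qc = list(window = 5L, z_threshold = 5,
                                      min_cluster = 3L),
                            normalization = list(trim = 0),
                            fit = list(multistart = 5L, seed = 1L),
                            classify = classify_thresholds(),
                            triage = triage_thresholds(),
                            save_plots = FALSE) {
  if (is.null(plates) && (is.null(plate_table) || is.null(layout))) {
    abort("supply either `plates` or both `plate_table` and `layout`")
  }
  stopifnot(inherits(classify, "classify_thresholds"),
            inherits(triage, "triage_thresholds"))
  if (qc$window < 3L || qc$window %% 2L == 0L) {
    abort("invalid config: qc$window must be odd and >= 3")
  }
  if (qc$z_threshold <= 0) abort("invalid config: qc$z_threshold must be > 0")
  if (fit$multistart < 1L) abort("invalid config: fit$multistart must be >= 1")
  structure(list(plates = plates, plate_table = plate_table, layout = layout,
                 compound_map = compound_map, out_dir = out_dir, qc = qc,
                 normalization = normalization, fit = fit,
                 classify = classify, triage = triage,
                 save_plots = save_plots),
            class = "pipeline_config")
}

# stable hash of everything that influences the numbers (not the paths)
config_hash <- function(config) {
  keep <- config[c("qc", "normalization", "fit", "classify", "triage")]
  keep <- rapply(keep, unclass, how = "replace")
  txt <- yaml::as.yaml(keep)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full screening-analysis pipeline
#'
#' Executes QC masking, normalization, Hill fitting with classification,
#' and triage, writing each stage's table under `config$out_dir`
#' (`mask_report.csv`, `scores.csv`, `fits.csv`, `verdicts.csv`,
#' `hits.csv`, `summary.txt`, `run_log.txt`). Every CSV starts with a
#' comment line carrying the configuration hash; rerunning with an
#' identical config and inputs reproduces identical CSV bytes.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle, invisibly printable via [summarize()]: a list
#'   with the plates, mask report, scores, fits, verdicts, hits, verdict
#'   counts, config and its hash, and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  stamp <- paste0("# qhtscreen config_hash=", hash)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }
  plates <- config$plates %||%
    read_plate_table(config$plate_table, config$layout)
  tick("read")
  qc <- tryCatch(
    mask_local_artifacts(plates, window = config$qc$window,
                         z_threshold = config$qc$z_threshold,
                         min_cluster = config$qc$min_cluster),
    error = function(e) abort(paste0("stage qc failed: ", conditionMessage(e))))
  write_csv_commented(qc$report, file.path(config$out_dir, "mask_report.csv"), stamp)
  tick("qc")
  scores <- tryCatch(
    normalize_campaign(qc$plates,
                       stats = control_stats(qc$plates,
                                             trim = config$normalization$trim)),
    error = function(e) abort(paste0("stage normalize failed: ",
                                     conditionMessage(e))))
  write_csv_commented(scores, file.path(config$out_dir, "scores.csv"), stamp)
  tick("normalize")
  fits <- tryCatch(
    fit_campaign(scores, multistart = config$fit$multistart,
                 seed = config$fit$seed, thresholds = config$classify),
    error = function(e) abort(paste0("stage fit failed: ",
                                     conditionMessage(e))))
  write_csv_commented(fits, file.path(config$out_dir, "fits.csv"), stamp)
  tick("fit")
  tri <- tryCatch(triage_campaign(fits, thresholds = config$triage),
                  error = function(e) abort(paste0("stage triage failed: ",
                                                   conditionMessage(e))))
  write_csv_commented(tri$verdicts, file.path(config$out_dir, "verdicts.csv"), stamp)
  write_csv_commented(tri$hits, file.path(config$out_dir, "hits.csv"), stamp)
  tick("triage")
  counts <- table(factor(tri$verdicts$verdict, levels = VERDICTS))
  bundle <- structure(list(
    plates = qc$plates, mask_report = qc$report, scores = scores,
    fits = fits, verdicts = tri$verdicts, hits = tri$hits,
    verdict_counts = counts, config = config, config_hash = hash,
    out_dir = config$out_dir, timings = timings
  ), class = "screen_bundle")
  writeLines(summarize(bundle), file.path(config$out_dir, "summary.txt"))
  writeLines(c(stamp,
               paste0("seed=", config$fit$seed),
               sprintf("timing %s=%.3fs", names(timings), unlist(timings))),
             file.path(config$out_dir, "run_log.txt"))
  if (isTRUE(config$save_plots) && nrow(bundle$hits)) {
    pdir <- file.path(config$out_dir, "plots")
    dir.create(pdir, showWarnings = FALSE)
    for (cid in head(bundle$hits$compound_id, 10L)) {
      ggplot2::ggsave(file.path(pdir, paste0(cid, ".png")),
                      plot_dose_response(bundle$scores, cid, bundle$fits),
                      width = 6, height = 4, dpi = 120)
    }
  }
  bundle
}

#' Summarize a pipeline report bundle
#'
#' @param bundle A `screen_bundle` from [run_pipeline()].
#' @param top Number of ranked hits to list.
#' @return Character vector of report lines (also printed by
#'   `print.screen_bundle`).
#' @export
summarize <- function(bundle, top = 10L) {
  stopifnot(inherits(bundle, "screen_bundle"))
  lines <- c(
    "qhtscreen pipeline summary",
    paste0("config_hash: ", bundle$config_hash),
    "",
    sprintf("wells: %d (%d masked; %d masked by QC)", nrow(bundle$plates),
            sum(bundle$plates$masked),
            sum(bundle$mask_report$reason != "MANUAL")),
    sprintf("compounds scored: %d", n_distinct(bundle$scores$compound_id)),
    "",
    "verdict counts:",
    sprintf("  %-16s %d", names(bundle$verdict_counts),
            as.integer(bundle$verdict_counts)),
    "")
  if (nrow(bundle$hits)) {
    hits <- head(bundle$hits, top)
    has_fluor <- any(!is.na(bundle$scores$fluorescence))
    lines <- c(lines, sprintf("top %d hits (of %d):", nrow(hits),
                              nrow(bundle$hits)),
      sprintf("  %-8s Ainf=%5.1f%%  AC50=%8.3g M  ratio_tox=%-8s ratio_fluor=%-8s",
              hits$compound_id, hits$ainf_efficacy, hits$ac50_efficacy,
              formatC(hits$ratio_tox, digits = 3, format = "g"),
              if (has_fluor) formatC(hits$ratio_fluor, digits = 3, format = "g")
              else "not-assessed"))
  } else {
    lines <- c(lines, "no hits")
  }
  lines
}

#' @export
print.screen_bundle <- function(x, ...) {
  cat(summarize(x), sep = "\n")
  invisible(x)
}
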