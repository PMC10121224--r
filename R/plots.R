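# ggplot2 views of fits and score tables.

#' Plot a compound's concentration-response data and fitted curves
#'
#' @param scores A [normalize_campaign()] table.
#' @param compound_id Compound to plot.
#' @param fits Optional [fit_campaign()] table; converged curves are drawn
#'   over the points.
#' @return A ggplot.
#' @export
plot_dose_response <- function(scores, compound_id, fits = NULL) {
  sc <- scores %>%
    filter(.data$compound_id == !!compound_id) %>%
    tidyr::pivot_longer(c("efficacy", "toxicity", "fluorescence"),
                        names_to = "score_type", values_to = "score") %>%
    filter(!is.na(.data$score))
  if (!nrow(sc)) abort(paste0("no scores for compound ", compound_id))
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = log10(.data$concentration_molar),
                                        y = .data$score,
                                        colour = .data$score_type)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "log10 concentration (M)", y = "score (%)",
                  colour = NULL, title = compound_id) +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    ft <- fits %>%
      filter(.data$compound_id == !!compound_id, .data$converged)
    if (nrow(ft)) {
      grid <- seq(min(log10(sc$concentration_molar)),
                  max(log10(sc$concentration_molar)), length.out = 120)
      curves <- purrr::pmap_dfr(ft, function(score_type, a0, ainf, log_ac50,
                                             n, ...) {
        tibble(score_type = tolower(score_type), lg = grid,
               score = hill_response(list(a0 = a0, ainf = ainf,
                                          log_ac50 = log_ac50, n = n),
                                     10^grid))
      })
      p <- p + ggplot2::geom_line(
        data = curves,
        ggplot2::aes(x = .data$lg, y = .data$score,
                     colour = .data$score_type))
    }
  }
  p
}

#' @rdname plot_dose_response
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @export
autoplot.hill_fit <- function(object, ...) {
  sc <- object$data
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = log10(.data$conc),
                                        y = .data$score)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "log10 concentration (M)", y = "score (%)",
                  title = paste(object$compound_id, object$score_type)) +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- seq(min(log10(sc$conc)), max(log10(sc$conc)), length.out = 120)
    p <- p + ggplot2::geom_line(
      data = tibble(lg = grid,
                    score = hill_response(object$params, 10^grid)),
      ggplot2::aes(x = .data$lg, y = .data$score), colour = "steelblue")
  }
  p
}

#' Plate heatmap of raw intensity or mask status
#'
#' @param plates A [plate_set()] tibble.
#' @param plate_id Plate to draw.
#' @param channel `"gfp"`, `"dapi"` or `"masked"`.
#' @return A ggplot.
#' @export
plot_plate <- function(plates, plate_id, channel = c("gfp", "dapi", "masked")) {
  channel <- match.arg(channel)
  pw <- plates %>% filter(.data$plate_id == !!plate_id)
  if (!nrow(pw)) abort(paste0("no such plate: ", plate_id))
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[channel]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = plate_id, x = "column", y = "row") +
    ggplot2::theme_minimal()
}
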