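# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`. `ac50_molar` is the
#'   back-transformed midpoint for convenience.
#' @export
tidy.hill_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(
    term = c("a0", "ainf", "log_ac50", "n", "ac50_molar"),
    estimate = c(x$params$a0, x$params$ainf, x$params$log_ac50, x$params$n,
                 10^x$params$log_ac50))
}

#' Glance at a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One-row tibble: `sse`, `r2`, `n_points`, `n_conc`, `converged`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(sse = x$sse, r2 = x$r2, n_points = x$n_points, n_conc = x$n_conc,
         converged = x$converged)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
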