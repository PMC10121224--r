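# Four-parameter Hill (log-logistic) concentration-response model and
# bounded multistart least-squares fitting.
#
# The model, in log10 concentration,
#
#   A(c) = A0 + (Ainf - A0) / (1 + 10^(n * (log10 AC50 - log10 c)))
#
# has bottom asymptote A0, top asymptote Ainf, midpoint AC50 (the
# concentration giving a response half-way between the two asymptotes) and
# Hill coefficient n > 0 controlling steepness.

#' Hill model parameters
#'
#' @param a0 Response at zero concentration (percent).
#' @param ainf Response at infinite concentration (percent).
#' @param log_ac50 log10 of the midpoint concentration (mol/L).
#' @param n Hill coefficient, > 0.
#' @return A named list of class `hill_params`.
#' @export
hill_params <- function(a0, ainf, log_ac50, n) {
  stopifnot(is.finite(a0), is.finite(ainf), is.finite(log_ac50),
            is.finite(n), n > 0)
  structure(list(a0 = a0, ainf = ainf, log_ac50 = log_ac50, n = n),
            class = "hill_params")
}

#' Evaluate the Hill concentration-response model
#'
#' @param params A [hill_params()] (or any list with `a0`, `ainf`,
#'   `log_ac50`, `n`).
#' @param conc Concentrations in mol/L, all > 0 (vectorized).
#' @return Model response at each concentration. At `conc = 10^log_ac50`
#'   the response is exactly `(a0 + ainf) / 2`.
#' @examples
#' p <- hill_params(0, 100, -5, 1)
#' hill_response(p, 1e-5)   # 50
#' hill_response(p, 1e-4)   # ~90.9
#' @export
hill_response <- function(params, conc) {
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("concentrations must be positive and finite (mol/L)")
  }
  params$a0 + (params$ainf - params$a0) /
    (1 + 10^(params$n * (params$log_ac50 - log10(conc))))
}

#' Default parameter bounds for Hill fitting
#'
#' Asymptotes span [-100, 200] percent (twice the control window on either
#' side); the midpoint may sit up to two decades outside the tested range;
#' the Hill coefficient lies in (0, 10].
#'
#' @param conc Tested concentrations (mol/L).
#' @return List with `lower` and `upper` vectors over
#'   `(a0, ainf, log_ac50, n)`.
#' @export
hill_bounds <- function(conc) {
  list(lower = c(a0 = -100, ainf = -100,
                 log_ac50 = log10(min(conc)) - 2, n = 1e-3),
       upper = c(a0 = 200, ainf = 200,
                 log_ac50 = log10(max(conc)) + 2, n = 10))
}

#' Heuristic starting values for a Hill fit
#'
#' The bottom asymptote starts at the mean score of the two lowest
#' concentrations and the top at the mean of the two highest; the midpoint
#' starts where the per-concentration mean response, linearly interpolated
#' in log10 concentration, first crosses half-way between the two — or at
#' the centre of the tested log-range when it never crosses; the Hill
#' coefficient starts at 1.
#'
#' @param points Data frame with columns `conc` (mol/L) and `score`.
#' @return A [hill_params()].
#' @export
initial_guess <- function(points) {
  pts <- collapse_points(points)
  if (nrow(pts) < 4L) {
    abort("initial_guess needs >= 4 distinct concentrations")
  }
  a0 <- mean(pts$score[1:2])
  ainf <- mean(pts$score[(nrow(pts) - 1):nrow(pts)])
  mid <- (a0 + ainf) / 2
  lg <- log10(pts$conc)
  above <- (pts$score - mid) * sign(ainf - a0 + (ainf == a0)) >= 0
  cross <- which(above & !dplyr::lag(above, default = TRUE))
  log_ac50 <- if (ainf != a0 && length(cross)) {
    i <- cross[1]
    s0 <- pts$score[i - 1]; s1 <- pts$score[i]
    if (s1 == s0) lg[i] else lg[i - 1] + (mid - s0) / (s1 - s0) * (lg[i] - lg[i - 1])
  } else {
    mean(range(lg))
  }
  hill_params(a0, ainf, log_ac50, 1)
}

# mean score per distinct concentration, ascending
collapse_points <- function(points) {
  points <- as_tibble(points)
  stopifnot(all(c("conc", "score") %in% names(points)))
  points %>%
    filter(is.finite(.data$score), is.finite(.data$conc), .data$conc > 0) %>%
    group_by(.data$conc) %>%
    summarise(score = mean(.data$score), .groups = "drop") %>%
    arrange(.data$conc)
}

hill_sse <- function(par, conc, score) {
  r <- score - (par[1] + (par[2] - par[1]) /
                  (1 + 10^(par[4] * (par[3] - log10(conc)))))
  sum(r * r)
}

#' Fit the Hill model by bounded multistart least squares
#'
#' Minimizes the sum of squared residuals over `(a0, ainf, log_ac50, n)`
#' inside a parameter box, starting from [initial_guess()] plus
#' `multistart - 1` deterministically jittered restarts, and keeps the
#' lowest-SSE converged solution. Replicate observations enter as
#' individual residuals.
#'
#' @param points Data frame with columns `conc` (mol/L, > 0) and `score`
#'   (percent); replicates are separate rows.
#' @param bounds Parameter box, as [hill_bounds()].
#' @param multistart Number of starts (>= 1).
#' @param seed Seed for the restart jitter (deterministic fits).
#' @param compound_id,score_type Optional labels carried into the result.
#' @return An object of class `hill_fit`: the data, fitted `params` (NULL
#'   when unconverged or under-determined), `sse`, `r2`, `n_points`,
#'   `n_conc`, `converged`.
#' @examples
#' conc <- dilution_series(1e-2, 3, 11)
#' y <- hill_response(hill_params(0, 100, -5, 1), conc)
#' fit <- fit_hill(data.frame(conc = conc, score = y))
#' fit$params$log_ac50
#' @export
fit_hill <- function(points, bounds = NULL, multistart = 5L, seed = 1L,
                     compound_id = NA_character_, score_type = NA_character_) {
  points <- as_tibble(points)
  points <- points %>%
    filter(is.finite(.data$score), is.finite(.data$conc))
  if (any(points$conc <= 0)) abort("concentrations must be positive")
  n_conc <- n_distinct(points$conc)
  base <- structure(list(
    compound_id = compound_id, score_type = score_type,
    data = points, params = NULL, sse = NA_real_, r2 = NA_real_,
    n_points = nrow(points), n_conc = n_conc, converged = FALSE
  ), class = "hill_fit")
  if (n_conc < 4L) return(base)
  bounds <- bounds %||% hill_bounds(points$conc)
  guess <- initial_guess(points)
  g <- unlist(guess)
  starts <- list(g)
  if (multistart > 1L) {
    jit <- withr::with_seed(seed, {
      lapply(seq_len(multistart - 1L), function(k) {
        g + c(rnorm(2, 0, 15), rnorm(1, 0, 0.75), 0) *
          c(1, 1, 1, 1) + c(0, 0, 0, stats::runif(1, -0.5, 2))
      })
    })
    starts <- c(starts, jit)
  }
  lower <- bounds$lower
  upper <- bounds$upper
  clamp <- function(p) pmin(pmax(p, lower), upper)
  conc <- points$conc
  score <- points$score
  resid_fn <- function(p) {
    score - (p[1] + (p[2] - p[1]) / (1 + 10^(p[4] * (p[3] - log10(conc)))))
  }
  # coarse global scan: profile the asymptotes (linear given la, n) on a
  # lax lattice and seed the local optimizer from the best cells
  scan_starts <- function(k = 3L) {
    las <- seq(lower[["log_ac50"]], upper[["log_ac50"]], by = 0.1)
    ns <- c(0.3, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10)
    grid <- expand.grid(la = las, n = ns)
    lg <- log10(conc)
    f <- 1 / (1 + 10^(outer(grid$n * grid$la, rep(1, length(lg))) -
                        outer(grid$n, lg)))
    one_f <- 1 - f
    s11 <- rowSums(one_f^2); s12 <- rowSums(one_f * f); s22 <- rowSums(f^2)
    b1 <- as.vector(one_f %*% score); b2 <- as.vector(f %*% score)
    det <- s11 * s22 - s12^2
    a0 <- ifelse(det > 1e-12, (b1 * s22 - b2 * s12) / det, mean(score))
    ai <- ifelse(det > 1e-12, (b2 * s11 - b1 * s12) / det, mean(score))
    a0 <- pmin(pmax(a0, lower[["a0"]]), upper[["a0"]])
    ai <- pmin(pmax(ai, lower[["ainf"]]), upper[["ainf"]])
    sse <- rowSums((a0 * one_f + ai * f -
                      matrix(score, nrow(f), length(score), byrow = TRUE))^2)
    top <- order(sse)[seq_len(min(k, length(sse)))]
    lapply(top, function(i) c(a0[i], ai[i], grid$la[i], grid$n[i]))
  }
  starts <- c(starts, scan_starts())
  run_lm <- function(p0) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 400, ftol = 1e-15, ptol = 1e-15))),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    par <- clamp(fit$par)
    list(par = par, sse = sum(resid_fn(par)^2))
  }
  best <- NULL
  for (st in starts) {
    cand <- run_lm(clamp(st))
    if (is.null(cand)) {
      opt <- tryCatch(
        suppressWarnings(optim(clamp(st), hill_sse, conc = conc, score = score,
                               method = "L-BFGS-B", lower = lower,
                               upper = upper,
                               control = list(factr = 1e2, maxit = 500))),
        error = function(e) NULL)
      if (!is.null(opt)) cand <- list(par = opt$par, sse = opt$value)
    }
    if (!is.null(cand) && (is.null(best) || cand$sse < best$sse)) best <- cand
  }
  if (is.null(best)) return(base)
  # polish: asymptotes are linear given (log_ac50, n) -> solve them exactly,
  # then re-run the local optimizer from the refined point
  f <- 1 / (1 + 10^(best$par[4] * (best$par[3] - log10(conc))))
  X <- cbind(1 - f, f)
  ab <- tryCatch(qr.solve(crossprod(X), crossprod(X, score)),
                 error = function(e) NULL)
  if (!is.null(ab)) {
    pol <- run_lm(clamp(c(ab[1], ab[2], best$par[3], best$par[4])))
    if (!is.null(pol) && pol$sse < best$sse) best <- pol
  }
  pol <- run_lm(best$par)
  if (!is.null(pol) && pol$sse < best$sse) best <- pol
  par <- unname(best$par)
  sst <- sum((score - mean(score))^2)
  base$params <- hill_params(par[1], par[2], par[3], max(par[4], 1e-3))
  base$sse <- best$sse
  base$r2 <- if (sst > 0) 1 - best$sse / sst else NA_real_
  base$converged <- TRUE
  base
}

#' Midpoint concentration of a converged fit
#'
#' @param fit A `hill_fit`.
#' @return `10^log_ac50` in mol/L, or `NA` for an unconverged fit.
#' @export
ac50 <- function(fit) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!fit$converged) return(NA_real_)
  10^fit$params$log_ac50
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<hill_fit %s/%s> A0=%.2f Ainf=%.2f AC50=%.3g M n=%.2f r2=%.3f (%d pts)\n",
      x$compound_id, x$score_type, x$params$a0, x$params$ainf,
      10^x$params$log_ac50, x$params$n, x$r2, x$n_points))
  } else {
    cat(sprintf("<hill_fit %s/%s> unconverged (%d pts, %d concentrations)\n",
                x$compound_id, x$score_type, x$n_points, x$n_conc))
  }
  invisible(x)
}

#' Fit Hill curves for every compound and score type in a campaign
#'
#' Pivots a [normalize_campaign()] score table to long form and fits each
#' (compound, score type) series, then classifies each curve with
#' [classify_curve()].
#'
#' @param scores Output of [normalize_campaign()].
#' @param multistart,seed Passed to [fit_hill()].
#' @param thresholds A [classify_thresholds()].
#' @return Tibble with one row per fitted curve: `compound_id, score_type,`
#'   `a0, ainf, log_ac50, n, sse, r2, n_points, converged, curve_class,`
#'   `reasons` (semicolon-joined failed criteria).
#' @export
fit_campaign <- function(scores, multistart = 5L, seed = 1L,
                         thresholds = classify_thresholds()) {
  long <- scores %>%
    tidyr::pivot_longer(c("efficacy", "toxicity", "fluorescence"),
                        names_to = "score_type", values_to = "score") %>%
    filter(!is.na(.data$score)) %>%
    mutate(score_type = toupper(.data$score_type))
  groups <- split(long, list(long$compound_id, long$score_type), drop = TRUE)
  rows <- lapply(groups, function(gr) {
    fit <- fit_hill(
      tibble(conc = gr$concentration_molar, score = gr$score),
      multistart = multistart, seed = seed,
      compound_id = gr$compound_id[1], score_type = gr$score_type[1])
    cls <- classify_curve(fit, thresholds = thresholds)
    # model-free registration summary: mean response at the two lowest /
    # two highest tested concentrations (triage uses it to decide whether
    # a counter-assay registered at all, independent of fit pathology)
    pc <- collapse_points(fit$data)
    resp_low <- if (nrow(pc) >= 2) mean(pc$score[1:2]) else NA_real_
    resp_high <- if (nrow(pc) >= 2) {
      mean(pc$score[(nrow(pc) - 1):nrow(pc)])
    } else NA_real_
    tibble(
      compound_id = fit$compound_id, score_type = fit$score_type,
      a0 = if (fit$converged) fit$params$a0 else NA_real_,
      ainf = if (fit$converged) fit$params$ainf else NA_real_,
      log_ac50 = if (fit$converged) fit$params$log_ac50 else NA_real_,
      n = if (fit$converged) fit$params$n else NA_real_,
      sse = fit$sse, r2 = fit$r2, n_points = fit$n_points,
      converged = fit$converged, curve_class = cls$value,
      reasons = paste(cls$reasons, collapse = ";"),
      resp_low = resp_low, resp_high = resp_high)
  })
  bind_rows(rows) %>% arrange(.data$compound_id, .data$score_type)
}
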