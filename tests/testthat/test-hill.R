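test_that("hill_response matches hand-evaluated closed-form values", {
  p <- hill_params(0, 100, -5, 1)
  # midpoint: half-way between bottom and top
  expect_equal(hill_response(p, 1e-5), 50)
  # one decade above the midpoint with n = 1
  expect_equal(hill_response(p, 1e-4), 100 / 1.1, tolerance = 1e-12)
  # top asymptote at very large concentration
  expect_equal(hill_response(p, 1e-5 * 1e6), 100, tolerance = 1e-4)
  # general midpoint with offset asymptotes
  p2 <- hill_params(-20, 60, -4.2, 2.5)
  expect_equal(hill_response(p2, 10^-4.2), 20)
  expect_error(hill_response(p, 0), "positive")
  expect_error(hill_response(p, -1), "positive")
})

test_that("model is strictly increasing in concentration when ainf > a0", {
  set.seed(21)
  lg <- seq(-9, -1, length.out = 400)
  for (k in 1:25) {
    p <- hill_params(runif(1, -50, 50), runif(1, 60, 150),
                     runif(1, -7, -3), runif(1, 0.2, 9))
    if (p$ainf <= p$a0) next
    y <- hill_response(p, 10^lg)
    expect_true(all(diff(y) >= 0))
    # strict increase where the response is not saturated to float
    # precision (within two half-decades of the midpoint, scaled by n)
    mid <- abs(lg[-1] - p$log_ac50) < 2 / p$n
    expect_true(all(diff(y)[mid] > 0))
  }
})

test_that("initial guess anchors asymptotes and midpoint sensibly", {
  conc <- dilution_series(1e-2, 3, 11)
  y <- hill_response(hill_params(0, 100, -5, 1), conc)
  g <- initial_guess(data.frame(conc = conc, score = y))
  expect_lt(abs(g$a0 - 0), 5)
  expect_gt(g$ainf, 90)
  expect_lt(abs(g$log_ac50 - (-5)), 0.5)
  expect_equal(g$n, 1)
  # flat data: no crossing, midpoint of tested log-range
  gf <- initial_guess(data.frame(conc = conc, score = rep(7, 11)))
  expect_equal(gf$a0, 7)
  expect_equal(gf$ainf, 7)
  expect_equal(gf$log_ac50, mean(range(log10(conc))))
  # decreasing data keeps the inhibition shape at init
  gd <- initial_guess(data.frame(conc = conc, score = 100 - y))
  expect_gt(gd$a0, gd$ainf)
  expect_error(initial_guess(data.frame(conc = conc[1:3], score = y[1:3])),
               "4 distinct")
})

test_that("noiseless curves are recovered to high precision", {
  conc <- dilution_series(1e-2, 3, 11)
  cases <- list(c(0, 100, -5, 1), c(10, 80, -4, 2.4), c(-15, 120, -3.5, 0.7))
  for (cs in cases) {
    y <- hill_response(hill_params(cs[1], cs[2], cs[3], cs[4]), conc)
    f <- fit_hill(data.frame(conc = conc, score = y))
    expect_true(f$converged)
    expect_lt(abs(f$params$log_ac50 - cs[3]), 1e-6)
    expect_equal(unname(unlist(f$params)), cs, tolerance = 1e-4)
    expect_lt(f$sse, 1e-12)
  }
})

test_that("fits are deterministic and label-stable", {
  conc <- dilution_series(1e-2, 3, 7)
  set.seed(3)
  y <- hill_response(hill_params(0, 90, -4.5, 1.3), conc) + rnorm(7, 0, 6)
  f1 <- fit_hill(data.frame(conc = conc, score = y), seed = 2L)
  f2 <- fit_hill(data.frame(conc = conc, score = y), seed = 2L)
  expect_identical(unlist(f1$params), unlist(f2$params))
})

test_that("rescaling concentrations shifts log_ac50 and nothing else", {
  conc <- dilution_series(1e-2, 3, 9)
  set.seed(5)
  y <- hill_response(hill_params(5, 95, -4, 1.6), conc) + rnorm(9, 0, 4)
  f <- fit_hill(data.frame(conc = conc, score = y))
  k <- 1e3
  fk <- fit_hill(data.frame(conc = conc * k, score = y))
  expect_equal(fk$params$log_ac50, f$params$log_ac50 + log10(k),
               tolerance = 1e-6)
  expect_equal(fk$params$a0, f$params$a0, tolerance = 1e-6)
  expect_equal(fk$params$ainf, f$params$ainf, tolerance = 1e-6)
  expect_equal(fk$params$n, f$params$n, tolerance = 1e-6)
})

test_that("degenerate inputs degrade gracefully", {
  conc <- dilution_series(1e-2, 3, 7)
  # all-zero scores: converged flat fit, negligible amplitude
  f0 <- fit_hill(data.frame(conc = conc, score = rep(0, 7)))
  expect_true(f0$converged)
  expect_lt(abs(f0$params$ainf - f0$params$a0), 1e-6)
  expect_equal(classify_curve(f0)$value, "INACTIVE")
  # too few distinct concentrations: unconverged, params NULL
  f3 <- fit_hill(data.frame(conc = conc[1:3], score = c(1, 2, 3)))
  expect_false(f3$converged)
  expect_null(f3$params)
  expect_equal(classify_curve(f3)$value, "INCONCLUSIVE")
  expect_true(is.na(ac50(f3)))
})

test_that("ac50 back-transforms the fitted midpoint", {
  conc <- dilution_series(1e-2, 3, 11)
  y <- hill_response(hill_params(0, 100, -5, 1), conc)
  f <- fit_hill(data.frame(conc = conc, score = y))
  expect_equal(ac50(f), 1e-5, tolerance = 1e-6)
  # the screen's lead-compound potency scale: log10 AC50 of -4.7772 is
  # about 16.7 micromolar
  expect_equal(10^-4.7772 * 1e6, 16.7, tolerance = 1e-3)
})

test_that("tidy and glance expose fit terms broom-style", {
  conc <- dilution_series(1e-2, 3, 11)
  y <- hill_response(hill_params(0, 100, -5, 1), conc)
  f <- fit_hill(data.frame(conc = conc, score = y))
  td <- tidy(f)
  expect_equal(td$term, c("a0", "ainf", "log_ac50", "n", "ac50_molar"))
  expect_equal(td$estimate[td$term == "ac50_molar"], 1e-5, tolerance = 1e-6)
  gl <- glance(f)
  expect_equal(gl$n_points, 11L)
  expect_true(gl$converged)
})
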