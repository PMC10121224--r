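test_that("identical seed and config reproduce the campaign bit-for-bit", {
  a <- simulate_campaign(sim_config(n_compounds = 30, seed = 5))
  b <- simulate_campaign(sim_config(n_compounds = 30, seed = 5))
  expect_identical(a$plates, b$plates)
  expect_identical(a$truth, b$truth)
  c <- simulate_campaign(sim_config(n_compounds = 30, seed = 6))
  expect_false(identical(a$plates$gfp, c$plates$gfp))
})

test_that("config validation rejects inconsistent probabilities and fractions", {
  expect_error(sim_config(class_probabilities = c(
    inactive = 0.5, efficacious = 0.2, toxic = 0.2, autofluorescent = 0.2,
    efficacious_toxic = 0, efficacious_autofluorescent = 0)), "sum to 1")
  expect_error(sim_config(rd16_gfp_fraction = 1.2), "\\(0, 1\\]")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
})

noiseless_cfg <- function(...) {
  sim_config(noise_cv = 0, gradient_amplitude = 0, edge_amplitude = 0, ...)
}

fixed_truth <- function(id = "C0001", class = "efficacious",
                        ainf_e = 1, ac50_e = 1e-7, n_e = 2) {
  tibble::tibble(
    compound_id = id, class = class,
    is_efficacious = class != "inactive", is_toxic = FALSE,
    is_autofluorescent = FALSE,
    ainf_e = ifelse(class == "inactive", NA_real_, ainf_e),
    ac50_e = ifelse(class == "inactive", NA_real_, ac50_e),
    n_e = ifelse(class == "inactive", NA_real_, n_e),
    max_kill = NA_real_, ac50_t = NA_real_, n_t = NA_real_,
    added_gfp = NA_real_, ac50_f = NA_real_, n_f = NA_real_)
}

test_that("noiseless saturating full rescue reaches the WT+DMSO level", {
  cfg <- noiseless_cfg(n_compounds = 1, seed = 1)
  # AC50 far below every tested concentration -> saturated everywhere
  sim <- simulate_campaign(cfg, truth = fixed_truth(ac50_e = 1e-9, n_e = 2))
  wt <- dplyr::filter(sim$plates, cell_line == "WT", treatment == "DMSO")
  top <- dplyr::filter(sim$plates, treatment == "COMPOUND",
                       assay_kind == "DISEASE_ASSAY",
                       concentration == max(concentration, na.rm = TRUE))
  expect_equal(top$gfp, mean(wt$gfp), tolerance = 1e-6)
})

test_that("noiseless null screen sits exactly on the RD16+DMSO baselines", {
  cfg <- noiseless_cfg(n_compounds = 3, seed = 1)
  truth <- dplyr::bind_rows(lapply(sprintf("C%04d", 1:3), fixed_truth,
                                   class = "inactive"))
  sim <- simulate_campaign(cfg, truth = truth)
  dis <- dplyr::filter(sim$plates, assay_kind == "DISEASE_ASSAY")
  dmso <- dplyr::filter(dis, treatment == "DMSO", cell_line == "RD16")
  cmp <- dplyr::filter(dis, treatment == "COMPOUND")
  expect_equal(cmp$gfp, rep(mean(dmso$gfp), nrow(cmp)))
  expect_equal(cmp$dapi, rep(mean(dmso$dapi), nrow(cmp)))
})

test_that("expected GFP is monotone in the efficacy amplitude", {
  cfg <- noiseless_cfg(n_compounds = 1, seed = 1)
  gfp_at <- function(ainf_e) {
    sim <- simulate_campaign(cfg, truth = fixed_truth(ainf_e = ainf_e,
                                                      ac50_e = 1e-4, n_e = 1))
    dplyr::filter(sim$plates, treatment == "COMPOUND",
                  assay_kind == "DISEASE_ASSAY")$gfp
  }
  amps <- seq(0.1, 1, by = 0.15)
  curves <- vapply(amps, gfp_at, numeric(7))
  for (i in seq_len(nrow(curves))) {
    expect_true(all(diff(curves[i, ]) >= 0))
  }
})

test_that("disease-line control deficits match the configured fractions", {
  ratio_se <- function(x, y) {
    r <- mean(x) / mean(y)
    list(r = r, se = r * sqrt(var(x) / length(x) / mean(x)^2 +
                                var(y) / length(y) / mean(y)^2))
  }
  ctrl_ratios <- function(cfg) {
    sim <- simulate_campaign(cfg)
    ctrl <- dplyr::filter(sim$plates, treatment == "DMSO",
                          assay_kind == "DISEASE_ASSAY")
    rd <- dplyr::filter(ctrl, cell_line == "RD16")
    wt <- dplyr::filter(ctrl, cell_line == "WT")
    list(gfp = ratio_se(rd$gfp, wt$gfp), dapi = ratio_se(rd$dapi, wt$dapi))
  }
  # artifact-free: pure Monte-Carlo error around the configured fractions
  clean <- ctrl_ratios(sim_config(seed = 1, gradient_amplitude = 0,
                                  edge_amplitude = 0))
  expect_lt(abs(clean$gfp$r - 0.4), 3 * clean$gfp$se)
  expect_lt(abs(clean$dapi$r - 0.5), 3 * clean$dapi$se)
  # full default config: gradients and edge offsets bias the control
  # columns slightly, by construction; the ratios stay close
  full <- ctrl_ratios(sim_config(seed = 1))
  expect_lt(abs(full$gfp$r - 0.4), 0.05)
  expect_lt(abs(full$dapi$r - 0.5), 0.05)
})

test_that("every plate carries enough vehicle controls", {
  sim <- simulate_campaign(sim_config(n_compounds = 50, seed = 2))
  counts <- sim$plates %>%
    dplyr::filter(treatment == "DMSO") %>%
    dplyr::count(plate_id, assay_kind, cell_line)
  own <- dplyr::filter(counts, cell_line != "WT")
  expect_true(all(own$n >= 16))
  dis <- dplyr::filter(counts, assay_kind == "DISEASE_ASSAY",
                       cell_line == "WT")
  expect_true(all(dis$n >= 8))
})

test_that("expected calls mirror the generative parameters analytically", {
  cfg <- sim_config(n_compounds = 1, seed = 1)
  call_for <- function(truth) {
    truth_to_expected_calls(truth, cfg)$expected_verdict
  }
  # clean efficacious compound in-range -> hit
  expect_equal(call_for(fixed_truth(ac50_e = 1e-4, n_e = 1)), "HIT")
  # inactive -> non-hit
  expect_equal(call_for(fixed_truth(class = "inactive")), "INACTIVE")
  # efficacious + equally potent autofluorescence -> removed by counter-screen
  tt <- fixed_truth(ac50_e = 1e-4, n_e = 1)
  tt$is_autofluorescent <- TRUE
  tt$added_gfp <- 500; tt$ac50_f <- 1e-4; tt$n_f <- 1
  expect_equal(call_for(tt), "AUTOFLUORESCENT")
  # same fluorophore but 100x less potent -> ratio clears the margin
  tt$ac50_f <- 1e-2
  expect_equal(call_for(tt), "HIT")
  # potent toxicity crushes the rescue -> toxic
  tt2 <- fixed_truth(ac50_e = 1e-4, n_e = 1)
  tt2$is_toxic <- TRUE
  tt2$max_kill <- 0.9; tt2$ac50_t <- 3e-4; tt2$n_t <- 1.5
  expect_equal(call_for(tt2), "TOXIC")
})
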