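test_that("noiseless self-generated Randles spectra are recovered to optimizer precision", {
  truth <- table4_m0()
  sp <- simulate_eis(truth, default_eis_frequencies(40))
  fit <- fit_circuit(sp, "M0_randles_w")
  expect_true(fit$converged)
  rel <- abs(coef(fit) / truth$parameters - 1)
  expect_true(all(rel < 1e-3))
  expect_true(all(fit$uncertainties >= 0 | is.na(fit$uncertainties)))
  expect_gte(fit$chi_square, 0)
})

test_that("noisy spectra recover parameters with bounded median error", {
  # fixture with every element resolved inside the sweep: charge-transfer arc
  # mid-window, diffusion knee near the low-frequency end
  truth <- circuit_spec("M0_randles_w",
                        c(Rs = 100, CPE_T = 1e-6, CPE_P = 0.85, Rct = 2e3,
                          W_R = 3e3, W_T = 10, W_P = 0.5))
  f <- 10^seq(4, -2, length.out = 50)
  errs <- sapply(1:30, function(s) {
    sp <- simulate_eis(truth, f, noise_fraction = 0.01, seed = s)
    abs(coef(fit_circuit(sp, "M0_randles_w")) / truth$parameters - 1)
  })
  expect_true(all(apply(errs, 1L, median) < 0.10))
})

test_that("refitting from a converged solution does not increase chi-square", {
  sp <- simulate_eis(table4_m0(), default_eis_frequencies(40),
                     noise_fraction = 0.01, seed = 2)
  fit1 <- fit_circuit(sp, "M0_randles_w")
  fit2 <- fit_circuit(sp, "M0_randles_w", initial_guess = fit1$circuit,
                      n_starts = 1)
  expect_lte(fit2$chi_square, fit1$chi_square * (1 + 1e-8))
})

test_that("model selection penalizes superfluous circuit blocks and finds needed ones", {
  f <- default_eis_frequencies(40)
  m1_truth <- circuit_spec("M1_randles_w_extra",
    c(Rs = 100, CPE_T = 1e-5, CPE_P = 0.9, Rct = 1e3, W_R = 500, W_T = 0.1,
      W_P = 0.5, CPE2_T = 5e-5, CPE2_P = 0.9, R2 = 1e3))
  sp1 <- simulate_eis(m1_truth, f, noise_fraction = 0.002, seed = 11)
  sel1 <- select_circuit(sp1)
  expect_identical(sel1$best, "M1_randles_w_extra")

  sp0 <- simulate_eis(table4_m0(), f, noise_fraction = 0.002, seed = 12)
  sel0 <- select_circuit(sp0)
  expect_identical(sel0$best, "M0_randles_w")
})

test_that("AIC ties break toward the smaller circuit", {
  pick <- aptascreen:::choose_best_fit
  expect_identical(pick(c(10, 10 + 1e-12), c(9, 7)), 2L)
  expect_identical(pick(c(10, 10 + 1e-12), c(5, 7)), 1L)
  expect_identical(pick(c(10, 12), c(9, 2)), 1L)
})

test_that("effective capacitance reduces to T at alpha = 1 and follows the Brug form", {
  expect_equal(effective_capacitance(1e-5, 1, "hsu_mansfeld", omega_peak = 50),
               1e-5)
  expect_equal(effective_capacitance(1e-5, 1, "brug", Rs = 100, Rct = 1e4),
               1e-5)
  C_brug <- effective_capacitance(1e-5, 0.9, "brug", Rs = 100, Rct = 1e4)
  expect_equal(C_brug, (1e-5)^(1 / 0.9) * (1 / 100 + 1 / 1e4)^((0.9 - 1) / 0.9))
  expect_error(effective_capacitance(1e-5, 0.9, "hsu_mansfeld"), "omega_peak")
  expect_error(effective_capacitance(1e-5, 0.9, "brug", Rs = 100), "Rs and Rct")

  # both conversions agree to within a factor of two on a single-arc spectrum
  Rs <- 100; Rct <- 2e3; Tc <- 1e-5; al <- 0.85
  circ <- circuit_spec("M0_randles_w", c(Rs = Rs, CPE_T = Tc, CPE_P = al,
                                         Rct = Rct, W_R = 1e-9, W_T = 1,
                                         W_P = 0.5))
  sp <- circuit_impedance(circ, 10^seq(5, -2, length.out = 400))
  w_peak <- 2 * pi * sp$frequencies[which.max(-Im(sp$impedance))]
  C_hm <- effective_capacitance(Tc, al, "hsu_mansfeld", omega_peak = w_peak)
  C_br <- effective_capacitance(Tc, al, "brug", Rs = Rs, Rct = Rct)
  expect_lt(max(C_hm / C_br, C_br / C_hm), 2)
})

test_that("the decision rule combines the CPE1 drop and CPE2 rise as stated", {
  fake_fit <- function(T1, T2, converged = TRUE) {
    structure(list(circuit = circuit_spec("M2_nonfaradaic",
                     c(Rs = 100, CPE1_T = T1, CPE1_P = 0.9, Rp1 = 500,
                       CPE2_T = T2, CPE2_P = 0.85, Rp2 = 1e4,
                       W_R = 5e3, W_T = 0.2, W_P = 0.45)),
                   converged = converged),
              class = "circuit_fit")
  }
  # two-orders drop with CPE2 rise: positive
  expect_identical(as.character(eis_decision_rule(fake_fit(4e-5, 1e-5),
                                                  fake_fit(4e-7, 3e-5))),
                   "LC_positive")
  # identical fits: negative
  expect_identical(as.character(eis_decision_rule(fake_fit(4e-5, 1e-5),
                                                  fake_fit(4e-5, 1e-5))),
                   "negative")
  # drop without the CPE2 rise: negative
  expect_identical(as.character(eis_decision_rule(fake_fit(4e-5, 1e-5),
                                                  fake_fit(4e-7, 0.5e-5))),
                   "negative")
  # non-converged fit: indeterminate, with detail retained
  r <- eis_decision_rule(fake_fit(4e-5, 1e-5), fake_fit(4e-7, 3e-5, FALSE))
  expect_identical(as.character(r), "indeterminate")
  expect_equal(attr(r, "detail")$log10_cpe1_drop, 2, tolerance = 1e-12)
})

test_that("predict/residuals/coef methods are mutually consistent", {
  sp <- simulate_eis(table4_m0(), default_eis_frequencies(40))
  fit <- fit_circuit(sp, "M0_randles_w")
  expect_identical(names(coef(fit)), names(table4_m0()$parameters))
  pr <- predict(fit)
  expect_s3_class(pr, "impedance_spectrum")
  expect_equal(sp$impedance - pr$impedance, residuals(fit), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 4, noise_fraction = 0.01)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "impedance_spectrum")
})
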