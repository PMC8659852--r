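test_that("the CPE interpolates between capacitor and resistor and matches the direct formula", {
  expect_equal(z_cpe(1e-6, 1, 1e3), complex(real = 0, imaginary = -1000),
               tolerance = 1e-12)
  expect_equal(Re(z_cpe(0.01, 1e-9, 1)), 100, tolerance = 1e-4)
  # fitted-parameter scale: T = 4.2e-5, alpha = 0.72 at 100 Hz
  w <- 2 * pi * 100
  z <- z_cpe(4.2e-5, 0.72, w)
  expect_equal(Mod(z), 1 / (4.2e-5 * w^0.72), tolerance = 1e-12)
  expect_equal(Arg(z) * 180 / pi, -64.8, tolerance = 1e-6)
  expect_error(z_cpe(1e-6, 1.2, 1), "\\(0, 1\\]")
})

test_that("Warburg variants have the expected limits and constant -45 degree phase", {
  expect_equal(z_warburg(100, variant = "semi_infinite", omega = 1),
               complex(real = 100, imaginary = -100), tolerance = 1e-12)
  ws <- z_warburg(100, variant = "semi_infinite", omega = 10^seq(-2, 4))
  expect_true(all(abs(Arg(ws) * 180 / pi + 45) < 1e-9))
  # generalized short at large omega*tau scales like the semi-infinite element
  zs <- z_warburg(1000, 0.5, "generalized_short", omega = c(1e4, 4e4), tau = 1)
  expect_equal(Mod(zs[1]) / Mod(zs[2]), 2, tolerance = 0.01)
  # open (reflective) variant diverges capacitively at low frequency
  zo <- z_warburg(1000, 0.5, "generalized_open", omega = 1e-4, tau = 1)
  expect_gt(Mod(zo), 1e4)
  expect_error(z_warburg(100, 1.5, "generalized_short", omega = 1), "\\(0, 1\\)")
})

test_that("the Randles limit reproduces the textbook RC semicircle", {
  Rs <- 100; Rct <- 2e3; C <- 1e-6
  circ <- circuit_spec("M0_randles_w",
                       c(Rs = Rs, CPE_T = C, CPE_P = 1, Rct = Rct,
                         W_R = 1e-9, W_T = 1, W_P = 0.5))
  f <- 10^seq(5, -2, length.out = 600)
  sp <- circuit_impedance(circ, f)
  apex <- which.max(-Im(sp$impedance))
  w_apex <- 2 * pi * sp$frequencies[apex]
  expect_equal(w_apex, 1 / (Rct * C), tolerance = 0.05)
  expect_equal(max(Re(sp$impedance)) - Rs, Rct, tolerance = 1e-3)
})

test_that("the series resistance dominates at high frequency", {
  sp <- circuit_impedance(default_cohort_circuit(), 1e6)
  expect_equal(Re(sp$impedance), 100, tolerance = 0.01)
})

test_that("the two-interface circuit equals the hand-composed sum of its blocks", {
  circ <- default_cohort_circuit()
  p <- as.list(circ$parameters)
  f <- default_eis_frequencies(20)
  w <- 2 * pi * f
  parallel <- function(a, b) 1 / (1 / a + 1 / b)
  zw <- z_warburg(p$W_R, p$W_P, "generalized_short", w, tau = p$W_T)
  by_hand <- p$Rs +
    parallel(z_cpe(p$CPE1_T, p$CPE1_P, w), p$Rp1) +
    parallel(z_cpe(p$CPE2_T, p$CPE2_P, w), p$Rp2 + zw)
  expect_equal(circuit_impedance(circ, f)$impedance, by_hand, tolerance = 1e-12)
})

test_that("forward model real part is non-increasing with frequency for all topologies", {
  f <- 10^seq(4, -1, length.out = 300)
  circs <- list(
    table4_m0(),
    circuit_spec("M1_randles_w_extra",
                 c(Rs = 100, CPE_T = 1e-5, CPE_P = 0.9, Rct = 1e3, W_R = 500,
                   W_T = 0.1, W_P = 0.5, CPE2_T = 5e-5, CPE2_P = 0.9, R2 = 1e3)),
    default_cohort_circuit())
  for (circ in circs) {
    sp <- circuit_impedance(circ, f)
    expect_true(all(diff(Re(sp$impedance)[order(sp$frequencies)]) <= 1e-9))
  }
})

test_that("Cole-Cole transform satisfies the capacitor, resistor and series-RC identities", {
  f <- 10^seq(3, 0, length.out = 20)
  w <- 2 * pi * f
  # capacitor: C' = C at every frequency, C'' = 0
  cap <- cole_cole_transform(simulate_eis(circuit_spec("cpe",
    c(CPE_T = 1e-6, CPE_P = 1)), f))
  expect_equal(cap$C_real, rep(1e-6, 20), tolerance = 1e-9)
  expect_equal(cap$C_imag, rep(0, 20), tolerance = 1e-15)
  # resistor: C' = 0, C'' = 1/(omega R)
  res <- cole_cole_transform(impedance_spectrum(f, rep(complex(real = 100,
                                                               imaginary = 0),
                                                       length(f))))
  expect_equal(res$C_real, rep(0, 20), tolerance = 1e-15)
  expect_equal(res$C_imag, 1 / (res$angular_frequencies * 100), tolerance = 1e-12)
  # series RC at omega = 1/(RC): C' = C/2
  R <- 100; C <- 1e-6
  w0 <- 1 / (R * C)
  Z <- R + 1 / (1i * w0 * C)
  rc <- cole_cole_transform(impedance_spectrum(w0 / (2 * pi), Z))
  expect_equal(rc$C_real, C / 2, tolerance = 1e-12)
})

test_that("EIS features find the plateau capacitance and relaxation extrema", {
  f <- 10^seq(3, 0, length.out = 40)
  cap <- cole_cole_transform(simulate_eis(circuit_spec("cpe",
    c(CPE_T = 2e-6, CPE_P = 1)), f))
  feats <- extract_eis_features(cap)
  expect_equal(feats$C_dl, 2e-6, tolerance = 1e-9)
  expect_true(is.na(feats$omega_min) && is.na(feats$omega_max))

  m2 <- cole_cole_transform(simulate_eis(default_cohort_circuit(), f))
  fm2 <- extract_eis_features(m2)
  expect_true(is.finite(fm2$C_dl) && fm2$C_dl > 0)
  if (is.finite(fm2$omega_min)) {
    expect_identical(fm2$C_min,
                     m2$C_real[which(m2$angular_frequencies == fm2$omega_min)])
  }

  flipped <- m2
  ord <- order(flipped$angular_frequencies)
  flipped$angular_frequencies <- flipped$angular_frequencies[ord]
  flipped$C_real <- flipped$C_real[ord]
  flipped$C_imag <- flipped$C_imag[ord]
  expect_identical(extract_eis_features(flipped), fm2)

  short <- m2
  short$angular_frequencies <- short$angular_frequencies[1:5]
  short$C_real <- short$C_real[1:5]; short$C_imag <- short$C_imag[1:5]
  expect_error(extract_eis_features(short), "8 points")
})
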