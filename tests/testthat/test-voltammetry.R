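test_that("baseline fit recovers an exact line and a flat pre-peak window", {
  seg <- make_segment(function(E) 2.0e-6 * E + 1.0e-7)
  b <- estimate_baseline(seg)
  expect_equal(b$slope, 2.0e-6, tolerance = 1e-10)
  expect_equal(b$intercept, 1.0e-7, tolerance = 1e-10)

  seg2 <- gaussian_segment(mu = 0.15, s = 0.05)   # peak well past the leading 20%
  b2 <- estimate_baseline(seg2, 0.2)
  expect_lt(abs(b2$slope), 1e-12)

  expect_error(estimate_baseline(seg, 0.6), "\\(0, 0.5\\]")
  short <- list(potential = 1:10 / 10, current = rep(0, 10), direction = 1)
  expect_error(estimate_baseline(short, 0.2), "fewer than 5")
})

test_that("baseline slope is unbiased on noisy segments", {
  ests <- vapply(1:100, function(s) {
    seg <- gaussian_segment(mu = 0.3, s = 0.05, slope = 2e-6, intercept = 1e-7,
                            noise_sd = 2e-8, seed = s)
    estimate_baseline(seg)$slope
  }, 0)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 2e-6), 3 * se)
})

test_that("peak location round-trips the generator and rejects monotone traces", {
  cv <- simulate_cv(cv_shape(noise_sd = 0))
  fwd <- cv$segments$forward
  pk <- find_peak(fwd, estimate_baseline(fwd))
  expect_lt(abs(pk$E_peak - 0.30), grid_step(fwd) + 1e-12)

  mono <- make_segment(function(E) 1e-6 * E)
  expect_error(find_peak(mono, estimate_baseline(mono)), "no peak")

  two <- make_segment(function(E)
    1e-5 * exp(-(E - 0.0)^2 / (2 * 0.04^2)) +
    2e-5 * exp(-(E - 0.4)^2 / (2 * 0.04^2)))
  pk2 <- find_peak(two, estimate_baseline(two))
  expect_lt(abs(pk2$E_peak - 0.4), 0.01)
})

test_that("onset matches the analytic Gaussian inversion and is monotone in the threshold", {
  s <- 0.05
  seg <- gaussian_segment(mu = 0.3, s = s)
  b <- estimate_baseline(seg)
  pk <- find_peak(seg, b)
  on5 <- peak_onset(seg, b, pk, 0.05)
  expect_lt(abs(on5$E_init - (0.3 - s * sqrt(2 * log(20)))),
            grid_step(seg) + 1e-12)
  on100 <- peak_onset(seg, b, pk, 1.0)
  expect_equal(on100$E_init, pk$E_peak)
  onsets <- vapply(c(0.02, 0.05, 0.1, 0.3, 0.6), function(th)
    peak_onset(seg, b, pk, th)$E_init, 0)
  expect_true(all(diff(onsets) >= 0))
})

test_that("width and shape follow the closed-form Gaussian geometry and are scale-invariant", {
  s <- 0.05
  seg <- gaussian_segment(mu = 0.3, s = s, n = 2001L)
  b <- estimate_baseline(seg)
  pk <- find_peak(seg, b)
  ws <- peak_width_shape(seg, b, pk)
  expect_equal(ws$E_w, 2 * s * sqrt(2 * log(2)), tolerance = 2e-3)
  expect_equal(ws$E_sh, 1.0, tolerance = 0.02)

  cv <- simulate_cv(cv_shape(noise_sd = 0, baseline_slope = 0,
                             baseline_offset = 0))
  fa <- extract_cv_features(cv)
  expect_lt(fa$Esh_a, 1)   # diffusional tail after the peak

  seg10 <- seg; seg10$current <- seg$current * 10
  ws10 <- peak_width_shape(seg10, estimate_baseline(seg10),
                           find_peak(seg10, estimate_baseline(seg10)))
  expect_equal(ws10$E_w, ws$E_w)
  expect_equal(ws10$E_sh, ws$E_sh)

  edge <- gaussian_segment(mu = 0.78, s = 0.05)
  bedg <- estimate_baseline(edge)
  expect_error(peak_width_shape(edge, bedg, find_peak(edge, bedg)),
               "departure-side")
})

test_that("peak areas integrate a rectangle exactly, track the analytic area, and are linear", {
  h <- 1e-5; w <- 0.2
  seg <- make_segment(function(E) ifelse(E >= 0.2 & E <= 0.2 + w, h, 0),
                      n = 1301L)
  b <- estimate_baseline(seg)
  pk <- find_peak(seg, b)
  S <- peak_area(seg, b, pk)
  expect_lt(abs(S - h * w), h * grid_step(seg) + 1e-12)

  cv <- simulate_cv(cv_shape(noise_sd = 0), points_per_segment = 500L)
  fwd <- cv$segments$forward
  bb <- estimate_baseline(fwd)
  pp <- find_peak(fwd, bb)
  S1 <- peak_area(fwd, bb, pp, threshold_fraction = 0.01)
  expect_equal(S1, cv$metadata$anodic_area, tolerance = 0.01)

  fwd2 <- fwd; fwd2$current <- 2 * fwd$current
  bb2 <- estimate_baseline(fwd2)
  S2 <- peak_area(fwd2, bb2, find_peak(fwd2, bb2), threshold_fraction = 0.01)
  expect_equal(S2 / S1, 2, tolerance = 1e-9)
})

test_that("derived CV features satisfy their defining identities exactly", {
  cv <- simulate_cv(cv_shape(noise_sd = 0))
  f <- extract_cv_features(cv)
  expect_identical(f$dE, abs(f$Ea - f$Ec))
  expect_identical(f$R_I, f$Ia / f$Ic)
  expect_identical(f$R_S, f$Sa / f$Sc)
  expect_identical(f$E_half, 0.5 * (f$Ea + f$Ec))
  step <- 1.3 / 259
  expect_lt(abs(f$Ea - 0.30), step)
  expect_lt(abs(f$Ec - 0.20), step)
  expect_lt(abs(f$dE - 0.10), 2 * step)
  expect_lt(abs(f$E_half - 0.25), step)
})

test_that("extraction stays finite and identity-consistent across random noisy sensors", {
  set.seed(99)
  for (s in sample.int(1e6, 12)) {
    sh <- cv_shape(anodic_peak_current = 10^runif(1, -5.5, -4.5),
                   cathodic_peak_current = 10^runif(1, -5.5, -4.5),
                   noise_sd = 5e-8)
    f <- extract_cv_features(simulate_cv(sh, seed = s))
    vals <- unlist(f[c("Ea", "Ec", "Einit_a", "Einit_c", "dE", "Ew_a", "Ew_c",
                       "Esh_a", "Esh_c", "Ia", "Ic", "Sa", "Sc", "R_I", "R_S",
                       "E_half")])
    expect_true(all(is.finite(vals)))
    expect_true(all(c(f$Ia, f$Ic, f$Ew_a, f$Ew_c, f$Esh_a, f$Esh_c,
                      f$Sa, f$Sc) > 0))
    expect_identical(f$dE, abs(f$Ea - f$Ec))
    expect_identical(f$E_half, 0.5 * (f$Ea + f$Ec))
  }
})

test_that("surface coverage round-trips the generator and is scale-invariant", {
  cv <- simulate_cv(cv_shape(noise_sd = 0))
  expect_equal(surface_coverage(cv, cv), 0)

  p96 <- simulate_coverage_pair(96, cv_shape(noise_sd = 0))
  expect_equal(surface_coverage(p96$before, p96$after), 96, tolerance = 0.5 / 96)

  p68 <- simulate_coverage_pair(68, cv_shape(noise_sd = 0))
  cov68 <- surface_coverage(p68$before, p68$after)
  expect_equal(cov68, 68, tolerance = 0.5 / 68)

  scaled <- function(cv, k) {
    voltammogram(list(potential = cv$segments$forward$potential,
                      current = cv$segments$forward$current * k),
                 list(potential = cv$segments$reverse$potential,
                      current = cv$segments$reverse$current * k),
                 scan_rate = cv$scan_rate)
  }
  expect_equal(surface_coverage(scaled(p68$before, 3), scaled(p68$after, 3)),
               cov68, tolerance = 1e-9)

  grown <- simulate_coverage_pair(0, cv_shape(noise_sd = 0))
  bigger <- scaled(grown$after, 1.5)
  expect_warning(cov_neg <- surface_coverage(grown$before, bigger), "negative")
  expect_lt(cov_neg, 0)
  expect_true(isTRUE(attr(cov_neg, "negative")))
})

test_that("halving the potential step moves peak statistics by less than the coarse step", {
  sh <- cv_shape(noise_sd = 0)
  coarse <- extract_cv_features(simulate_cv(sh, points_per_segment = 260L))
  fine <- extract_cv_features(simulate_cv(sh, points_per_segment = 520L))
  step <- 1.3 / 259
  expect_lt(abs(coarse$Ea - fine$Ea), step)
  expect_lt(abs(coarse$Ew_a - fine$Ew_a), step)
  expect_lt(abs(coarse$Sa - fine$Sa) / fine$Sa, step)
})
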