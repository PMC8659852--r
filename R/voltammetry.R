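#' Estimate a linear baseline for a sweep segment
#'
#' Least-squares line through the leading `pre_peak_fraction` of the segment
#' (the approach side of the peak, in sweep order) -- the conventional tangent
#' baseline for voltammetric peak quantification.
#'
#' @param segment A segment of a [voltammogram()] (list with `potential`,
#'   `current`, `direction`).
#' @param pre_peak_fraction Fraction of leading points used, in (0, 0.5].
#' @return List with `slope` (A/V), `intercept` (A), and `residual_sd` (A,
#'   the fit's residual standard deviation, used as a noise estimate).
#' @export
estimate_baseline <- function(segment, pre_peak_fraction = 0.2) {
  if (!is_number(pre_peak_fraction) || pre_peak_fraction <= 0 || pre_peak_fraction > 0.5)
    stop_apt("estimate_baseline: pre_peak_fraction must lie in (0, 0.5]")
  n <- length(segment$potential)
  m <- floor(pre_peak_fraction * n)
  if (m < 5L)
    stop_apt("estimate_baseline: fewer than 5 points in the baseline window")
  idx <- seq_len(m)
  fit <- lm(segment$current[idx] ~ segment$potential[idx])
  res <- fit$residuals
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       residual_sd = if (m > 2L) sd(res) else 0)
}

# baseline-corrected current in "peak-positive" orientation: anodic branches
# (forward sweep) keep their sign, cathodic branches are negated so the peak
# is a positive excursion in both cases
corrected_current <- function(segment, baseline) {
  corr <- segment$current - (baseline$slope * segment$potential + baseline$intercept)
  if (segment$direction < 0) -corr else corr
}

#' Locate the peak of a sweep segment
#'
#' Finds the extremum of the baseline-corrected current: the maximum on an
#' anodic (forward) branch, the minimum (largest negative excursion) on a
#' cathodic (reverse) branch.  The extremum must be interior to the segment
#' and exceed a signal-to-noise floor of five baseline residual standard
#' deviations; otherwise a "no peak" error is raised.
#'
#' @inheritParams estimate_baseline
#' @param baseline Output of [estimate_baseline()].
#' @return List with `E_peak` (V), `I_peak` (A, baseline-corrected magnitude)
#'   and `index` (grid index of the peak).
#' @export
find_peak <- function(segment, baseline) {
  y <- corrected_current(segment, baseline)
  n <- length(y)
  idx <- which.max(y)
  if (idx == 1L || idx == n)
    stop_apt("no peak: extremum lies on the segment boundary (monotone trace?)",
             class = "aptascreen_no_peak")
  floor_snr <- 5 * baseline$residual_sd
  if (y[idx] <= floor_snr || y[idx] <= 0)
    stop_apt("no peak: no interior extremum above the signal-to-noise floor",
             class = "aptascreen_no_peak")
  list(E_peak = segment$potential[idx], I_peak = y[idx], index = idx)
}

# indices of the contiguous run around the peak where the corrected current
# stays at or above `level`; walk outward from the peak
sustained_run <- function(y, peak_index, level) {
  i0 <- peak_index
  while (i0 > 1L && y[i0 - 1L] >= level) i0 <- i0 - 1L
  i1 <- peak_index
  n <- length(y)
  while (i1 < n && y[i1 + 1L] >= level) i1 <- i1 + 1L
  c(i0, i1)
}

#' Peak onset potential and current
#'
#' The first potential, sweeping toward the peak, at which the
#' baseline-corrected current magnitude exceeds
#' `threshold_fraction * I_peak` and remains above it until the peak.
#'
#' @inheritParams find_peak
#' @param peak Output of [find_peak()].
#' @param threshold_fraction Onset threshold as a fraction of peak height,
#'   in (0, 1].
#' @return List with `E_init` (V) and `I_init` (A, the raw current at onset).
#' @export
peak_onset <- function(segment, baseline, peak, threshold_fraction = 0.05) {
  if (!is_number(threshold_fraction) || threshold_fraction <= 0 || threshold_fraction > 1)
    stop_apt("peak_onset: threshold_fraction must lie in (0, 1]")
  y <- corrected_current(segment, baseline)
  level <- threshold_fraction * peak$I_peak
  run <- sustained_run(y, peak$index, level)
  i <- run[1L]
  if (!is.finite(y[i]) || y[i] < level)
    stop_apt("peak_onset: onset threshold never crossed (degenerate flat peak)")
  list(E_init = segment$potential[i], I_init = segment$current[i])
}

#' Peak width and shape parameters
#'
#' Full width at half of the baseline-corrected peak height (`E_w`), with
#' crossings located by linear interpolation, and the shape ratio
#' `E_sh = (E_peak - E_approach_half) / (E_departure_half - E_peak)` with the
#' half-height crossings taken in sweep direction.  A symmetric peak has
#' `E_sh = 1`; a diffusional tail after the peak gives `E_sh < 1`.  Both are
#' invariant to scaling the current by a positive constant.
#'
#' @inheritParams peak_onset
#' @return List with `E_w` (V) and `E_sh` (dimensionless).
#' @export
peak_width_shape <- function(segment, baseline, peak) {
  y <- corrected_current(segment, baseline)
  E <- segment$potential
  half <- peak$I_peak / 2
  n <- length(y)
  i <- peak$index
  while (i > 1L && y[i] >= half) i <- i - 1L
  if (y[i] >= half)
    stop_apt("peak_width_shape: approach-side half-height crossing lies outside ",
             "the recorded window")
  E_left <- cross_interp(E, y, i, half)
  j <- peak$index
  while (j < n && y[j] >= half) j <- j + 1L
  if (y[j] >= half)
    stop_apt("peak_width_shape: departure-side half-height crossing lies outside ",
             "the recorded window")
  E_right <- cross_interp(E, y, j - 1L, half)
  E_w <- abs(E_right - E_left)
  E_sh <- abs(peak$E_peak - E_left) / abs(E_right - peak$E_peak)
  if (E_w <= 0 || !is.finite(E_sh) || E_sh <= 0)
    stop_apt("peak_width_shape: degenerate half-height geometry")
  list(E_w = E_w, E_sh = E_sh)
}

#' Baseline-corrected peak area
#'
#' Trapezoidal integral of the baseline-corrected current magnitude over
#' potential, between the onset-threshold crossings on both flanks (clipped to
#' the recorded segment).
#'
#' @inheritParams peak_onset
#' @return Area `S` (A.V), strictly positive.
#' @export
peak_area <- function(segment, baseline, peak, threshold_fraction = 0.05) {
  y <- corrected_current(segment, baseline)
  level <- threshold_fraction * peak$I_peak
  run <- sustained_run(y, peak$index, level)
  idx <- run[1L]:run[2L]
  if (length(idx) < 2L) stop_apt("peak_area: empty integration window")
  E <- segment$potential[idx]
  S <- sum(diff(E) * (y[idx][-1L] + y[idx][-length(idx)]) / 2)
  S <- abs(S)
  if (S <= 0) stop_apt("peak_area: non-positive area")
  S
}

# full descriptor for one branch
describe_peak <- function(segment, branch, baseline_fraction, onset_fraction) {
  wrap <- function(expr) {
    tryCatch(expr, error = function(e) {
      stop_apt(branch, " branch: ", conditionMessage(e),
               class = class(e)[1L])
    })
  }
  baseline <- wrap(estimate_baseline(segment, baseline_fraction))
  peak <- wrap(find_peak(segment, baseline))
  onset <- wrap(peak_onset(segment, baseline, peak, onset_fraction))
  ws <- wrap(peak_width_shape(segment, baseline, peak))
  S <- wrap(peak_area(segment, baseline, peak, onset_fraction))
  list(branch = branch, E_peak = peak$E_peak, I_peak = peak$I_peak,
       E_init = onset$E_init, I_init = onset$I_init,
       E_w = ws$E_w, E_sh = ws$E_sh, S = S, baseline = baseline)
}

#' Extract the full set of CV base-features
#'
#' Runs baseline estimation, peak location, onset, width/shape and area on
#' both branches of a voltammogram and assembles the base-feature set:
#' peak potentials `Ea`/`Ec`, onsets `Einit_a`/`Einit_c` with currents
#' `Iinit_a`/`Iinit_c`, widths `Ew_a`/`Ew_c`, shapes `Esh_a`/`Esh_c`, peak
#' currents `Ia`/`Ic`, areas `Sa`/`Sc`, and the derived scalars
#' `dE = |Ea - Ec|`, `R_I = Ia/Ic`, `R_S = Sa/Sc`,
#' `E_half = 0.5 (Ea + Ec)`.
#'
#' @param cv A [voltammogram()].
#' @param onset_fraction Onset threshold fraction (see [peak_onset()]).
#' @param baseline_fraction Leading fraction for [estimate_baseline()].
#' @return Object of class `cv_features`: a named list of the scalars above
#'   plus `anodic`/`cathodic` peak descriptors.
#' @examples
#' f <- extract_cv_features(simulate_cv(cv_shape(noise_sd = 0)))
#' c(f$Ea, f$Ec, f$dE, f$E_half)
#' @export
extract_cv_features <- function(cv, onset_fraction = 0.05,
                                baseline_fraction = 0.2) {
  if (!inherits(cv, "voltammogram"))
    stop_apt("extract_cv_features: `cv` must be a voltammogram")
  an <- describe_peak(cv$segments$forward, "anodic", baseline_fraction, onset_fraction)
  ca <- describe_peak(cv$segments$reverse, "cathodic", baseline_fraction, onset_fraction)
  out <- list(Ea = an$E_peak, Ec = ca$E_peak,
              Einit_a = an$E_init, Einit_c = ca$E_init,
              dE = abs(an$E_peak - ca$E_peak),
              Ew_a = an$E_w, Ew_c = ca$E_w,
              Esh_a = an$E_sh, Esh_c = ca$E_sh,
              Ia = an$I_peak, Ic = ca$I_peak,
              Iinit_a = an$I_init, Iinit_c = ca$I_init,
              Sa = an$S, Sc = ca$S,
              R_I = an$I_peak / ca$I_peak,
              R_S = an$S / ca$S,
              E_half = 0.5 * (an$E_peak + ca$E_peak),
              anodic = an, cathodic = ca)
  structure(out, class = "cv_features")
}

#' @export
print.cv_features <- function(x, ...) {
  cat("CV base-features\n")
  cat(sprintf("  Ea = %.4f V, Ec = %.4f V, dE = %.4f V, E1/2 = %.4f V\n",
              x$Ea, x$Ec, x$dE, x$E_half))
  cat(sprintf("  Ia = %.3e A, Ic = %.3e A, R(I) = %.3f\n", x$Ia, x$Ic, x$R_I))
  cat(sprintf("  Sa = %.3e A.V, Sc = %.3e A.V, R(S) = %.3f\n", x$Sa, x$Sc, x$R_S))
  invisible(x)
}

#' Surface coverage from a before/after voltammogram pair
#'
#' The percentage attenuation of the redox-probe oxidation (anodic) peak after
#' layer immobilization: `coverage = (1 - S_after / S_before) * 100`, with `S`
#' the baseline-corrected anodic peak area (or peak height with
#' `method = "height"`).  A physically odd negative coverage (after-peak larger
#' than before) is returned with a warning and an attribute flag rather than
#' an error.
#'
#' @param cv_before,cv_after [voltammogram()]s recorded under the same scan
#'   conditions.
#' @param method `"area"` (default) or `"height"`.
#' @param onset_fraction,baseline_fraction Extraction settings, see
#'   [extract_cv_features()].
#' @return Coverage in percent; negative values carry attribute
#'   `negative = TRUE`.
#' @export
surface_coverage <- function(cv_before, cv_after, method = c("area", "height"),
                             onset_fraction = 0.05, baseline_fraction = 0.2) {
  method <- match.arg(method)
  stat <- function(cv) {
    seg <- cv$segments$forward
    baseline <- estimate_baseline(seg, baseline_fraction)
    peak <- find_peak(seg, baseline)
    if (method == "height") peak$I_peak
    else peak_area(seg, baseline, peak, onset_fraction)
  }
  s_before <- stat(cv_before)
  s_after <- stat(cv_after)
  cov <- (1 - s_after / s_before) * 100
  if (cov < 0) {
    warning("surface_coverage: after-incubation peak exceeds the before peak; ",
            "negative coverage returned")
    attr(cov, "negative") <- TRUE
  }
  cov
}
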