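#' Cyclic-voltammogram shape parameters
#'
#' Bundles the generative description of a one-cycle redox-probe voltammogram:
#' one asymmetric (exponentially modified Gaussian) peak per sweep branch on a
#' shared linear baseline.  The anodic peak sits on the forward (rising) sweep,
#' the cathodic peak -- with negative current -- on the reverse sweep.
#'
#' Defaults place the couple at 0.30/0.20 V with 10 uA peaks and a 50 mV width
#' scale; they are calibration knobs of the simulator, not measured constants.
#'
#' @param anodic_peak_potential,cathodic_peak_potential Peak potentials (V).
#'   The anodic peak must lie above the cathodic one.
#' @param anodic_peak_current,cathodic_peak_current Baseline-corrected peak
#'   heights (A, both given as positive magnitudes).
#' @param peak_width_scale Gaussian width scale sigma of both peaks (V).
#' @param peak_asymmetry Ratio tau/sigma of the exponential tail constant to
#'   the Gaussian width; larger values give a heavier diffusional tail in the
#'   sweep direction. Must be > 0.
#' @param baseline_slope,baseline_offset Linear capacitive baseline (A/V, A).
#' @param noise_sd Additive Gaussian current noise (A, >= 0).
#' @param cathodic_asymmetry Optional branch-specific tail ratio for the
#'   cathodic peak; `NA` (default) inherits `peak_asymmetry`.  Lets a
#'   perturbation reshape one branch only, as an analyte binding to the layer
#'   does.
#' @return An object of class `cv_shape`.
#' @examples
#' sh <- cv_shape()
#' sh$anodic_peak_potential
#' @export
cv_shape <- function(anodic_peak_potential = 0.30,
                     cathodic_peak_potential = 0.20,
                     anodic_peak_current = 1.0e-5,
                     cathodic_peak_current = 1.0e-5,
                     peak_width_scale = 0.05,
                     peak_asymmetry = 1.5,
                     baseline_slope = 2.0e-6,
                     baseline_offset = 1.0e-6,
                     noise_sd = 0,
                     cathodic_asymmetry = NA_real_) {
  if (is.na(cathodic_asymmetry)) cathodic_asymmetry <- peak_asymmetry
  s <- list(anodic_peak_potential = anodic_peak_potential,
            cathodic_peak_potential = cathodic_peak_potential,
            anodic_peak_current = anodic_peak_current,
            cathodic_peak_current = cathodic_peak_current,
            peak_width_scale = peak_width_scale,
            peak_asymmetry = peak_asymmetry,
            baseline_slope = baseline_slope,
            baseline_offset = baseline_offset,
            noise_sd = noise_sd,
            cathodic_asymmetry = cathodic_asymmetry)
  for (nm in names(s))
    if (!is_number(s[[nm]])) stop_apt("cv_shape: `", nm, "` must be a single finite number")
  if (s$anodic_peak_potential <= s$cathodic_peak_potential)
    stop_apt("cv_shape: anodic peak potential must exceed the cathodic peak potential")
  if (s$anodic_peak_current <= 0 || s$cathodic_peak_current <= 0)
    stop_apt("cv_shape: peak currents must be strictly positive")
  if (s$peak_width_scale <= 0) stop_apt("cv_shape: peak_width_scale must be > 0")
  if (s$peak_asymmetry <= 0 || s$cathodic_asymmetry <= 0)
    stop_apt("cv_shape: peak_asymmetry must be > 0")
  if (s$noise_sd < 0) stop_apt("cv_shape: noise_sd must be >= 0")
  structure(s, class = "cv_shape")
}

# exponentially modified Gaussian density (mean-zero Gaussian component),
# computed in logs for numerical stability:
#   emg(x) = 1/(2 tau) exp( (sigma^2/tau - 2 x) / (2 tau) ) erfc( (sigma^2/tau - x) / (sqrt(2) sigma) )
# integrates to 1 over the real line.
emg_density <- function(x, sigma, tau) {
  z <- (sigma^2 / tau - 2 * x) / (2 * tau)
  w <- (sigma^2 / tau - x) / (sqrt(2) * sigma)
  log_erfc <- log(2) + stats::pnorm(sqrt(2) * w, lower.tail = FALSE, log.p = TRUE)
  exp(-log(2 * tau) + z + log_erfc)
}

# mode location and density value at the mode of emg_density
emg_mode <- function(sigma, tau) {
  opt <- stats::optimize(function(x) emg_density(x, sigma, tau),
                         interval = c(-4 * sigma, 4 * sigma + 6 * tau),
                         maximum = TRUE, tol = 1e-12)
  list(x = opt$maximum, h = opt$objective)
}

# branch peak evaluated on a potential grid: height `i_peak` at `e_peak`,
# tail pointing in `direction` (+1 toward increasing E).  Returns the current
# contribution and, as an attribute, the exact analytic area (A * V).
emg_peak_current <- function(potential, e_peak, i_peak, sigma, asymmetry, direction) {
  tau <- asymmetry * sigma
  m <- emg_mode(sigma, tau)
  amp <- i_peak / m$h
  x <- direction * (potential - e_peak) + m$x
  cur <- amp * emg_density(x, sigma, tau)
  attr(cur, "area") <- amp
  cur
}

#' Analytic area of the simulator's peak function
#'
#' The exact integral over potential of a branch peak as produced by
#' [simulate_cv()], used as the closed-form oracle for trapezoidal peak areas.
#'
#' @param i_peak Peak height (A).
#' @param sigma Width scale (V).
#' @param asymmetry Tail ratio tau/sigma.
#' @return Area in A.V.
#' @export
emg_peak_area <- function(i_peak, sigma, asymmetry) {
  m <- emg_mode(sigma, asymmetry * sigma)
  i_peak / m$h
}
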