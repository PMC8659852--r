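#' Simulate a one-cycle cyclic voltammogram
#'
#' Generates a two-segment cycle (forward anodic sweep, reverse cathodic sweep)
#' for a reversible redox-probe couple.  Each segment is a linear capacitive
#' baseline plus one exponentially modified Gaussian peak -- the asymmetric
#' tail points in the sweep direction, mimicking the diffusional decay of a
#' real voltammetric wave -- plus optional additive Gaussian noise.  The
#' cathodic peak carries negative current.
#'
#' The default measurement geometry follows the aptasensor protocol: a
#' -0.5 to 0.8 V window at 0.03 V/s.
#'
#' @param shape A [cv_shape()] object.
#' @param window Length-2 potential window (V); must span both peak potentials.
#' @param scan_rate Scan rate (V/s), > 0.
#' @param points_per_segment Number of grid points per sweep segment (>= 50).
#' @param seed Optional integer seed; identical seeds give bit-identical traces.
#' @return A [voltammogram()] whose metadata records the generating shape and
#'   the exact analytic areas of both peaks (`anodic_area`, `cathodic_area`,
#'   in A.V).
#' @examples
#' cv <- simulate_cv(cv_shape(noise_sd = 0))
#' cv$metadata$anodic_area
#' @export
simulate_cv <- function(shape = cv_shape(), window = c(-0.5, 0.8),
                        scan_rate = 0.03, points_per_segment = 260L,
                        seed = NULL) {
  if (!inherits(shape, "cv_shape")) stop_apt("simulate_cv: `shape` must be a cv_shape object")
  if (length(window) != 2L || !all(is.finite(window)) || window[1] >= window[2])
    stop_apt("simulate_cv: `window` must be an increasing length-2 potential range")
  if (!is_number(scan_rate) || scan_rate <= 0)
    stop_apt("simulate_cv: scan rate must be strictly positive")
  if (points_per_segment < 50L)
    stop_apt("simulate_cv: points_per_segment must be >= 50")
  for (ep in c(shape$anodic_peak_potential, shape$cathodic_peak_potential))
    if (ep <= window[1] || ep >= window[2])
      stop_apt("simulate_cv: potential window [", window[1], ", ", window[2],
               "] excludes a configured peak potential (", ep, " V)")

  E_fwd <- seq(window[1], window[2], length.out = points_per_segment)
  E_rev <- rev(E_fwd)
  baseline <- function(E) shape$baseline_slope * E + shape$baseline_offset

  pk_a <- emg_peak_current(E_fwd, shape$anodic_peak_potential,
                           shape$anodic_peak_current, shape$peak_width_scale,
                           shape$peak_asymmetry, direction = +1)
  pk_c <- emg_peak_current(E_rev, shape$cathodic_peak_potential,
                           shape$cathodic_peak_current, shape$peak_width_scale,
                           shape$cathodic_asymmetry, direction = -1)
  I_fwd <- baseline(E_fwd) + as.numeric(pk_a)
  I_rev <- baseline(E_rev) - as.numeric(pk_c)

  if (shape$noise_sd > 0) {
    noise <- with_seed(seed, rnorm(2L * points_per_segment, sd = shape$noise_sd))
    I_fwd <- I_fwd + noise[seq_len(points_per_segment)]
    I_rev <- I_rev + noise[points_per_segment + seq_len(points_per_segment)]
  }

  voltammogram(forward = list(potential = E_fwd, current = I_fwd),
               reverse = list(potential = E_rev, current = I_rev),
               scan_rate = scan_rate,
               metadata = list(shape = shape,
                               anodic_area = attr(pk_a, "area"),
                               cathodic_area = attr(pk_c, "area"),
                               seed = seed))
}

#' Simulate a before/after voltammogram pair with a given surface coverage
#'
#' Produces two voltammograms whose anodic (oxidation) peak areas are related
#' by the stated surface coverage: the second peak area equals
#' `(1 - coverage_percent/100)` times the first, emulating the attenuation of
#' the redox-probe response after an electrode is partially blocked by an
#' immobilized monolayer.
#'
#' @param coverage_percent Target coverage, `0 <= coverage_percent < 100`.
#'   A fully blocked electrode (>= 100) is rejected: it has no measurable peak.
#' @param base_shape [cv_shape()] of the bare-electrode ("before") CV.
#' @param seed Optional integer seed (noise only).
#' @inheritParams simulate_cv
#' @return List with elements `before` and `after`, both [voltammogram()]s.
#' @export
simulate_coverage_pair <- function(coverage_percent, base_shape = cv_shape(),
                                   window = c(-0.5, 0.8), scan_rate = 0.03,
                                   points_per_segment = 260L, seed = NULL) {
  if (!is_number(coverage_percent) || coverage_percent < 0 || coverage_percent >= 100)
    stop_apt("simulate_coverage_pair: coverage must satisfy 0 <= coverage < 100 ",
             "(a fully blocked electrode has no measurable peak)")
  frac <- 1 - coverage_percent / 100
  after_shape <- base_shape
  after_shape$anodic_peak_current <- base_shape$anodic_peak_current * frac
  after_shape$cathodic_peak_current <- base_shape$cathodic_peak_current * frac
  list(before = simulate_cv(base_shape, window, scan_rate, points_per_segment,
                            seed = if (is.null(seed)) NULL else seed),
       after = simulate_cv(after_shape, window, scan_rate, points_per_segment,
                           seed = if (is.null(seed)) NULL else seed + 1L))
}
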