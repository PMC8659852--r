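#' Default non-Faradaic baseline circuit of the cohort simulator
#'
#' The population-mean two-interface circuit from which simulated sensors are
#' drawn: an electrode-surface relaxation (`CPE1`/`Rp1`, characteristic
#' frequency ~10 Hz) in series with a biolayer relaxation
#' (`CPE2`/`Rp2` plus a generalized finite-length Warburg tail, ~1 Hz), both
#' inside the 1 Hz - 1 kHz measurement window so that every element is
#' identifiable from a single sweep.
#'
#' @return A [circuit_spec()] on topology `M2_nonfaradaic`.
#' @export
default_cohort_circuit <- function() {
  circuit_spec("M2_nonfaradaic",
               c(Rs = 100, CPE1_T = 4e-5, CPE1_P = 0.9, Rp1 = 500,
                 CPE2_T = 1e-5, CPE2_P = 0.85, Rp2 = 1e4,
                 W_R = 5e3, W_T = 0.2, W_P = 0.45))
}

#' Cohort simulation configuration
#'
#' Study design of a synthetic before/after-plasma cohort: `n_lc` lung-cancer
#' and `n_h` healthy samples, each a paired CV + EIS measurement before and
#' after incubation.  Lung-cancer samples receive the configured
#' class-dependent effects (electrode-interface CPE magnitude divided by
#' `cpe1_drop`, biolayer CPE magnitude multiplied by `cpe2_rise`, cathodic
#' peak shifted, attenuated and reshaped); healthy samples receive only a
#' small symmetric drift.  Identical seeds reproduce the cohort bit-for-bit.
#'
#' @param n_lc,n_h Class sizes, both >= 2 (leave-one-out classification needs
#'   both classes in every training fold).
#' @param seed Integer seed.
#' @param lc_effect Named list of lung-cancer effect sizes:
#'   `cpe1_drop` (multiplicative drop factor of `CPE1_T`, default 30, the
#'   centre of a one-to-two-orders-of-magnitude drop), `cpe2_rise`
#'   (multiplicative rise of `CPE2_T`, default 3), `ec_shift` (cathodic peak
#'   potential shift, V), `ic_attenuation` (fractional cathodic current loss),
#'   `shape_factor` (multiplier of the cathodic tail asymmetry).
#' @param h_drift Log-scale SD of the symmetric healthy before/after drift
#'   applied to currents and circuit magnitudes (0 = identical pairs).
#' @param sensor_sd Log-scale SD of inter-sensor variability around the
#'   population baselines.
#' @param cv_noise_sd Additive CV current noise (A).
#' @param eis_noise Multiplicative EIS noise fraction.
#' @param base_shape Population-mean [cv_shape()].
#' @param base_circuit Population-mean [circuit_spec()] (topology
#'   `M2_nonfaradaic`).
#' @param frequencies EIS frequency grid (Hz).
#' @param window,scan_rate,points_per_segment CV measurement geometry.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_lc = 10L, n_h = 10L, seed = 1L,
                          lc_effect = list(), h_drift = 0.02,
                          sensor_sd = 0.05, cv_noise_sd = 1.5e-7,
                          eis_noise = 0.005,
                          base_shape = cv_shape(),
                          base_circuit = default_cohort_circuit(),
                          frequencies = default_eis_frequencies(),
                          window = c(-0.5, 0.8), scan_rate = 0.03,
                          points_per_segment = 260L) {
  if (n_lc < 2L || n_h < 2L)
    stop_apt("cohort_config: both classes need at least 2 samples")
  eff <- modifyList(list(cpe1_drop = 30, cpe2_rise = 3, ec_shift = 0.02,
                         ic_attenuation = 0.15, shape_factor = 1.2),
                    lc_effect)
  if (eff$cpe1_drop <= 1 || eff$cpe2_rise <= 1)
    stop_apt("cohort_config: cpe1_drop and cpe2_rise must exceed 1")
  if (h_drift < 0 || sensor_sd < 0 || cv_noise_sd < 0 || eis_noise < 0)
    stop_apt("cohort_config: variability and noise scales must be >= 0")
  if (!inherits(base_circuit, "circuit_spec") ||
      base_circuit$topology != "M2_nonfaradaic")
    stop_apt("cohort_config: base_circuit must be an M2_nonfaradaic circuit_spec")
  structure(list(n_lc = as.integer(n_lc), n_h = as.integer(n_h),
                 seed = as.integer(seed), lc_effect = eff, h_drift = h_drift,
                 sensor_sd = sensor_sd, cv_noise_sd = cv_noise_sd,
                 eis_noise = eis_noise, base_shape = base_shape,
                 base_circuit = base_circuit, frequencies = frequencies,
                 window = window, scan_rate = scan_rate,
                 points_per_segment = as.integer(points_per_segment)),
            class = "cohort_config")
}

# lognormal multiplicative jitter on the positive magnitudes of a circuit;
# CPE/Warburg exponents are left at their population values
jitter_circuit <- function(circuit, sdlog) {
  if (sdlog <= 0) return(circuit)
  p <- circuit$parameters
  mag <- !grepl("_P$", names(p))
  p[mag] <- p[mag] * exp(rnorm(sum(mag), sd = sdlog))
  circuit_spec(circuit$topology, p, warburg = circuit$warburg)
}

jitter_shape <- function(shape, sdlog, noise_sd) {
  s <- shape
  if (sdlog > 0) {
    s$anodic_peak_current <- s$anodic_peak_current * exp(rnorm(1, sd = sdlog))
    s$cathodic_peak_current <- s$cathodic_peak_current * exp(rnorm(1, sd = sdlog))
    s$peak_width_scale <- s$peak_width_scale * exp(rnorm(1, sd = sdlog / 2))
    s$anodic_peak_potential <- s$anodic_peak_potential + rnorm(1, sd = 0.1 * sdlog)
    s$cathodic_peak_potential <- s$cathodic_peak_potential + rnorm(1, sd = 0.1 * sdlog)
  }
  s$noise_sd <- noise_sd
  do.call(cv_shape, unclass(s))
}

apply_lc_effect <- function(shape, circuit, eff) {
  s <- shape
  s$cathodic_peak_potential <- s$cathodic_peak_potential + eff$ec_shift
  s$cathodic_peak_current <- s$cathodic_peak_current * (1 - eff$ic_attenuation)
  s$cathodic_asymmetry <- s$cathodic_asymmetry * eff$shape_factor
  s <- do.call(cv_shape, unclass(s))
  p <- circuit$parameters
  p[["CPE1_T"]] <- p[["CPE1_T"]] / eff$cpe1_drop
  p[["CPE2_T"]] <- p[["CPE2_T"]] * eff$cpe2_rise
  list(shape = s, circuit = circuit_spec(circuit$topology, p,
                                         warburg = circuit$warburg))
}

apply_h_drift <- function(shape, circuit, sdlog) {
  if (sdlog <= 0) return(list(shape = shape, circuit = circuit))
  s <- shape
  s$anodic_peak_current <- s$anodic_peak_current * exp(rnorm(1, sd = sdlog))
  s$cathodic_peak_current <- s$cathodic_peak_current * exp(rnorm(1, sd = sdlog))
  s$anodic_peak_potential <- s$anodic_peak_potential + rnorm(1, sd = 0.1 * sdlog)
  s$cathodic_peak_potential <- s$cathodic_peak_potential + rnorm(1, sd = 0.1 * sdlog)
  s <- do.call(cv_shape, unclass(s))
  list(shape = s, circuit = jitter_circuit(circuit, sdlog))
}

#' Simulate a paired before/after LC/H cohort
#'
#' Draws `n_lc + n_h` synthetic sensors from the population baselines with
#' inter-sensor variability, then produces a "before" CV + EIS pair and an
#' "after" pair per sample.  Lung-cancer samples receive the configured
#' effects; healthy samples only drift.  Fully reproducible from the config
#' seed.
#'
#' @param config A [cohort_config()].
#' @return Object of class `cohort`: a list of sample records, each with
#'   `sample_id`, `label` (`"LC"`/`"H"`), `before`/`after` (lists with `cv`,
#'   a [voltammogram()], and `eis`, an [impedance_spectrum()]) and `truth`
#'   (the generating shapes and circuits).
#' @examples
#' coh <- simulate_cohort(cohort_config(n_lc = 2, n_h = 2, seed = 7,
#'                                      points_per_segment = 60))
#' table(vapply(coh, `[[`, "", "label"))
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stop_apt("simulate_cohort: `config` must be a cohort_config")
  n <- config$n_lc + config$n_h
  labels <- c(rep("LC", config$n_lc), rep("H", config$n_h))
  with_seed(config$seed, {
    records <- vector("list", n)
    for (i in seq_len(n)) {
      shape_i <- jitter_shape(config$base_shape, config$sensor_sd,
                              config$cv_noise_sd)
      circuit_i <- jitter_circuit(config$base_circuit, config$sensor_sd)
      if (labels[i] == "LC") {
        aft <- apply_lc_effect(shape_i, circuit_i, config$lc_effect)
      } else {
        aft <- apply_h_drift(shape_i, circuit_i, config$h_drift)
      }
      seeds <- sample.int(.Machine$integer.max - 1L, 4L)
      make_cv <- function(shape, sd_seed)
        simulate_cv(shape, config$window, config$scan_rate,
                    config$points_per_segment, seed = sd_seed)
      make_eis <- function(circ, sd_seed, st)
        simulate_eis(circ, config$frequencies, config$eis_noise,
                     seed = sd_seed, state = st)
      records[[i]] <- structure(
        list(sample_id = sprintf("S%02d", i), label = labels[i],
             before = list(cv = make_cv(shape_i, seeds[1L]),
                           eis = make_eis(circuit_i, seeds[2L], "before")),
             after = list(cv = make_cv(aft$shape, seeds[3L]),
                          eis = make_eis(aft$circuit, seeds[4L], "after")),
             truth = list(shape_before = shape_i, shape_after = aft$shape,
                          circuit_before = circuit_i,
                          circuit_after = aft$circuit)),
        class = "sample_record")
    }
    structure(records, class = "cohort", config = config)
  })
}

#' @export
print.cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("Synthetic aptasensor cohort: %d samples (%d LC, %d H)\n",
              length(x), sum(labs == "LC"), sum(labs == "H")))
  invisible(x)
}
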