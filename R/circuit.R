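#' Constant phase element impedance
#'
#' `Z = 1 / (T (j w)^alpha)`.  With `alpha = 1` this is an ideal capacitor of
#' capacitance `T`; as `alpha -> 0` it degenerates to a resistor of `1/T`.
#' The phase is `-alpha * 90` degrees at every frequency.
#'
#' @param T CPE magnitude (Ohm^-1 s^alpha), > 0.
#' @param alpha CPE exponent, in (0, 1].
#' @param omega Angular frequency (rad/s), > 0; vectorised.
#' @return Complex impedance (Ohm).
#' @examples
#' z_cpe(1e-6, 1, 1e3)   # -1000i: a 1 uF capacitor
#' @export
z_cpe <- function(T, alpha, omega) {
  if (!is_number(T) || T <= 0) stop_apt("z_cpe: T must be > 0")
  if (!is_number(alpha) || alpha <= 0 || alpha > 1)
    stop_apt("z_cpe: alpha must lie in (0, 1]")
  if (any(omega <= 0)) stop_apt("z_cpe: omega must be > 0")
  1 / (T * (1i * omega)^alpha)
}

#' Warburg diffusion impedance
#'
#' Three diffusion models: the semi-infinite Warburg
#' `Z = sigma w^(-1/2) (1 - j)` (constant -45 degree phase); the generalized
#' finite-length element with a free exponent `P`, in its transmissive
#' ("short", `tanh`) and reflective ("open", `coth`) variants
#' `Z = R f((j w tau)^P) / (j w tau)^P`.  The free exponent accommodates the
#' non-ideal diffusion behaviour typical of layered electrodes.
#'
#' @param magnitude For `semi_infinite`, the Warburg coefficient sigma
#'   (Ohm s^-1/2); for the generalized variants, the diffusion resistance R
#'   (Ohm). Must be > 0.
#' @param exponent Exponent `P` in (0, 1) for the generalized variants;
#'   ignored (fixed 0.5) for `semi_infinite`.
#' @param variant One of `"semi_infinite"`, `"generalized_short"`,
#'   `"generalized_open"`.
#' @param omega Angular frequency (rad/s), vectorised.
#' @param tau Diffusion time constant (s) for the generalized variants.
#' @return Complex impedance (Ohm).
#' @export
z_warburg <- function(magnitude, exponent = 0.5,
                      variant = c("semi_infinite", "generalized_short",
                                  "generalized_open"),
                      omega, tau = 1) {
  variant <- match.arg(variant)
  if (!is_number(magnitude) || magnitude <= 0) stop_apt("z_warburg: magnitude must be > 0")
  if (any(omega <= 0)) stop_apt("z_warburg: omega must be > 0")
  if (variant == "semi_infinite")
    return(magnitude * omega^(-0.5) * (1 - 1i))
  if (!is_number(exponent) || exponent <= 0 || exponent >= 1)
    stop_apt("z_warburg: generalized variants need exponent in (0, 1)")
  if (!is_number(tau) || tau <= 0) stop_apt("z_warburg: tau must be > 0")
  s <- (1i * omega * tau)^exponent
  if (variant == "generalized_short") magnitude * tanh(s) / s
  else magnitude / (s * tanh(s))
}

# element inventories per topology (Warburg names appended where a W is present)
warburg_params <- function(variant) {
  if (variant == "semi_infinite") "W_sigma" else c("W_R", "W_T", "W_P")
}

topology_params <- function(topology, warburg_variant) {
  w <- warburg_params(warburg_variant)
  switch(topology,
    M0_randles_w = c("Rs", "CPE_T", "CPE_P", "Rct", w),
    M1_randles_w_extra = c("Rs", "CPE_T", "CPE_P", "Rct", w, "CPE2_T", "CPE2_P", "R2"),
    M2_nonfaradaic = c("Rs", "CPE1_T", "CPE1_P", "Rp1", "CPE2_T", "CPE2_P", "Rp2", w),
    cpe = c("CPE_T", "CPE_P"),
    stop_apt("unknown circuit topology `", topology, "`"))
}

#' Equivalent-circuit specification
#'
#' Declares a circuit topology with named element parameters.  Implemented
#' topologies (`+` series, `||` parallel):
#' \describe{
#'   \item{M0_randles_w}{`Rs + [CPE || (Rct + W)]` -- the Randles circuit with
#'     a CPE double layer and a Warburg diffusion tail (redox-probe solution).}
#'   \item{M1_randles_w_extra}{`M0 + [CPE2 || R2]` -- an additional parallel
#'     relaxation appearing when the surface layer is partially decomposed.}
#'   \item{M2_nonfaradaic}{`Rs + [CPE1 || Rp1] + [CPE2 || (Rp2 + W)]` -- the
#'     two-interface non-Faradaic circuit (electrode surface / biolayer) used
#'     for plasma measurements in background electrolyte.}
#'   \item{cpe}{a bare CPE, a degenerate single-element topology.}
#' }
#'
#' @param topology Topology id (see Details).
#' @param parameters Named numeric vector/list matching the topology's element
#'   inventory exactly: resistances (`Rs`, `Rct`, `Rp1`, `Rp2`, `R2`, Ohm),
#'   CPE magnitudes `*_T` (Ohm^-1 s^alpha) and exponents `*_P` in (0, 1],
#'   and Warburg parameters (`W_R`, `W_T`, `W_P` for the generalized variants
#'   or `W_sigma` for semi-infinite).
#' @param warburg One of `"generalized_short"` (default), `"generalized_open"`,
#'   `"semi_infinite"`.
#' @return Object of class `circuit_spec`.
#' @examples
#' circuit_spec("M0_randles_w",
#'              c(Rs = 100, CPE_T = 4.2e-5, CPE_P = 0.72, Rct = 2e3,
#'                W_R = 3e3, W_T = 0.05, W_P = 0.45))
#' @export
circuit_spec <- function(topology, parameters,
                         warburg = c("generalized_short", "generalized_open",
                                     "semi_infinite")) {
  warburg <- match.arg(warburg)
  parameters <- unlist(parameters)
  wanted <- topology_params(topology, warburg)
  missing <- setdiff(wanted, names(parameters))
  if (length(missing))
    stop_apt("circuit_spec: topology ", topology, " is missing parameter(s): ",
             paste(missing, collapse = ", "))
  extra <- setdiff(names(parameters), wanted)
  if (length(extra))
    stop_apt("circuit_spec: parameter(s) not in the ", topology,
             " inventory: ", paste(extra, collapse = ", "))
  parameters <- parameters[wanted]
  if (any(!is.finite(parameters)) || any(parameters <= 0))
    stop_apt("circuit_spec: all element parameters must be finite and > 0")
  pn <- names(parameters)
  alphas <- parameters[grepl("_P$", pn) & !grepl("^W", pn)]
  if (any(alphas > 1)) stop_apt("circuit_spec: every CPE exponent must lie in (0, 1]")
  if ("W_P" %in% pn && (parameters[["W_P"]] >= 1))
    stop_apt("circuit_spec: Warburg exponent must lie in (0, 1)")
  structure(list(topology = topology, parameters = parameters, warburg = warburg),
            class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat("Equivalent circuit:", x$topology,
      sprintf("(Warburg: %s)\n", x$warburg))
  print(signif(x$parameters, 5))
  invisible(x)
}

z_warburg_spec <- function(p, variant, omega) {
  if (variant == "semi_infinite")
    z_warburg(p[["W_sigma"]], variant = "semi_infinite", omega = omega)
  else z_warburg(p[["W_R"]], p[["W_P"]], variant, omega, tau = p[["W_T"]])
}

par_c <- function(...) {
  zs <- list(...)
  y <- 0
  for (z in zs) y <- y + 1 / z
  1 / y
}

#' Forward impedance of an equivalent circuit
#'
#' Evaluates the exact complex impedance of a [circuit_spec()] on a frequency
#' grid.
#'
#' @param circuit A [circuit_spec()].
#' @param frequencies Frequencies (Hz), > 0; stored sorted descending.
#' @return An [impedance_spectrum()].
#' @export
circuit_impedance <- function(circuit, frequencies) {
  if (!inherits(circuit, "circuit_spec"))
    stop_apt("circuit_impedance: `circuit` must be a circuit_spec")
  if (any(frequencies <= 0)) stop_apt("circuit_impedance: frequencies must be > 0")
  f <- sort(as.numeric(frequencies), decreasing = TRUE)
  omega <- 2 * pi * f
  p <- as.list(circuit$parameters)
  Z <- switch(circuit$topology,
    cpe = z_cpe(p$CPE_T, p$CPE_P, omega),
    M0_randles_w = p$Rs + par_c(z_cpe(p$CPE_T, p$CPE_P, omega),
                                p$Rct + z_warburg_spec(p, circuit$warburg, omega)),
    M1_randles_w_extra = p$Rs +
      par_c(z_cpe(p$CPE_T, p$CPE_P, omega),
            p$Rct + z_warburg_spec(p, circuit$warburg, omega)) +
      par_c(z_cpe(p$CPE2_T, p$CPE2_P, omega), p$R2),
    M2_nonfaradaic = p$Rs +
      par_c(z_cpe(p$CPE1_T, p$CPE1_P, omega), p$Rp1) +
      par_c(z_cpe(p$CPE2_T, p$CPE2_P, omega),
            p$Rp2 + z_warburg_spec(p, circuit$warburg, omega)))
  impedance_spectrum(f, Z, metadata = list(circuit = circuit))
}
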