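#' Construct an impedance spectrum
#'
#' Frequencies with complex impedance values; stored sorted by descending
#' frequency (the acquisition order of a typical sweep).
#'
#' @param frequencies Frequencies (Hz), all > 0.
#' @param impedance Complex impedance values (Ohm), same length.
#' @param state Measurement state, `"before"` or `"after"` plasma incubation
#'   (or `NA` when not applicable).
#' @param metadata Free-form named list.
#' @return Object of class `impedance_spectrum` with elements `frequencies`,
#'   `impedance`, `state`, `metadata`.
#' @export
impedance_spectrum <- function(frequencies, impedance, state = NA_character_,
                               metadata = list()) {
  f <- as.numeric(frequencies)
  Z <- as.complex(impedance)
  if (length(f) != length(Z) || length(f) < 1L)
    stop_apt("impedance_spectrum: frequency and impedance arrays must have equal length")
  if (any(!is.finite(f)) || any(f <= 0))
    stop_apt("impedance_spectrum: all frequencies must be finite and > 0")
  if (anyDuplicated(f)) stop_apt("impedance_spectrum: duplicated frequencies")
  ord <- order(f, decreasing = TRUE)
  structure(list(frequencies = f[ord], impedance = Z[ord],
                 state = state, metadata = metadata),
            class = "impedance_spectrum")
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf("Impedance spectrum: %d points, %.4g -> %.4g Hz",
              length(x$frequencies), max(x$frequencies), min(x$frequencies)))
  if (!is.na(x$state)) cat(sprintf(" [%s]", x$state))
  cat("\n")
  cat(sprintf("  |Z| range: %.4g - %.4g Ohm\n",
              min(Mod(x$impedance)), max(Mod(x$impedance))))
  invisible(x)
}

#' @export
plot.impedance_spectrum <- function(x, ...) {
  plot(Re(x$impedance), -Im(x$impedance), type = "b", pch = 16, cex = 0.6,
       xlab = expression(paste("Re Z (", Omega, ")")),
       ylab = expression(paste("-Im Z (", Omega, ")")), asp = 1, ...)
  invisible(x)
}

#' Simulate an impedance spectrum from an equivalent circuit
#'
#' Evaluates the forward circuit model on a frequency grid and optionally adds
#' multiplicative Gaussian measurement noise, applied independently to the real
#' and imaginary parts (`Re' = Re (1 + eps)`, `eps ~ N(0, noise_fraction)`).
#' With `noise_fraction = 0` the spectrum equals the forward model exactly.
#' The default grid covers the measurement protocol's 1 Hz - 1 kHz range.
#'
#' @param circuit A [circuit_spec()].
#' @param frequencies Frequencies (Hz), strictly positive.
#' @param noise_fraction Relative noise level, >= 0.
#' @param seed Optional integer seed for reproducible noise.
#' @param state Measurement state tag carried by the spectrum.
#' @return An [impedance_spectrum()].
#' @examples
#' spec <- circuit_spec("cpe", c(CPE_T = 1e-6, CPE_P = 1))
#' simulate_eis(spec, frequencies = 10^seq(3, 0, length.out = 12))
#' @export
simulate_eis <- function(circuit, frequencies = default_eis_frequencies(),
                         noise_fraction = 0, seed = NULL,
                         state = NA_character_) {
  if (!is_number(noise_fraction) || noise_fraction < 0)
    stop_apt("simulate_eis: noise_fraction must be >= 0")
  sp <- circuit_impedance(circuit, frequencies)
  Z <- sp$impedance
  if (noise_fraction > 0) {
    n <- length(Z)
    eps <- with_seed(seed, rnorm(2L * n, sd = noise_fraction))
    Z <- complex(real = Re(Z) * (1 + eps[seq_len(n)]),
                 imaginary = Im(Z) * (1 + eps[n + seq_len(n)]))
  }
  impedance_spectrum(sp$frequencies, Z, state = state,
                     metadata = list(circuit = circuit,
                                     noise_fraction = noise_fraction,
                                     seed = seed))
}

#' Default EIS frequency grid
#'
#' 40 logarithmically spaced frequencies from 1 kHz down to 1 Hz, matching the
#' measurement protocol's range.
#'
#' @param n Number of points.
#' @return Numeric vector of frequencies (Hz), descending.
#' @export
default_eis_frequencies <- function(n = 40L) {
  10^seq(3, 0, length.out = n)
}
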