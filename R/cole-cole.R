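#' Cole-Cole complex-capacitance transform
#'
#' Converts an impedance spectrum to complex capacitance,
#' `C*(w) = 1 / (j w Z(w))`, the representation in which capacitive
#' relaxations of a layered electrode separate.  Returns `C' = Re(C*)` and
#' `C'' = -Im(C*)` pointwise.
#'
#' @param spectrum An [impedance_spectrum()].
#' @return Object of class `cole_cole_curve` with `angular_frequencies`
#'   (rad/s, descending), `C_real`, `C_imag` (F).
#' @examples
#' sp <- simulate_eis(circuit_spec("cpe", c(CPE_T = 1e-6, CPE_P = 1)))
#' cc <- cole_cole_transform(sp)
#' range(cc$C_real)   # constant 1e-6: the capacitor identity
#' @export
cole_cole_transform <- function(spectrum) {
  if (!inherits(spectrum, "impedance_spectrum"))
    stop_apt("cole_cole_transform: input must be an impedance_spectrum")
  if (any(Mod(spectrum$impedance) == 0))
    stop_apt("cole_cole_transform: zero impedance encountered")
  omega <- 2 * pi * spectrum$frequencies
  Cc <- 1 / (1i * omega * spectrum$impedance)
  structure(list(angular_frequencies = omega,
                 C_real = Re(Cc), C_imag = -Im(Cc),
                 state = spectrum$state),
            class = "cole_cole_curve")
}

#' @export
plot.cole_cole_curve <- function(x, ...) {
  plot(x$C_real, x$C_imag, type = "b", pch = 16, cex = 0.6,
       xlab = "C' (F)", ylab = "C'' (F)", ...)
  invisible(x)
}

#' Extract EIS base-features from a Cole-Cole curve
#'
#' Four scalar features of the real (active) capacitance `C'` as a function of
#' `log(w)`:
#' \describe{
#'   \item{C_dl}{double-layer capacitance: the median `C'` over the top
#'     half-decade of frequency (the high-frequency plateau);}
#'   \item{omega_min, C_min}{angular frequency of the interior local minimum
#'     of `C'` vs `log(w)` and the capacitance there;}
#'   \item{omega_max}{angular frequency of the interior local maximum.}
#' }
#' When several interior extrema exist the most extreme one is reported;
#' absent extrema are reported as `NA`, not errors.  The curve must span at
#' least two frequency decades and contain at least 8 points.
#'
#' @param curve A [cole_cole_transform()] output.
#' @return Object of class `eis_features`: named list `C_dl`, `omega_min`,
#'   `C_min`, `omega_max`.
#' @export
extract_eis_features <- function(curve) {
  if (!inherits(curve, "cole_cole_curve"))
    stop_apt("extract_eis_features: input must be a cole_cole_curve")
  ord <- order(curve$angular_frequencies)   # ascending; sort-order independent
  w <- curve$angular_frequencies[ord]
  C <- curve$C_real[ord]
  n <- length(w)
  if (n < 8L) stop_apt("extract_eis_features: curve shorter than 8 points")
  if (max(w) / min(w) < 100)
    stop_apt("extract_eis_features: spectrum must span at least two decades")
  plateau <- w >= max(w) / sqrt(10)
  C_dl <- median(C[plateau])
  interior <- 2:(n - 1L)
  # strict extrema with a relative prominence floor, so a numerically flat
  # curve (ideal capacitor) reports no extrema
  tol <- 1e-9 * max(abs(C))
  is_min <- C[interior] < C[interior - 1L] - tol & C[interior] < C[interior + 1L] - tol
  is_max <- C[interior] > C[interior - 1L] + tol & C[interior] > C[interior + 1L] + tol
  omega_min <- C_min <- omega_max <- NA_real_
  if (any(is_min)) {
    cand <- interior[is_min]
    k <- cand[which.min(C[cand])]
    omega_min <- w[k]; C_min <- C[k]
  }
  if (any(is_max)) {
    cand <- interior[is_max]
    k <- cand[which.max(C[cand])]
    omega_max <- w[k]
  }
  structure(list(C_dl = C_dl, omega_min = omega_min,
                 C_min = C_min, omega_max = omega_max),
            class = "eis_features")
}

#' @export
print.eis_features <- function(x, ...) {
  cat("EIS base-features (Cole-Cole)\n")
  cat(sprintf("  C_dl = %.4g F\n", x$C_dl))
  cat(sprintf("  omega_min = %s rad/s, C_min = %s F, omega_max = %s rad/s\n",
              format(x$omega_min, digits = 4), format(x$C_min, digits = 4),
              format(x$omega_max, digits = 4)))
  invisible(x)
}
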