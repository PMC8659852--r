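# complex nonlinear least-squares fitting of equivalent circuits
# (the in-package replacement for interactive circuit-fitting tools)

# parameters are optimised unconstrained: log for magnitudes, logit for the
# (0,1)-bounded exponents
is_exponent_par <- function(nm) grepl("_P$", nm)

to_theta <- function(p) {
  nm <- names(p)
  th <- ifelse(is_exponent_par(nm), qlogis(pmin(pmax(p, 1e-6), 1 - 1e-6)), log(p))
  names(th) <- nm
  th
}
from_theta <- function(th) {
  nm <- names(th)
  p <- ifelse(is_exponent_par(nm), plogis(th), exp(th))
  names(p) <- nm
  p
}

# data-driven starting values per topology.  The combined high-frequency CPE
# scale T_hf = 1/(|Z_top - Rs| w_top^0.9) conflates the parallel blocks of the
# two-interface topologies, so the multi-block heuristics return a *grid* of
# structured starts that spreads the CPE magnitudes and resistance split over
# the degeneracy directions; the best converged fit wins.
initial_guess_grid <- function(spectrum, topology, warburg) {
  Z <- spectrum$impedance
  f <- spectrum$frequencies
  w_top <- 2 * pi * max(f)
  Rs0 <- max(0.9 * min(Re(Z)), 1e-3)
  Rtot <- max(max(Re(Z)) - Rs0, 10 * Rs0, 1)
  Ztop <- Z[which.max(f)]
  T_hf <- 1 / (max(Mod(Ztop - Rs0), 1e-9) * w_top^0.9)
  wb <- function(scale) {
    if (warburg == "semi_infinite") c(W_sigma = scale / sqrt(2 * pi * min(f)))
    else c(W_R = scale, W_T = 0.2, W_P = 0.5)
  }
  specs <- switch(topology,
    cpe = list(c(CPE_T = T_hf, CPE_P = 0.85)),
    M0_randles_w = lapply(c(0.5, 2, 8), function(s)
      c(Rs = Rs0, CPE_T = s * T_hf, CPE_P = 0.8, Rct = 0.6 * Rtot,
        wb(0.4 * Rtot))),
    M1_randles_w_extra = unlist(recursive = FALSE,
      lapply(c(1, 6), function(s1) lapply(c(3, 20), function(s2)
        c(Rs = Rs0, CPE_T = s1 * T_hf, CPE_P = 0.85, Rct = 0.5 * Rtot,
          wb(0.25 * Rtot), CPE2_T = s2 * T_hf, CPE2_P = 0.85,
          R2 = 0.25 * Rtot)))),
    M2_nonfaradaic = unlist(recursive = FALSE, unlist(recursive = FALSE,
      lapply(c(1, 5, 25), function(s1)
        lapply(c(0.3, 3), function(s2) lapply(c(0.1, 0.4), function(r)
          c(Rs = Rs0, CPE1_T = s1 * T_hf, CPE1_P = 0.9, Rp1 = r * Rtot,
            CPE2_T = s2 * T_hf, CPE2_P = 0.85, Rp2 = (0.9 - r) * Rtot,
            wb(0.3 * Rtot))))))),
    stop_apt("no initial-guess heuristic for topology ", topology))
  lapply(specs, circuit_spec, topology = topology, warburg = warburg)
}

default_initial_guess <- function(spectrum, topology, warburg) {
  initial_guess_grid(spectrum, topology, warburg)[[1L]]
}

#' Fit an equivalent circuit to an impedance spectrum
#'
#' Complex nonlinear least squares: minimises
#' `sum_i w_i |Z_model(w_i) - Z_i|^2` over strictly positive element
#' parameters (log-parameterised internally; CPE and Warburg exponents
#' logit-parameterised) with Levenberg-Marquardt.  Modulus weighting
#' (`w_i = 1/|Z_i|^2`, the default) balances residuals across spectra whose
#' impedance spans orders of magnitude.  Five starts (the initial guess plus
#' four deterministic log-space perturbations) guard against local minima;
#' the best converged solution is kept.
#'
#' @param spectrum An [impedance_spectrum()] with more points than free
#'   parameters.
#' @param topology Circuit topology id (see [circuit_spec()]).
#' @param initial_guess Optional [circuit_spec()] used as the central start;
#'   by default a data-driven heuristic.
#' @param weighting `"modulus"` or `"unit"`.
#' @param warburg Warburg variant for topologies containing a diffusion
#'   element.
#' @param n_starts Number of starts (>= 1).
#' @return Object of class `circuit_fit`: the fitted [circuit_spec()]
#'   (`$circuit`), per-parameter standard errors from the local curvature
#'   (`$uncertainties`), `$chi_square` (weighted residual sum), `$n_points`,
#'   `$aic`, `$converged`, plus the data and settings.  Never errors on
#'   non-convergence: inspect `$converged`.
#' @examples
#' truth <- circuit_spec("cpe", c(CPE_T = 1e-6, CPE_P = 0.9))
#' fit <- fit_circuit(simulate_eis(truth), "cpe")
#' coef(fit)
#' @export
fit_circuit <- function(spectrum, topology, initial_guess = NULL,
                        weighting = c("modulus", "unit"),
                        warburg = c("generalized_short", "generalized_open",
                                    "semi_infinite"),
                        n_starts = 5L) {
  weighting <- match.arg(weighting)
  warburg <- match.arg(warburg)
  if (!inherits(spectrum, "impedance_spectrum"))
    stop_apt("fit_circuit: `spectrum` must be an impedance_spectrum")
  if (is.null(initial_guess)) {
    guesses <- initial_guess_grid(spectrum, topology, warburg)
    initial_guess <- guesses[[1L]]
  } else {
    if (!inherits(initial_guess, "circuit_spec") ||
        initial_guess$topology != topology)
      stop_apt("fit_circuit: initial_guess must be a circuit_spec of topology ", topology)
    guesses <- list(initial_guess)
  }
  warburg <- initial_guess$warburg
  pn <- names(initial_guess$parameters)
  k <- length(pn)
  n <- length(spectrum$frequencies)
  if (n <= k)
    stop_apt("fit_circuit: spectrum must contain more points than free parameters")

  Zd <- spectrum$impedance
  f <- spectrum$frequencies
  wts <- if (weighting == "modulus") 1 / Mod(Zd) else rep(1, n)

  resid_fn <- function(theta) {
    p <- from_theta(setNames(theta, pn))
    Zm <- tryCatch(
      circuit_impedance(circuit_spec(topology, p, warburg = warburg), f)$impedance,
      error = function(e) rep(NA_complex_, n))
    r <- c(wts * (Re(Zm) - Re(Zd)), wts * (Im(Zm) - Im(Zd)))
    r[!is.finite(r)] <- 1e6
    r
  }

  theta0 <- to_theta(initial_guess$parameters)
  perturb <- with_seed(20201L, matrix(rnorm(max(n_starts - 1L, 1L) * k, sd = 0.7),
                                      ncol = k))
  starts <- c(lapply(guesses, function(g) to_theta(g$parameters)),
              if (n_starts > 1L)
                lapply(seq_len(n_starts - 1L),
                       function(i) theta0 + perturb[i, ]))

  lm_ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                        ptol = 1e-12)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(minpack.lm::nls.lm(par = st, fn = resid_fn, control = lm_ctrl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop_apt("fit_circuit: every optimisation start failed to evaluate")
  # polish: restart Levenberg-Marquardt from the best solution (a fresh trust
  # region often finishes a run that stopped on the iteration cap)
  repolish <- tryCatch(minpack.lm::nls.lm(par = best$par, fn = resid_fn,
                                          control = lm_ctrl),
                       error = function(e) NULL)
  if (!is.null(repolish) && repolish$deviance <= best$deviance) best <- repolish

  theta_hat <- setNames(best$par, pn)
  p_hat <- from_theta(theta_hat)
  chi2 <- best$deviance
  nres <- 2L * n
  converged <- best$info %in% 1:3
  # parameter covariance from the local curvature (finite-difference Jacobian)
  se <- rep(NA_real_, k)
  r0 <- resid_fn(theta_hat)
  J <- matrix(0, nres, k)
  h <- 1e-6
  for (j in seq_len(k)) {
    tp <- theta_hat; tp[j] <- tp[j] + h
    J[, j] <- (resid_fn(tp) - r0) / h
  }
  dof <- nres - k
  cov_theta <- tryCatch(chi2 / dof * solve(crossprod(J)),
                        error = function(e) NULL)
  if (!is.null(cov_theta)) {
    se_theta <- sqrt(pmax(diag(cov_theta), 0))
    scale <- ifelse(is_exponent_par(pn), p_hat * (1 - p_hat), p_hat)
    se <- se_theta * scale
  }
  aic <- nres * log(chi2 / nres) + 2 * k

  structure(list(circuit = circuit_spec(topology, p_hat, warburg = warburg),
                 uncertainties = setNames(se, pn),
                 chi_square = chi2, n_points = n, aic = aic,
                 converged = converged, info = best$info,
                 weighting = weighting, spectrum = spectrum,
                 initial_guess = initial_guess),
            class = "circuit_fit")
}

#' @export
coef.circuit_fit <- function(object, ...) object$circuit$parameters

#' @export
print.circuit_fit <- function(x, ...) {
  cat("Equivalent-circuit fit:", x$circuit$topology, "\n")
  cat(sprintf("  %d frequencies, %s weighting, chi^2 = %.4g, AIC = %.2f, %s\n",
              x$n_points, x$weighting, x$chi_square, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  print(signif(coef(x), 5))
  invisible(x)
}

#' @export
summary.circuit_fit <- function(object, ...) {
  tab <- data.frame(estimate = coef(object),
                    std_error = object$uncertainties)
  structure(list(topology = object$circuit$topology, table = tab,
                 chi_square = object$chi_square, aic = object$aic,
                 n_points = object$n_points, converged = object$converged),
            class = "summary.circuit_fit")
}

#' @export
print.summary.circuit_fit <- function(x, ...) {
  cat("Circuit fit summary --", x$topology, "\n")
  print(signif(as.matrix(x$table), 5))
  cat(sprintf("chi^2 = %.5g on %d points; AIC = %.2f; converged: %s\n",
              x$chi_square, x$n_points, x$aic, x$converged))
  invisible(x)
}

#' @export
predict.circuit_fit <- function(object, frequencies = NULL, ...) {
  if (is.null(frequencies)) frequencies <- object$spectrum$frequencies
  circuit_impedance(object$circuit, frequencies)
}

#' @export
residuals.circuit_fit <- function(object, ...) {
  Zm <- predict(object)$impedance
  object$spectrum$impedance - Zm
}

#' @export
plot.circuit_fit <- function(x, ...) {
  Zd <- x$spectrum$impedance
  fine <- 10^seq(log10(max(x$spectrum$frequencies)),
                 log10(min(x$spectrum$frequencies)), length.out = 200)
  Zm <- predict(x, fine)$impedance
  plot(Re(Zd), -Im(Zd), pch = 16, cex = 0.7,
       xlab = expression(paste("Re Z (", Omega, ")")),
       ylab = expression(paste("-Im Z (", Omega, ")")), asp = 1, ...)
  lines(Re(Zm), -Im(Zm), col = "steelblue")
  legend("topleft", legend = c("data", "fit"), bty = "n",
         pch = c(16, NA), lty = c(NA, 1), col = c("black", "steelblue"))
  invisible(x)
}

#' @export
simulate.circuit_fit <- function(object, nsim = 1, seed = NULL,
                                 noise_fraction = 0.01, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_eis(object$circuit, object$spectrum$frequencies,
                 noise_fraction = noise_fraction)))
}

#' Fit several candidate topologies and select the best by AIC
#'
#' Fits every candidate circuit to the spectrum and selects the minimum-AIC
#' converged fit; AIC ties (within 1e-9) go to the topology with fewer
#' parameters.
#'
#' @inheritParams fit_circuit
#' @param candidates Character vector of >= 2 topology ids.
#' @param ... Passed to [fit_circuit()].
#' @return List with `best` (topology id) and `fits` (named list of
#'   `circuit_fit` objects).
#' @export
select_circuit <- function(spectrum, candidates = c("M0_randles_w",
                                                    "M1_randles_w_extra"),
                           ...) {
  if (length(candidates) < 2L)
    stop_apt("select_circuit: need at least two candidate topologies")
  fits <- lapply(candidates, function(tp)
    tryCatch(fit_circuit(spectrum, tp, ...), error = function(e) NULL))
  names(fits) <- candidates
  ok <- !vapply(fits, is.null, logical(1)) &
    vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok))
    stop_apt("select_circuit: no candidate converged; inspect the fits individually")
  aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, numeric(1))
  aics[!ok] <- Inf
  npar <- vapply(fits, function(f)
    if (is.null(f)) Inf else length(coef(f)), numeric(1))
  best <- choose_best_fit(aics, npar)
  list(best = candidates[best], fits = fits)
}

# minimum-AIC index; ties (within 1e-9) go to the fewest parameters
choose_best_fit <- function(aics, npars) {
  tied <- which(aics <= min(aics) + 1e-9)
  tied[which.min(npars[tied])]
}

#' Effective capacitance of a CPE
#'
#' Converts CPE parameters to an equivalent capacitance by either the
#' Hsu-Mansfeld relation `C = T * w_peak^(alpha - 1)` (with `w_peak` the
#' angular frequency of the -Im(Z) maximum of the relevant arc) or the Brug
#' relation `C = T^(1/alpha) * (1/Rs + 1/Rct)^((alpha-1)/alpha)`.  Both reduce
#' to `C = T` for an ideal capacitor (`alpha = 1`).
#'
#' @param T,alpha CPE parameters, `alpha` in (0, 1].
#' @param method `"hsu_mansfeld"` or `"brug"`.
#' @param omega_peak Arc-apex angular frequency (rad/s), required for
#'   Hsu-Mansfeld.
#' @param Rs,Rct Series and charge-transfer resistances (Ohm), required for
#'   Brug.
#' @return Capacitance (F).
#' @export
effective_capacitance <- function(T, alpha, method = c("hsu_mansfeld", "brug"),
                                  omega_peak = NULL, Rs = NULL, Rct = NULL) {
  method <- match.arg(method)
  if (!is_number(alpha) || alpha <= 0 || alpha > 1)
    stop_apt("effective_capacitance: alpha must lie in (0, 1]")
  if (!is_number(T) || T <= 0) stop_apt("effective_capacitance: T must be > 0")
  if (method == "hsu_mansfeld") {
    if (!is_number(omega_peak) || omega_peak <= 0)
      stop_apt("effective_capacitance: hsu_mansfeld needs the arc-apex omega_peak")
    T * omega_peak^(alpha - 1)
  } else {
    if (!is_number(Rs) || !is_number(Rct) || Rs <= 0 || Rct <= 0)
      stop_apt("effective_capacitance: brug needs both Rs and Rct")
    T^(1 / alpha) * (1 / Rs + 1 / Rct)^((alpha - 1) / alpha)
  }
}

#' Before/after decision rule on fitted non-Faradaic circuits
#'
#' Classifies a before/after pair of `M2_nonfaradaic` fits: positive for the
#' lung-cancer signature when the electrode-interface CPE magnitude drops by
#' at least `drop_orders` orders of magnitude
#' (`log10(CPE1_T_before / CPE1_T_after) >= drop_orders`) while the
#' biolayer-interface magnitude rises (`CPE2_T_after > CPE2_T_before`).
#' Non-converged fits give an indeterminate result rather than a silent call.
#'
#' @param fit_before,fit_after `circuit_fit` objects on topology
#'   `M2_nonfaradaic`.
#' @param drop_orders Required decadic drop of `CPE1_T` (default 1).
#' @return Character scalar, one of `"LC_positive"`, `"negative"`,
#'   `"indeterminate"`, with attribute `detail` (named list with the fitted
#'   log10 drop and the CPE2 change).
#' @export
eis_decision_rule <- function(fit_before, fit_after, drop_orders = 1) {
  for (f in list(fit_before, fit_after)) {
    if (!inherits(f, "circuit_fit") || f$circuit$topology != "M2_nonfaradaic")
      stop_apt("eis_decision_rule: both fits must be circuit_fit objects on M2_nonfaradaic")
  }
  pb <- coef(fit_before); pa <- coef(fit_after)
  drop <- log10(pb[["CPE1_T"]] / pa[["CPE1_T"]])
  rise <- pa[["CPE2_T"]] > pb[["CPE2_T"]]
  detail <- list(log10_cpe1_drop = drop, cpe2_rises = rise,
                 converged = c(before = fit_before$converged,
                               after = fit_after$converged))
  if (!fit_before$converged || !fit_after$converged)
    return(structure("indeterminate", detail = detail))
  out <- if (drop >= drop_orders && rise) "LC_positive" else "negative"
  structure(out, detail = detail)
}
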