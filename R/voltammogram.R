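#' Construct a voltammogram object
#'
#' A one-cycle cyclic voltammogram stored as explicit sweep segments.  Each
#' segment carries its own uniform potential grid, current trace and sweep
#' direction; within a segment the potential must be strictly monotone in the
#' stated direction.
#'
#' @param forward,reverse Lists with numeric elements `potential` (V) and
#'   `current` (A) of equal length (>= 10) for the forward (rising) and
#'   reverse (falling) sweep.
#' @param scan_rate Scan rate (V/s), strictly positive.
#' @param metadata Free-form named list.
#' @return An object of class `voltammogram` with elements `segments`
#'   (named list `forward`/`reverse`, each with `potential`, `current`,
#'   `direction`), `scan_rate` and `metadata`.
#' @export
voltammogram <- function(forward, reverse, scan_rate, metadata = list()) {
  check_segment <- function(seg, dir, name) {
    if (!is.list(seg) || is.null(seg$potential) || is.null(seg$current))
      stop_apt("voltammogram: segment `", name, "` needs `potential` and `current`")
    E <- as.numeric(seg$potential); I <- as.numeric(seg$current)
    if (length(E) != length(I) || length(E) < 10L)
      stop_apt("voltammogram: segment `", name,
               "` needs equal-length potential/current arrays of length >= 10")
    dE <- diff(E)
    if (!all(dir * dE > 0))
      stop_apt("voltammogram: segment `", name, "` potential is not strictly ",
               if (dir > 0) "increasing" else "decreasing")
    list(potential = E, current = I, direction = dir)
  }
  if (!is_number(scan_rate) || scan_rate <= 0)
    stop_apt("voltammogram: scan_rate must be a single positive number")
  structure(list(segments = list(forward = check_segment(forward, +1, "forward"),
                                 reverse = check_segment(reverse, -1, "reverse")),
                 scan_rate = scan_rate,
                 metadata = metadata),
            class = "voltammogram")
}

#' @export
print.voltammogram <- function(x, ...) {
  f <- x$segments$forward; r <- x$segments$reverse
  cat("Cyclic voltammogram\n")
  cat(sprintf("  forward sweep: %d points, %.3f -> %.3f V\n",
              length(f$potential), f$potential[1], f$potential[length(f$potential)]))
  cat(sprintf("  reverse sweep: %d points, %.3f -> %.3f V\n",
              length(r$potential), r$potential[1], r$potential[length(r$potential)]))
  cat(sprintf("  scan rate: %g V/s\n", x$scan_rate))
  invisible(x)
}

#' @export
plot.voltammogram <- function(x, ...) {
  f <- x$segments$forward; r <- x$segments$reverse
  plot(c(f$potential, r$potential), c(f$current, r$current), type = "n",
       xlab = "E (V)", ylab = "I (A)", ...)
  lines(f$potential, f$current, col = "firebrick")
  lines(r$potential, r$current, col = "steelblue")
  legend("topleft", legend = c("forward", "reverse"), bty = "n",
         col = c("firebrick", "steelblue"), lty = 1)
  invisible(x)
}
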