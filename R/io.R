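# plain-text file dialects: voltammogram CSV, spectrum CSV, cohort manifest
# JSON, feature-table CSV, fit-result JSON

#' Read and write voltammogram CSV files
#'
#' Dialect: header `potential_V,current_A,segment`, UTF-8, `.` decimal, one
#' row per point, `segment` in `{forward, reverse}`.
#'
#' @param cv A [voltammogram()].
#' @param path File path.
#' @param scan_rate Scan rate to attach on read (the dialect does not carry
#'   it).
#' @return `read_voltammogram` returns a [voltammogram()];
#'   `write_voltammogram` returns `path` invisibly.
#' @export
write_voltammogram <- function(cv, path) {
  f <- cv$segments$forward; r <- cv$segments$reverse
  df <- data.frame(
    potential_V = c(f$potential, r$potential),
    current_A = c(f$current, r$current),
    segment = rep(c("forward", "reverse"),
                  c(length(f$potential), length(r$potential))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_voltammogram
#' @export
read_voltammogram <- function(path, scan_rate = 0.03) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("potential_V", "current_A", "segment")
  if (!all(need %in% colnames(df)))
    stop_apt("read_voltammogram: expected header potential_V,current_A,segment")
  seg <- function(which)
    list(potential = df$potential_V[df$segment == which],
         current = df$current_A[df$segment == which])
  voltammogram(seg("forward"), seg("reverse"), scan_rate = scan_rate,
               metadata = list(path = path))
}

#' Read and write impedance-spectrum CSV files
#'
#' Dialect: header `freq_Hz,z_re_ohm,z_im_ohm`, rows in descending frequency.
#'
#' @param spectrum An [impedance_spectrum()].
#' @param path File path.
#' @param state Measurement state to attach on read.
#' @return `read_spectrum` returns an [impedance_spectrum()];
#'   `write_spectrum` returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  df <- data.frame(freq_Hz = spectrum$frequencies,
                   z_re_ohm = Re(spectrum$impedance),
                   z_im_ohm = Im(spectrum$impedance))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path, state = NA_character_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("freq_Hz", "z_re_ohm", "z_im_ohm")
  if (!all(need %in% colnames(df)))
    stop_apt("read_spectrum: expected header freq_Hz,z_re_ohm,z_im_ohm")
  impedance_spectrum(df$freq_Hz, complex(real = df$z_re_ohm,
                                         imaginary = df$z_im_ohm),
                     state = state, metadata = list(path = path))
}

#' Write a cohort to disk with a JSON manifest
#'
#' Writes one voltammogram and one spectrum CSV per sample and state, plus a
#' `manifest.json` listing
#' `{sample_id, label, before:{cv_path, eis_path}, after:{...}}` entries with
#' paths relative to the directory.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(rec) {
    paths <- list()
    for (state in c("before", "after")) {
      cvp <- sprintf("%s_%s_cv.csv", rec$sample_id, state)
      eip <- sprintf("%s_%s_eis.csv", rec$sample_id, state)
      write_voltammogram(rec[[state]]$cv, file.path(dir, cvp))
      write_spectrum(rec[[state]]$eis, file.path(dir, eip))
      paths[[state]] <- list(cv_path = cvp, eis_path = eip)
    }
    list(sample_id = rec$sample_id, label = rec$label,
         before = paths$before, after = paths$after)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort manifest back into records
#'
#' @param manifest Path to a `manifest.json` written by [write_cohort()].
#' @param scan_rate Scan rate attached to the voltammograms.
#' @return A list of sample records (class `cohort`).
#' @export
read_cohort <- function(manifest, scan_rate = 0.03) {
  entries <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  records <- lapply(entries, function(e) {
    load_state <- function(st, state_tag)
      list(cv = read_voltammogram(file.path(dir, st$cv_path), scan_rate),
           eis = read_spectrum(file.path(dir, st$eis_path), state_tag))
    structure(list(sample_id = e$sample_id, label = e$label,
                   before = load_state(e$before, "before"),
                   after = load_state(e$after, "after")),
              class = "sample_record")
  })
  structure(records, class = "cohort")
}

#' Write and read a feature table CSV
#'
#' First column `sample_id`, fixed registry-ordered feature columns, last
#' column `label`.
#'
#' @param table A [build_feature_table()] result.
#' @param path File path.
#' @return `read_feature_table` returns the table with class `feature_table`;
#'   `write_feature_table` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  df$label <- as.character(df$label)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$label <- factor(df$label, levels = c("H", "LC"))
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Serialize a circuit fit to JSON
#'
#' `{topology, params: {name: {value, stderr}}, chi_square, aic, converged}`.
#'
#' @param fit A `circuit_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  p <- coef(fit)
  params <- lapply(seq_along(p), function(i)
    list(value = unname(p[i]), stderr = unname(fit$uncertainties[i])))
  names(params) <- names(p)
  jsonlite::write_json(list(topology = fit$circuit$topology, params = params,
                            chi_square = fit$chi_square, aic = fit$aic,
                            converged = fit$converged),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
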