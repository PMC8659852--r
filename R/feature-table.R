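#' Change-features: delta and increment
#'
#' The two before/after change transforms applied to every base feature:
#' `dlt(p0, ppl) = p0 - ppl` and
#' `incr(p0, ppl) = (p0 - ppl) / p0 * 100` (percent), where `p0` is the
#' feature's value before contact with plasma and `ppl` its value after
#' incubation.  `incr` is undefined at `p0 = 0` and returns `NA` there with a
#' warning.  Both are vectorised.
#'
#' @param p0,ppl Feature values before and after incubation.
#' @return `dlt`: the difference; `incr`: the percent increment.
#' @examples
#' dlt(10, 7)    # 3
#' incr(10, 7)   # 30
#' @export
dlt <- function(p0, ppl) p0 - ppl

#' @rdname dlt
#' @export
incr <- function(p0, ppl) {
  out <- (p0 - ppl) / p0 * 100
  zero <- !is.na(p0) & p0 == 0
  if (any(zero)) {
    warning("incr: undefined at p0 = 0; returning NA")
    out[zero] <- NA_real_
  }
  out
}

# base-feature registries; order is the fixed export order
cv_feature_names <- function() {
  c("Ea", "Ec", "Einit_a", "Einit_c", "dE", "Ew_a", "Ew_c", "Esh_a", "Esh_c",
    "Ia", "Ic", "Iinit_a", "Iinit_c", "Sa", "Sc", "R_I", "R_S", "E_half")
}
eis_feature_names <- function() c("C_dl", "omega_min", "C_min", "omega_max")

#' Base-feature registry
#'
#' Column registry for the feature table.  `"full"` carries every extracted
#' quantity (18 CV + 4 EIS = 22 base features); `"paper12"` is the reduced
#' 12-feature set (8 CV: peak potentials, their separation, peak currents,
#' peak areas and the area ratio; plus the 4 EIS features).
#'
#' @param base_set `"full"` or `"paper12"`.
#' @return Character vector of base-feature names, in fixed order.
#' @export
feature_registry <- function(base_set = c("full", "paper12")) {
  base_set <- match.arg(base_set)
  if (base_set == "full") c(cv_feature_names(), eis_feature_names())
  else c("Ea", "Ec", "dE", "Ia", "Ic", "Sa", "Sc", "R_S", eis_feature_names())
}

#' Extract per-sample features from a cohort record
#'
#' Runs the CV extractor ([extract_cv_features()]) and the Cole-Cole EIS
#' extractor ([extract_eis_features()]) on both measurement states of a
#' sample record.  Individual extraction failures propagate as `NA` feature
#' values rather than dropping the sample.
#'
#' @param record A sample record from [simulate_cohort()] (or an equivalent
#'   list with `sample_id`, `label` and `before`/`after` `cv`/`eis` entries).
#' @param onset_fraction,baseline_fraction CV extraction settings.
#' @return List with `sample_id`, `label`, and named numeric vectors
#'   `before`/`after` over the full feature registry.
#' @export
extract_sample_features <- function(record, onset_fraction = 0.05,
                                    baseline_fraction = 0.2) {
  one_state <- function(state) {
    cvf <- tryCatch(extract_cv_features(state$cv, onset_fraction,
                                        baseline_fraction),
                    error = function(e) NULL)
    eisf <- tryCatch(extract_eis_features(cole_cole_transform(state$eis)),
                     error = function(e) NULL)
    cvv <- vapply(cv_feature_names(), function(nm)
      if (is.null(cvf)) NA_real_ else as.numeric(cvf[[nm]]), numeric(1))
    eisv <- vapply(eis_feature_names(), function(nm)
      if (is.null(eisf)) NA_real_ else as.numeric(eisf[[nm]]), numeric(1))
    c(cvv, eisv)
  }
  list(sample_id = record$sample_id, label = record$label,
       before = one_state(record$before), after = one_state(record$after))
}

#' Assemble the labelled base + change feature table
#'
#' For every base feature `P` in the chosen registry the table carries three
#' columns: `P` (the before-state value, the sensor's reference condition),
#' `Dlt_P = dlt(P_before, P_after)` and `Incr_P = incr(P_before, P_after)`.
#' With the 12-feature registry this yields exactly 12 base + 24 change
#' columns; change columns always number twice the base columns.  Missing
#' sub-features propagate as `NA` and are never silently dropped.
#'
#' @param records A [simulate_cohort()] cohort, or a list of
#'   [extract_sample_features()] outputs.
#' @param base_set `"full"` (default) or `"paper12"`.
#' @param onset_fraction,baseline_fraction Passed to the extractor when raw
#'   cohort records are supplied.
#' @return A `data.frame` of class `feature_table`: `sample_id`, the feature
#'   columns in registry order, and a trailing `label` factor.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_lc = 2, n_h = 2, seed = 1,
#'                                      points_per_segment = 60))
#' tab <- build_feature_table(coh, base_set = "paper12")
#' dim(tab)   # 4 samples x (1 + 36 + 1) columns
#' @export
build_feature_table <- function(records, base_set = c("full", "paper12"),
                                onset_fraction = 0.05,
                                baseline_fraction = 0.2) {
  base_set <- match.arg(base_set)
  if (length(records) == 0L) stop_apt("build_feature_table: no records")
  feats <- lapply(records, function(r) {
    if (!is.null(r$before) && is.list(r$before) && !is.null(r$before$cv))
      extract_sample_features(r, onset_fraction, baseline_fraction)
    else r
  })
  ids <- vapply(feats, `[[`, "", "sample_id")
  if (anyDuplicated(ids))
    stop_apt("build_feature_table: duplicated sample_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labels <- vapply(feats, `[[`, "", "label")
  if (!all(labels %in% c("LC", "H")))
    stop_apt("build_feature_table: labels must be 'LC' or 'H'")
  reg <- feature_registry(base_set)
  rows <- lapply(feats, function(fr) {
    p0 <- fr$before[reg]
    ppl <- fr$after[reg]
    incr_vals <- suppressWarnings(incr(p0, ppl))
    vals <- c(p0, dlt(p0, ppl), incr_vals)
    names(vals) <- c(reg, paste0("Dlt_", reg), paste0("Incr_", reg))
    vals
  })
  mat <- do.call(rbind, rows)
  # interleave per-feature column triplets: P, Dlt_P, Incr_P
  ord <- as.vector(rbind(seq_along(reg), seq_along(reg) + length(reg),
                         seq_along(reg) + 2L * length(reg)))
  mat <- mat[, ord, drop = FALSE]
  out <- data.frame(sample_id = ids, mat, label = factor(labels,
                                                         levels = c("H", "LC")),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "base_set") <- base_set
  attr(out, "base_features") <- reg
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature columns of a feature table
#'
#' @param table A [build_feature_table()] result.
#' @return Character vector of the feature column names (everything between
#'   `sample_id` and `label`).
#' @export
feature_columns <- function(table) {
  setdiff(colnames(table), c("sample_id", "label"))
}
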