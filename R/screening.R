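#' The default nine-member classifier bank
#'
#' Three interpretable families with three hyperparameter values each:
#' k-nearest neighbours (`k = 1, 3, 5`, Euclidean distance, distance ties
#' broken by the smallest training index), linear soft-margin SVMs
#' (`C = 0.1, 1, 10`) and L2-penalised logistic regressions
#' (inverse-regularisation `C = 0.1, 1, 10`).  All members are deterministic.
#'
#' @return A `data.frame` with columns `family` (`"knn"`, `"svm"`,
#'   `"logistic"`) and `param` (k or C).
#' @export
classifier_bank <- function() {
  data.frame(family = rep(c("knn", "svm", "logistic"), each = 3L),
             param = c(1, 3, 5, 0.1, 1, 10, 0.1, 1, 10),
             stringsAsFactors = FALSE)
}

bank_family_codes <- function(bank) {
  code <- match(bank$family, c("knn", "svm", "logistic"))
  if (anyNA(code))
    stop_apt("unknown classifier family: ",
             paste(unique(bank$family[is.na(code)]), collapse = ", "))
  as.integer(code)
}

bank_labels <- function(bank) {
  ifelse(bank$family == "knn", sprintf("knn_k%d", as.integer(bank$param)),
         sprintf("%s_C%g", bank$family, bank$param))
}

# labels to +1 (LC) / -1 (H)
table_to_xy <- function(table, features) {
  miss <- setdiff(features, colnames(table))
  if (length(miss))
    stop_apt("feature column(s) not in table: ", paste(miss, collapse = ", "))
  lab <- as.character(table$label)
  if (anyNA(lab)) stop_apt("missing labels in feature table")
  y <- ifelse(lab == "LC", 1L, -1L)
  X <- as.matrix(as.data.frame(table)[, feature_columns(table), drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = y, cols = match(features, colnames(X)) - 1L)
}

#' Leave-one-out cross-validated accuracy of one feature subset
#'
#' For each sample, a classifier is trained on all other samples -- features
#' z-scored and missing values mean-imputed with training-fold statistics
#' only -- and the held-out sample is predicted; the returned accuracy is the
#' fraction of correct folds.  A training fold that degenerates to a single
#' class predicts the majority class.
#'
#' @param table A [build_feature_table()] result (or any data.frame with
#'   feature columns and a `label` column with levels `H`/`LC`).
#' @param features Character vector of feature column names (the subset).
#' @param family,param Classifier family (`"knn"`, `"svm"`, `"logistic"`)
#'   and its hyperparameter (k or C).
#' @param detail If `TRUE`, also return the per-fold predictions.
#' @return The accuracy fraction, or (with `detail`) a list with `accuracy`
#'   and `predictions` (character vector of per-fold predicted labels).
#' @export
loocv_accuracy <- function(table, features, family = "knn", param = 1,
                           detail = FALSE) {
  d <- table_to_xy(table, features)
  if (sum(d$y > 0) < 2L || sum(d$y < 0) < 2L)
    stop_apt("loocv_accuracy: need at least 2 samples per class")
  bank <- data.frame(family = family, param = param)
  res <- cpp_loocv_detail(d$X, d$y, d$cols,
                          bank_family_codes(bank), as.numeric(bank$param))
  if (!detail) return(res$accuracy[1L])
  list(accuracy = res$accuracy[1L],
       predictions = ifelse(res$predictions[1L, ] > 0, "LC", "H"))
}

#' Exhaustive feature-combination screen
#'
#' Evaluates every feature combination of the given size against every bank
#' member under leave-one-out cross-validation and returns all results ranked
#' by accuracy.  Ties are broken by lexicographic feature names, then by
#' family in bank order, then by hyperparameter -- the ranking is fully
#' deterministic.
#'
#' @inheritParams loocv_accuracy
#' @param subset_size Combination size (1, 2 or 3).
#' @param bank Classifier bank data.frame (default [classifier_bank()]).
#' @param features Optional restriction of the screened feature columns
#'   (default: all feature columns of the table).
#' @param max_combinations Safety cap on the number of enumerated
#'   combinations.
#' @return A `data.frame` of class `screen_result` with columns `features`
#'   (comma-joined subset), `family`, `param`, `accuracy`, sorted by
#'   decreasing accuracy.
#' @examples
#' tab <- data.frame(a = c(1, 2, 8, 9, 1.5, 8.5), b = rnorm(6),
#'                   label = factor(c("H", "H", "LC", "LC", "H", "LC"),
#'                                  levels = c("H", "LC")))
#' head(screen_combinations(tab, 1))
#' @export
screen_combinations <- function(table, subset_size = 2L,
                                bank = classifier_bank(), features = NULL,
                                max_combinations = 2e5) {
  if (!subset_size %in% 1:3)
    stop_apt("screen_combinations: subset_size must be 1, 2 or 3")
  if (is.null(bank) || nrow(bank) == 0L)
    stop_apt("screen_combinations: empty classifier bank")
  if (is.null(features)) features <- feature_columns(table)
  if (subset_size > length(features))
    stop_apt("screen_combinations: subset_size exceeds the number of features")
  combos <- combn(sort(features), subset_size)
  if (ncol(combos) > max_combinations)
    stop_apt("screen_combinations: ", ncol(combos),
             " combinations exceed max_combinations = ", max_combinations)
  d <- table_to_xy(table, features)
  idx <- matrix(match(combos, colnames(d$X)) - 1L, nrow = subset_size)
  acc <- cpp_screen_engine(d$X, d$y, idx,
                           bank_family_codes(bank), as.numeric(bank$param))
  nb <- nrow(bank)
  nc <- ncol(combos)
  res <- data.frame(
    features = rep(apply(combos, 2L, paste, collapse = ","), times = nb),
    family = rep(bank$family, each = nc),
    param = rep(bank$param, each = nc),
    accuracy = as.vector(acc),
    stringsAsFactors = FALSE)
  fam_rank <- match(res$family, unique(classifier_bank()$family))
  ord <- order(-res$accuracy, res$features, fam_rank, res$param)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "subset_size") <- subset_size
  attr(res, "n_samples") <- nrow(table)
  class(res) <- c("screen_result", "data.frame")
  res
}

#' @export
print.screen_result <- function(x, n = 10L, ...) {
  cat(sprintf("Feature-combination screen: %d results (size %d, %d samples)\n",
              nrow(x), attr(x, "subset_size"), attr(x, "n_samples")))
  cat(sprintf("  max LOOCV accuracy: %.3f\n", max(x$accuracy)))
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

#' Summarise a combination screen
#'
#' Reports the maximum accuracy, the top combinations with their best
#' classifier, and how often each feature appears among the top decile of
#' combinations.
#'
#' @param results A [screen_combinations()] result.
#' @param top_n Number of top combinations to report.
#' @return Object of class `screen_summary` with `max_accuracy`, `top`
#'   (data.frame of the best classifier per combination, ranked) and
#'   `feature_counts` (appearance counts in the top decile).
#' @export
summarize_screen <- function(results, top_n = 10L) {
  if (is.null(results) || nrow(results) == 0L)
    stop_apt("summarize_screen: empty results")
  best_per_combo <- results[!duplicated(results$features), , drop = FALSE]
  top <- head(best_per_combo, top_n)
  top$rank <- seq_len(nrow(top))
  dec <- head(best_per_combo, max(1L, ceiling(nrow(best_per_combo) / 10)))
  feats <- unlist(strsplit(dec$features, ",", fixed = TRUE))
  structure(list(max_accuracy = max(results$accuracy),
                 top = top,
                 feature_counts = sort(table(feats), decreasing = TRUE)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Best LOOCV mean accuracy: %.3f\n", x$max_accuracy))
  cat("Top combinations (best classifier each):\n")
  print.data.frame(x$top[, c("rank", "features", "family", "param", "accuracy")])
  cat("Feature appearances in the top decile:\n")
  print(x$feature_counts)
  invisible(x)
}
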