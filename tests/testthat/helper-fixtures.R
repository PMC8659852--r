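# shared in-code fixtures

# a bare sweep segment (plain list, as consumed by the peak operations)
make_segment <- function(current_fn, window = c(-0.5, 0.8), n = 261L,
                         direction = +1) {
  E <- seq(window[1], window[2], length.out = n)
  if (direction < 0) E <- rev(E)
  list(potential = E, current = current_fn(E), direction = direction)
}

gaussian_segment <- function(mu = 0.3, s = 0.05, h = 1e-5, slope = 0,
                             intercept = 0, noise_sd = 0, seed = NULL,
                             window = c(-0.5, 0.8), n = 261L) {
  fn <- function(E) {
    base <- slope * E + intercept + h * exp(-(E - mu)^2 / (2 * s^2))
    if (noise_sd > 0) {
      if (!is.null(seed)) set.seed(seed)
      base <- base + rnorm(length(E), sd = noise_sd)
    }
    base
  }
  make_segment(fn, window = window, n = n)
}

grid_step <- function(segment) abs(diff(segment$potential[1:2]))

# Table-4-style "before treatment" Randles circuit used in the recovery tests
table4_m0 <- function() {
  circuit_spec("M0_randles_w",
               c(Rs = 100, CPE_T = 4.2e-5, CPE_P = 0.72, Rct = 2e3,
                 W_R = 3e3, W_T = 0.05, W_P = 0.45))
}

# small labelled feature table with separated classes in feature `a`
separable_table <- function(n_per_class = 3, gap = 10, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  data.frame(a = c(rnorm(n_per_class), gap + rnorm(n_per_class)),
             b = rnorm(n),
             label = factor(rep(c("H", "LC"), each = n_per_class),
                            levels = c("H", "LC")))
}

# brute-force LOOCV over the bank using independent implementations
# (hand-rolled knn, e1071 SVM, glmnet ridge logistic)
naive_loocv <- function(X, y, family, param) {
  n <- nrow(X); p <- ncol(X)
  preds <- character(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0 | is.na(sdv)] <- Inf
    Xs <- scale(X[tr, , drop = FALSE], mu, sdv)
    xt <- (X[i, ] - mu) / sdv
    yy <- ifelse(y[tr] == "LC", 1, -1)
    preds[i] <- if (family == "knn") {
      d <- rowSums((Xs - matrix(xt, length(tr), p, byrow = TRUE))^2)
      o <- order(d, seq_along(d))
      v <- sum(yy[o[seq_len(min(param, length(tr)))]])
      if (v > 0) "LC" else if (v < 0) "H" else if (yy[o[1]] > 0) "LC" else "H"
    } else if (family == "svm") {
      m <- e1071::svm(Xs, factor(y[tr], levels = c("H", "LC")),
                      kernel = "linear", cost = param, scale = FALSE)
      as.character(predict(m, matrix(xt, 1)))
    } else {
      m <- suppressWarnings(
        glmnet::glmnet(Xs, factor(y[tr], levels = c("H", "LC")),
                       family = "binomial", alpha = 0,
                       lambda = 1 / (length(tr) * param),
                       standardize = FALSE, thresh = 1e-14, maxit = 1e6))
      as.character(predict(m, matrix(xt, 1), type = "class"))
    }
  }
  mean(preds == y)
}
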