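test_that("the default bank has nine deterministic members", {
  bank <- classifier_bank()
  expect_identical(nrow(bank), 9L)
  expect_identical(table(bank$family)[c("knn", "svm", "logistic")],
                   table(rep(c("knn", "svm", "logistic"), each = 3))[
                     c("knn", "svm", "logistic")])
})

test_that("perfectly separated one-dimensional clusters give accuracy 1", {
  tab <- separable_table(n_per_class = 5, gap = 50)
  expect_equal(loocv_accuracy(tab, "a", "knn", 1), 1.0)
  expect_equal(loocv_accuracy(tab, "a", "svm", 1), 1.0)
  expect_equal(loocv_accuracy(tab, "a", "logistic", 10), 1.0)
})

test_that("LOOCV equals a brute-force double loop with independent classifiers", {
  set.seed(21)
  for (rep in 1:4) {
    n <- c(6, 8)[1 + rep %% 2]
    p <- c(2, 3, 4)[1 + rep %% 3]
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("f", seq_len(p))
    y <- rep(c("H", "LC"), length.out = n)
    tab <- data.frame(X, label = factor(y, levels = c("H", "LC")))
    bank <- classifier_bank()
    for (b in seq_len(nrow(bank))) {
      mine <- loocv_accuracy(tab, colnames(X), bank$family[b], bank$param[b])
      ref <- naive_loocv(X, y, bank$family[b], bank$param[b])
      expect_equal(mine, ref,
                   info = sprintf("rep %d %s %g", rep, bank$family[b],
                                  bank$param[b]))
    }
  }
})

test_that("permuted labels score at the exchangeable chance level", {
  # For 1-NN under exchangeable noise the exact null accuracy is the
  # probability that the nearest neighbour shares the held-out label:
  # (n/2 - 1)/(n - 1) = 9/19 for n = 20 -- slightly below 1/2 because the
  # training fold under-represents the held-out class.
  set.seed(31)
  n <- 20
  X <- matrix(rnorm(n * 2), n)
  colnames(X) <- c("u", "v")
  base_y <- rep(c("H", "LC"), each = n / 2)
  accs <- vapply(seq_len(200), function(i) {
    tab <- data.frame(X, label = factor(sample(base_y), levels = c("H", "LC")))
    loocv_accuracy(tab, c("u", "v"), "knn", 1)
  }, 0)
  null_mean <- (n / 2 - 1) / (n - 1)
  se <- sd(accs) / sqrt(length(accs))
  z <- (mean(accs) - null_mean) / se
  expect_lt(abs(z), qnorm(1 - 0.01 / 2))   # alpha = 0.01 against the exact null
  expect_lt(abs(mean(accs) - 0.5), 0.05)   # and chance level overall
})

test_that("standardization and imputation use training folds only", {
  set.seed(7)
  n <- 20
  y <- rep(c("H", "LC"), each = n / 2)
  tab <- data.frame(canary = as.numeric(y == "LC"),
                    parity = seq_len(n) %% 2,
                    noise = rnorm(n),
                    label = factor(y, levels = c("H", "LC")))
  # a feature equal to the label must be learned perfectly
  expect_equal(loocv_accuracy(tab, "canary", "knn", 1), 1.0)
  expect_equal(loocv_accuracy(tab, "canary", "logistic", 1), 1.0)
  # a feature encoding the held-out index only scores at chance
  expect_lt(loocv_accuracy(tab, "parity", "knn", 1), 0.75)
})

test_that("screens enumerate C(p, k) x bank results and rank deterministically", {
  tab <- separable_table(n_per_class = 4)
  tab$c <- rnorm(8)
  res <- screen_combinations(tab, 2)
  expect_identical(nrow(res), 27L)   # C(3,2) x 9 bank members
  res2 <- screen_combinations(tab, 2)
  expect_identical(res, res2)
  expect_true(all(diff(res$accuracy) <= 0))
})

test_that("a constant feature is inert under standardization", {
  tab <- separable_table(n_per_class = 4)
  base <- loocv_accuracy(tab, c("a", "b"), "svm", 1)
  tab$const <- 5
  expect_equal(loocv_accuracy(tab, c("a", "b"), "svm", 1), base)
  expect_equal(loocv_accuracy(tab, c("a", "b", "const"), "svm", 1), base)
  expect_equal(loocv_accuracy(tab, c("a", "b", "const"), "knn", 3),
               loocv_accuracy(tab, c("a", "b"), "knn", 3))
})

test_that("a planted jointly-informative pair is recovered by the screen", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 20
    cls <- rep(c(-1, 1), each = n / 2)
    u <- runif(n, -2, 2)   # wide enough that each marginal overlaps
    X <- cbind(pair1 = u,
               pair2 = 1.2 * cls - u + rnorm(n, sd = 0.05),
               matrix(rnorm(n * 4), n,
                      dimnames = list(NULL, paste0("noise", 1:4))))
    tab <- data.frame(X, label = factor(ifelse(cls > 0, "LC", "H"),
                                        levels = c("H", "LC")))
    top <- screen_combinations(tab, 2)$features[1]
    if (top == "pair1,pair2") hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("screen summaries agree with the raw results", {
  tab <- separable_table(n_per_class = 4)
  res <- screen_combinations(tab, 1)
  s <- summarize_screen(res, top_n = 3)
  expect_equal(s$max_accuracy, max(res$accuracy))
  expect_identical(s$top$rank, seq_len(nrow(s$top)))
  one <- res[1, , drop = FALSE]
  class(one) <- c("screen_result", "data.frame")
  s1 <- summarize_screen(one)
  expect_identical(nrow(s1$top), 1L)
  expect_identical(s1$top$rank, 1L)
})

test_that("degenerate inputs are rejected", {
  tab <- separable_table(n_per_class = 4)
  expect_error(screen_combinations(tab, 5), "subset_size")
  expect_error(screen_combinations(tab, 2, bank = data.frame()), "empty")
  expect_error(loocv_accuracy(tab, "nope", "knn", 1), "not in table")
  one_class <- data.frame(a = rnorm(4), label = factor(rep("LC", 4),
                                                       levels = c("H", "LC")))
  expect_error(loocv_accuracy(one_class, "a", "knn", 1), "2 samples per class")
})
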