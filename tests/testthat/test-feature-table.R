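fake_feature_record <- function(id, label, before, after = before) {
  reg <- feature_registry("full")
  mk <- function(x) {
    v <- setNames(rep(1, length(reg)), reg)
    v[names(x)] <- unlist(x)
    v
  }
  list(sample_id = id, label = label, before = mk(before), after = mk(after))
}

test_that("dlt and incr follow their defining arithmetic", {
  expect_identical(dlt(10, 7), 3)
  expect_identical(dlt(5, 5), 0)
  expect_identical(dlt(-2.5, 1.5), -4.0)
  expect_equal(incr(10, 7), 30.0)
  expect_equal(incr(3.3, 3.3), 0)
  expect_equal(incr(4.2e-5, 4.2e-7), 99.0)
  expect_warning(z <- incr(0, 5), "undefined")
  expect_true(is.na(z))
})

test_that("the reduced base set yields exactly 12 base and 24 change columns", {
  recs <- list(fake_feature_record("a", "LC", list(Ea = 2)),
               fake_feature_record("b", "H", list(Ea = 3)))
  tab <- build_feature_table(recs, base_set = "paper12")
  feats <- feature_columns(tab)
  expect_length(feats, 36L)
  expect_length(grep("^Dlt_", feats), 12L)
  expect_length(grep("^Incr_", feats), 12L)
  expect_length(setdiff(feats, grep("^(Dlt|Incr)_", feats, value = TRUE)), 12L)
  expect_false(anyDuplicated(colnames(tab)) > 0)
})

test_that("the full base set yields 22 base and 44 change columns", {
  recs <- list(fake_feature_record("a", "LC", list()),
               fake_feature_record("b", "H", list()))
  tab <- build_feature_table(recs, base_set = "full")
  feats <- feature_columns(tab)
  expect_length(feats, 66L)
  expect_length(grep("^(Dlt|Incr)_", feats), 44L)
})

test_that("identical before/after states zero every defined change-feature", {
  recs <- list(fake_feature_record("a", "LC", list(Ea = 2, Ic = 5)),
               fake_feature_record("b", "H", list(Ea = 1)))
  tab <- build_feature_table(recs)
  expect_true(all(unlist(tab[, grep("^Dlt_", colnames(tab))]) == 0))
  expect_true(all(unlist(tab[, grep("^Incr_", colnames(tab))]) == 0))
})

test_that("the increment column equals Dlt/P0 x 100 wherever both are defined", {
  coh <- simulate_cohort(cohort_config(n_lc = 2, n_h = 2, seed = 5,
                                       points_per_segment = 80L,
                                       frequencies = default_eis_frequencies(16)))
  tab <- build_feature_table(coh)
  for (base in attr(tab, "base_features")) {
    p0 <- tab[[base]]
    d <- tab[[paste0("Dlt_", base)]]
    ic <- tab[[paste0("Incr_", base)]]
    ok <- !is.na(p0) & !is.na(d) & !is.na(ic) & p0 != 0
    expect_equal(ic[ok], d[ok] / p0[ok] * 100, tolerance = 1e-12)
  }
})

test_that("permuting input records permutes rows only", {
  recs <- list(fake_feature_record("a", "LC", list(Ea = 2), list(Ea = 1)),
               fake_feature_record("b", "H", list(Ea = 3)),
               fake_feature_record("c", "LC", list(Ic = 7), list(Ic = 5)))
  t1 <- build_feature_table(recs)
  t2 <- build_feature_table(recs[c(3, 1, 2)])
  reord <- t2[match(t1$sample_id, t2$sample_id), ]
  rownames(reord) <- NULL
  expect_equal(as.data.frame(t1), as.data.frame(reord))
})

test_that("duplicated sample ids and missing data are handled loudly", {
  recs <- list(fake_feature_record("a", "LC", list()),
               fake_feature_record("a", "H", list()))
  expect_error(build_feature_table(recs), "duplicated sample_id")

  r_na <- fake_feature_record("a", "LC", list(omega_min = NA_real_))
  tab <- build_feature_table(list(r_na, fake_feature_record("b", "H", list())))
  expect_identical(nrow(tab), 2L)           # the row survives
  expect_true(is.na(tab$omega_min[tab$sample_id == "a"]))
})
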