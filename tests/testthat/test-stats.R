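test_that("Clopper-Pearson bounds match closed forms and the root of the tail equation", {
  ci <- clopper_pearson(9, 10, 0.95)
  # Independent oracle: the lower bound solves P(Bin(10, p) >= 9) = 0.025,
  # i.e. 10 p^9 - 9 p^10 = 0.025, found by uniroot on the polynomial.
  root <- uniroot(
    function(p) 10 * p^9 - 9 * p^10 - 0.025,
    c(1e-6, 1 - 1e-6),
    tol = 1e-12
  )$root
  expect_equal(ci$lower, root, tolerance = 1e-7)
  expect_equal(ci$lower, 0.5550, tolerance = 5e-4)

  expect_identical(clopper_pearson(0, 10)$lower, 0)
  expect_identical(clopper_pearson(10, 10)$upper, 1)
  expect_equal(clopper_pearson(10, 10)$lower, 0.025^(1 / 10), tolerance = 1e-7)
  expect_equal(clopper_pearson(0, 10)$upper, 1 - 0.025^(1 / 10), tolerance = 1e-7)
})

test_that("Clopper-Pearson agrees with stats::binom.test across a grid", {
  for (n in c(1, 5, 10, 17, 25)) {
    for (x in unique(c(0, 1, n %/% 2, n))) {
      ci <- clopper_pearson(x, n, 0.95)
      ref <- binom.test(x, n)$conf.int
      expect_equal(ci$lower, ref[1], tolerance = 1e-6)
      expect_equal(ci$upper, ref[2], tolerance = 1e-6)
    }
  }
})

test_that("exact interval coverage is at least nominal for small n", {
  for (n in c(5, 10, 15)) {
    bounds <- lapply(0:n, function(x) clopper_pearson(x, n, 0.95))
    for (p in seq(0.05, 0.95, by = 0.15)) {
      covered <- vapply(0:n, function(x) {
        ci <- bounds[[x + 1]]
        ci$lower <= p && p <= ci$upper
      }, logical(1))
      expect_gte(sum(dbinom(0:n, n, p)[covered]), 0.95)
    }
  }
})

test_that("invalid binomial inputs are rejected", {
  expect_error(clopper_pearson(-1, 10), class = "mrdtrace_input_error")
  expect_error(clopper_pearson(11, 10), class = "mrdtrace_input_error")
  expect_error(clopper_pearson(1, 0), class = "mrdtrace_config_error")
})

test_that("Pearson chi-square matches the hand formula and chisq.test", {
  tab <- matrix(c(1, 8, 7, 9), nrow = 2)
  res <- pearson_chi2(tab)
  # Hand evaluation of sum (O - E)^2 / E on this table.
  expect_equal(res$statistic, 2.81989, tolerance = 1e-4)
  expect_equal(res$p_value, 0.09310, tolerance = 1e-4)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)

  yates <- pearson_chi2(tab, correct = TRUE)
  ref_y <- suppressWarnings(chisq.test(tab, correct = TRUE))
  expect_equal(yates$statistic, unname(ref_y$statistic), tolerance = 1e-10)
  expect_true(yates$correction_applied)
})

test_that("chi-square p agrees with the normal-tail identity for df = 1", {
  for (tab in list(
    matrix(c(1, 8, 7, 9), 2), matrix(c(12, 3, 5, 20), 2),
    matrix(c(2, 2, 9, 4), 2)
  )) {
    res <- pearson_chi2(tab)
    expect_equal(
      res$p_value, 2 * (1 - pnorm(sqrt(res$statistic))),
      tolerance = 1e-9
    )
  }
})

test_that("chi-square is symmetric under row/column swaps and zero for proportional tables", {
  tab <- matrix(c(1, 8, 7, 9), nrow = 2)
  expect_equal(pearson_chi2(tab)$statistic, pearson_chi2(t(tab))$statistic)
  expect_equal(
    pearson_chi2(tab)$statistic,
    pearson_chi2(tab[2:1, 2:1])$statistic
  )
  even <- pearson_chi2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
})

test_that("degenerate tables are rejected", {
  expect_error(
    pearson_chi2(matrix(c(0, 0, 3, 4), 2)),
    class = "mrdtrace_degenerate_table"
  )
  expect_error(pearson_chi2(matrix(1:6, 3)), class = "mrdtrace_input_error")
})

test_that("concordance reproduces worked fractions and is symmetric", {
  assayable <- paste0("v", 1:33)
  tissue <- paste0("v", 1:30)
  blood <- paste0("v", c(1:27, 31:33))
  res <- concordance(tissue, blood, assayable)
  expect_equal(res$n_both, 27L)
  expect_equal(res$fraction, 27 / 33)
  expect_equal(res$percent, "82%")
  flipped <- concordance(blood, tissue, assayable)
  expect_equal(res$fraction, flipped$fraction)

  all_in <- concordance(assayable, assayable, assayable)
  expect_equal(all_in$fraction, 1)
  disjoint <- concordance(paste0("v", 1:10), paste0("v", 20:30), assayable)
  expect_equal(disjoint$fraction, 0)
  expect_warning(empty <- concordance(character(0), character(0), character(0)))
  expect_true(is.na(empty$fraction))
})

test_that("rounding and percent rendering follow report conventions", {
  expect_equal(round_half_up(4.25, 1), 4.3)
  expect_equal(round_half_up(-4.25, 1), -4.3)
  expect_equal(round_half_up(2.5), 3)
  expect_identical(fmt_percent(1 / 8), "12.5%")
  expect_identical(fmt_percent(8 / 17), "47%")
  expect_identical(fmt_percent(27 / 33), "82%")
  expect_identical(fmt_percent(0.9), "90%")
})

test_that("tidy and glance methods return one-row tibbles", {
  td <- tidy(pearson_chi2(matrix(c(1, 8, 7, 9), 2)))
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  tb <- tidy(clopper_pearson(9, 10))
  expect_named(
    tb,
    c("estimate", "successes", "trials", "conf.level", "conf.low", "conf.high")
  )
})
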