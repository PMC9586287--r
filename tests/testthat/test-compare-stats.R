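test_that("conservativeness fractions use strict comparison over the overlap", {
  a <- toy_moe_table(c("X", "Y", "Z"), c(1, 2, 3))
  b <- toy_moe_table(c("X", "Y", "Z"), c(2, 2, 1))
  res <- conservativeness_fractions(a, b)
  expect_identical(res$n_common, 3L)
  expect_equal(res$frac_a_lt_b, 1 / 3)
  expect_equal(conservativeness_fractions(a, a)$frac_a_lt_b, 0)
  small <- toy_moe_table(c("X", "Y", "Z"), c(0.1, 0.2, 0.3))
  expect_equal(conservativeness_fractions(small, a)$frac_a_lt_b, 1)
  # ties absorb the remainder
  expect_lte(conservativeness_fractions(a, b)$frac_a_lt_b +
               conservativeness_fractions(b, a)$frac_a_lt_b, 1)
  expect_error(conservativeness_fractions(a, toy_moe_table("Q", 1)),
               "no chemicals")
})

test_that("log-space r2 detects perfect relations and independence", {
  withr::with_seed(8, {
    ids <- sprintf("c%04d", 1:200)
    base <- stats::rlnorm(200, 0, 1)
    a <- toy_moe_table(ids, base)
    expect_equal(log_r2(a, toy_moe_table(ids, base * 10)), 1)
    expect_equal(log_r2(a, toy_moe_table(ids, 1 / base)), 1)
    # symmetry
    b <- toy_moe_table(ids, stats::rlnorm(200))
    expect_equal(log_r2(a, b), log_r2(b, a))
  })
  withr::with_seed(9, {
    ids <- sprintf("c%05d", 1:10000)
    x <- toy_moe_table(ids, stats::rlnorm(10000))
    y <- toy_moe_table(ids, stats::rlnorm(10000))
    expect_lt(log_r2(x, y), 0.01)
  })
  flat <- toy_moe_table(c("a", "b", "c"), c(2, 2, 2))
  var_ <- toy_moe_table(c("a", "b", "c"), c(1, 2, 3))
  expect_warning(r <- log_r2(flat, var_), "zero variance")
  expect_true(is.na(r))
})

test_that("median MoE ratio is the type-2 median of per-chemical ratios", {
  num <- toy_moe_table(c("a", "b", "c"), c(1, 10, 100))
  den <- toy_moe_table(c("a", "b", "c"), c(1, 1, 1))
  expect_equal(median_moe_ratio(num, den), 10)
  expect_equal(median_moe_ratio(num, num), 1)
  scaled <- toy_moe_table(c("a", "b", "c"), c(1, 10, 100) * 3)
  expect_equal(median_moe_ratio(scaled, den), 30)
})

test_that("identical samples give D = 0 and a rank-sum p near 1", {
  x <- c(1, 2, 3, 4, 5)
  res <- suppressWarnings(group_difference_tests(x, x))
  expect_true(res$computed)
  expect_equal(res$ks$statistic, 0)
  expect_gte(res$rank_sum$p_value, 0.99)
  res2 <- suppressWarnings(group_difference_tests(c(1, 2), c(1, 2)))
  expect_equal(res2$ks$statistic, 0)
  expect_false(group_difference_tests(1, c(1, 2))$computed)
})

test_that("the KS statistic is bounded and detects disjoint supports", {
  res <- group_difference_tests(1:10, 101:110)
  expect_equal(res$ks$statistic, 1)
  expect_lt(res$ks$p_value, 0.01)
  withr::with_seed(13, {
    for (rep in 1:20) {
      x <- stats::rnorm(sample(5:30, 1)); y <- stats::rnorm(sample(5:30, 1))
      d <- suppressWarnings(group_difference_tests(x, y))$ks$statistic
      expect_gte(d, 0); expect_lte(d, 1)
    }
  })
})

test_that("compare_moe_tables assembles the full summary", {
  withr::with_seed(21, {
    ids <- sprintf("c%03d", 1:80)
    ttc <- toy_moe_table(ids, stats::rlnorm(80, -1),
                         category = sample(c("CRAMER_I", "CRAMER_III"), 80,
                                           replace = TRUE))
    oed <- toy_moe_table(ids, stats::rlnorm(80, 1))
    noael <- toy_moe_table(ids, stats::rlnorm(80, 3))
    cs <- compare_moe_tables(ttc, oed, noael)
  })
  expect_identical(cs$n_common, 80L)
  expect_gte(cs$frac_ttc_lt_oed, 0); expect_lte(cs$frac_ttc_lt_oed, 1)
  expect_gte(cs$r2_log_noael_vs_ttc, 0); expect_lte(cs$r2_log_noael_vs_ttc, 1)
  expect_gt(cs$median_ratio_noael_over_ttc, 1)
  expect_true(all(c("CRAMER_I", "CRAMER_III") %in% names(cs$category_tests)))
})
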