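test_that("exposure selection prefers SEEM3 and falls back to SEEM2", {
  exp_tab <- data.frame(
    chem_id = c("a", "a", "b", "c"),
    source = c("SEEM3", "SEEM2", "SEEM2", "SEEM3"),
    median = c(1, 2, 3, 4), upper95 = c(10, 20, 30, 40),
    stringsAsFactors = FALSE
  )
  sel <- select_exposure(exp_tab)
  expect_identical(sel$source[sel$chem_id == "a"], "SEEM3")
  expect_identical(sel$upper95[sel$chem_id == "a"], 10)
  expect_identical(sel$source[sel$chem_id == "b"], "SEEM2")
  expect_error(select_exposure(transform(exp_tab, source = "SEEM9")),
               "SEEM3 or SEEM2")
  expect_error(select_exposure(transform(exp_tab, upper95 = median / 2)),
               "upper95")
})

test_that("MoE = PoD / upper95 with a strict less-than-one flag", {
  pods <- data.frame(chem_id = c("a", "b", "c"), pod_type = "TTC",
                     pod = c(0.0015, 0.03, 0.5), stringsAsFactors = FALSE)
  expo <- data.frame(chem_id = c("a", "b", "c"), source = "SEEM3",
                     median = 1, upper95 = c(0.0015, 0.003, 5),
                     stringsAsFactors = FALSE)
  moe <- compute_moe_table(pods, expo)
  m <- moe[match(c("a", "b", "c"), moe$chem_id), ]
  expect_equal(m$moe, c(1, 10, 0.1))
  expect_identical(m$lt1, c(FALSE, FALSE, TRUE))  # boundary MoE = 1 unflagged
})

test_that("MoE is scale-invariant and monotone in its two arguments", {
  withr::with_seed(3, {
    pod <- stats::rlnorm(20); up <- stats::rlnorm(20)
    pods <- data.frame(chem_id = sprintf("c%02d", 1:20), pod_type = "OED",
                       pod = pod, stringsAsFactors = FALSE)
    expo <- data.frame(chem_id = sprintf("c%02d", 1:20), source = "SEEM3",
                       median = up / 2, upper95 = up, stringsAsFactors = FALSE)
    m1 <- compute_moe_table(pods, expo)
    k <- 7.3
    m2 <- compute_moe_table(transform(pods, pod = pod * k),
                            transform(expo, median = median * k,
                                      upper95 = upper95 * k))
    expect_equal(m1$moe, m2$moe)
    m3 <- compute_moe_table(pods, transform(expo, upper95 = upper95 * 2))
    expect_equal(sort(m3$moe), sort(m1$moe / 2))
  })
})

test_that("chemicals without exposure rows are dropped and counted", {
  pods <- data.frame(chem_id = c("a", "b"), pod_type = "TTC", pod = c(1, 2),
                     stringsAsFactors = FALSE)
  expo <- data.frame(chem_id = "a", source = "SEEM3", median = 1,
                     upper95 = 2, stringsAsFactors = FALSE)
  moe <- compute_moe_table(pods, expo)
  expect_identical(moe$chem_id, "a")
  expect_identical(attr(moe, "n_no_exposure"), 1L)
})

test_that("ranking is ascending by MoE with chem_id tie-break", {
  tab <- toy_moe_table(c("A", "B", "C"), c(0.5, 2, 0.1))
  top <- rank_by_moe(tab, 2)
  expect_identical(top$chem_id, c("C", "A"))
  ties <- toy_moe_table(c("Z", "A", "M"), c(1, 1, 1))
  expect_identical(rank_by_moe(ties, 3)$chem_id, c("A", "M", "Z"))
  expect_identical(nrow(rank_by_moe(tab, 100)), 3L)
  expect_error(rank_by_moe(tab, 0), ">= 1")
})

test_that("category summary conserves counts and uses the type-2 median", {
  tab <- toy_moe_table(sprintf("c%02d", 1:6), c(0.5, 2, 4, 8, 0.2, 0.8),
                       category = c(rep("CRAMER_III", 4), rep("CRAMER_I", 2)))
  s <- summarize_by_category(tab)
  tot <- s[s$category == "Total", ]
  expect_identical(sum(s$n[s$category != "Total"]), tot$n)
  expect_identical(sum(s$n_lt1[s$category != "Total"]), tot$n_lt1)
  expect_equal(s$median_moe[s$category == "CRAMER_III"],
               (2 + 4) / 2)  # even n: mean of middle pair
  one_cat <- toy_moe_table(c("a", "b"), c(1, 2), category = "CRAMER_I")
  s1 <- summarize_by_category(one_cat)
  expect_equal(s1$median_moe[1], s1$median_moe[s1$category == "Total"])
})
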