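test_that("generate_chemicals honors the mix, ids and seed", {
  degenerate <- generate_chemicals(10, c(CRAMER_I = 1), seed = 1)
  expect_identical(nrow(degenerate), 10L)
  expect_true(all(degenerate$truth_category == "CRAMER_I"))
  expect_false(anyDuplicated(degenerate$chem_id) > 0)
  a <- generate_chemicals(100, seed = 7)
  b <- generate_chemicals(100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_chemicals(100, seed = 8)))
  expect_error(generate_chemicals(0), ">= 1")
  expect_error(generate_chemicals(5, c(CRAMER_I = 0.5)), "sum to 1")
  expect_true(all(a$mw > 0))
})

test_that("the classifier recovers every generated truth label", {
  chems <- generate_chemicals(100, seed = 3)
  prof <- classify_chemicals(chems)
  asg <- assign_ttc(prof, genotox_filter = TRUE)
  got <- asg$category[match(chems$chem_id, asg$chem_id)]
  expect_identical(got, chems$truth_category)
})

test_that("bioactivity generation is seeded with the stated distribution", {
  chems <- generate_chemicals(5, seed = 2)
  one <- generate_bioactivity(chems[1, ], n_assays_range = c(1, 1),
                              logmean = log(10), logsd = 0, seed = 1)
  expect_identical(nrow(one), 1L)
  expect_equal(one$ac50_uM, 10)
  a <- generate_bioactivity(chems, seed = 5)
  expect_identical(a, generate_bioactivity(chems, seed = 5))
  expect_true(all(a$ac50_uM > 0))
  # lognormal median = exp(logmean)
  big <- generate_bioactivity(generate_chemicals(300, seed = 1),
                              n_assays_range = c(30, 40),
                              logmean = log(1), logsd = 1, seed = 9)
  expect_gt(nrow(big), 9000)
  expect_lt(abs(stats::median(big$ac50_uM) - 1), 0.1)
  expect_error(generate_bioactivity(chems[0, ]), "non-empty")
  expect_error(generate_bioactivity(chems, n_assays_range = c(1, 500)),
               "1, 200")
})

test_that("PK generation respects the fup range and Clint point mass", {
  chems <- generate_chemicals(200, seed = 4)
  pk <- generate_pk(chems, seed = 6)
  expect_true(all(pk$fup > 0 & pk$fup <= 1))
  expect_true(all(pk$clint >= 0))
  expect_identical(pk, generate_pk(chems, seed = 6))
  all_zero <- generate_pk(chems, p_clint_zero = 1, seed = 6)
  expect_true(all(all_zero$clint == 0))
})

test_that("exposure generation fixes the upper95/median factor and sources", {
  chems <- generate_chemicals(150, seed = 4)
  ex <- generate_exposures(chems, seed = 2)
  expect_identical(nrow(ex), nrow(chems))
  expect_equal(ex$upper95, ex$median * 10)
  flat <- generate_exposures(chems, upper95_factor = 1, seed = 2)
  expect_equal(flat$upper95, flat$median)
  s3only <- generate_exposures(chems, seem2_fraction = 0, seed = 2)
  expect_true(all(s3only$source == "SEEM3"))
  expect_identical(ex, generate_exposures(chems, seed = 2))
  expect_error(generate_exposures(chems, upper95_factor = 0.5), ">= 1")
})

test_that("NOAEL sets anchor their 5th percentile at 100x the truth TTC", {
  chem <- generate_chemicals(1, c(CRAMER_III = 1), seed = 1)
  # generating distribution: 5th percentile must be 100 x 1.5/1000 = 0.15
  many <- generate_noael_sets(chem[rep(1, 400), ], ttc_consistent = TRUE,
                              n_range = c(30, 30), decoy_fraction = 0,
                              seed = 11)
  p5 <- quantile_type2(many$value, 0.05)
  expect_equal(p5, 0.15, tolerance = 0.1)
  # conforming records only when decoy_fraction = 0
  expect_identical(nrow(filter_noael_records(many)), nrow(many))
  withdecoys <- generate_noael_sets(chem, n_range = c(20, 20),
                                    decoy_fraction = 0.25, seed = 1)
  expect_lt(nrow(filter_noael_records(withdecoys)), nrow(withdecoys))
  expect_identical(generate_noael_sets(chem, seed = 3),
                   generate_noael_sets(chem, seed = 3))
})

test_that("write_bundle round-trips through the CSV readers", {
  paths <- make_bundle_dir(n = 20, seed = 5)
  chems <- read_chemicals(paths$chemicals)
  expect_identical(nrow(chems), 20L)
  bio <- read_table_csv(paths$bioactivity, c("chem_id", "ac50_uM"))
  expect_true(all(bio$chem_id %in% chems$chem_id))
  truth <- jsonlite::read_json(file.path(paths$dir, "truth.json"))
  expect_identical(length(truth), 20L)
  expect_true(all(vapply(truth, function(x) x$truth_category, character(1))
                  %in% ttc_values()$category))
})
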