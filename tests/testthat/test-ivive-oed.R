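test_that("ac50_percentile applies the shared type-2 convention", {
  expect_identical(ac50_percentile(10), 10)
  expect_identical(ac50_percentile(1:20), 1.5)
  expect_identical(ac50_percentile(c(5, 3, 1)), 1)
  expect_error(ac50_percentile(numeric(0)), "non-empty")
  expect_error(ac50_percentile(c(1, -2)), "positive")
})

test_that("intrinsic clearance scales linearly to the whole liver", {
  phys <- default_physiology(hepatocellularity = 110, liver_mass = 25)
  expect_identical(scale_clint(0, phys), 0)
  expect_equal(scale_clint(10, phys), 1.65)
  expect_equal(scale_clint(20, phys), 2 * scale_clint(10, phys))
  expect_error(scale_clint(-1, phys), ">= 0")
})

test_that("Css has the renal-only closed form and is monotone", {
  phys <- default_physiology(gfr = 0.1)
  expect_equal(css_unit_dose(1, 0, phys), (1 / 24) / 0.1)
  phys2 <- default_physiology(gfr = 0.1, q_liver = 1.45)
  expect_equal(css_unit_dose(0.5, 1, phys2), 0.09878419, tolerance = 1e-6)
  # non-increasing in fup, clint and gfr on a random grid
  withr::with_seed(9, {
    for (rep in 1:50) {
      fup <- stats::runif(1, 0.01, 0.9)
      cl <- stats::runif(1, 0, 5)
      gfr <- stats::runif(1, 0.02, 0.3)
      p <- default_physiology(gfr = gfr)
      base <- css_unit_dose(fup, cl, p)
      expect_lte(css_unit_dose(min(fup * 1.5, 1), cl, p), base)
      expect_lte(css_unit_dose(fup, cl * 1.5, p), base)
      expect_lte(css_unit_dose(fup, cl, default_physiology(gfr = gfr * 1.5)),
                 base)
    }
  })
})

test_that("fractions unbound below the floor are raised with a warning", {
  phys <- default_physiology(fup_floor = 0.005)
  expect_warning(css_unit_dose(0.001, 0, phys), "floor")
  expect_equal(suppressWarnings(css_unit_dose(0.001, 0, phys)),
               css_unit_dose(0.005, 0, phys))
})

test_that("population Css p95 collapses to the closed form at zero CV", {
  phys <- default_physiology(cv_gfr = 0, cv_q_liver = 0,
                             cv_hepatocellularity = 0, cv_liver_mass = 0,
                             cv_fup = 0, cv_clint = 0)
  det <- css_unit_dose(0.3, scale_clint(10, phys), phys)
  mc <- css_population_p95(0.3, 10, phys, n_samples = 200, seed = 4)
  expect_equal(mc, det)
})

test_that("population Css p95 is seeded, reproducible and above the median", {
  phys <- default_physiology()
  a <- css_population_p95(0.2, 5, phys, n_samples = 500, seed = 42)
  b <- css_population_p95(0.2, 5, phys, n_samples = 500, seed = 42)
  expect_identical(a, b)
  med <- css_population_p95(0.2, 5, phys, n_samples = 500, seed = 42, p = 0.5)
  expect_gte(a, med)
  expect_error(css_population_p95(0.2, 5, phys, n_samples = 50), ">= 100")
})

test_that("the Monte Carlo p95 is stable in n_samples", {
  phys <- default_physiology()
  rel <- vapply(1:5, function(s) {
    p1 <- css_population_p95(0.3, 10, phys, n_samples = 10000, seed = s)
    p2 <- css_population_p95(0.3, 10, phys, n_samples = 20000, seed = s + 100)
    abs(p2 - p1) / p1
  }, numeric(1))
  expect_lt(mean(rel), 0.02)
})

test_that("OED conversion is linear and unit-consistent", {
  expect_equal(oed_from_ac50(1, 100, 0.1), 1)
  expect_equal(oed_from_ac50(10, 200, 1), 2)
  expect_equal(oed_from_ac50(1, 100, 0.05), 2)    # halving css doubles OED
  expect_equal(oed_from_ac50(2, 100, 0.1), 2)     # linear in AC50
  # at mw = 1000 g/mol, 1 uM is numerically 1 mg/L
  expect_equal(oed_from_ac50(3.7, 1000, 1), 3.7)
  expect_error(oed_from_ac50(1, 100, 0), "positive")
  expect_error(oed_from_ac50(-1, 100, 1), "positive")
})

test_that("derive_oed joins tables and drops chemicals without PK", {
  bio <- data.frame(chem_id = rep(c("a", "b"), each = 3),
                    ac50_uM = c(1, 2, 3, 4, 5, 6), stringsAsFactors = FALSE)
  pk <- data.frame(chem_id = "a", fup = 0.5, clint = 0,
                   stringsAsFactors = FALSE)
  mw <- data.frame(chem_id = c("a", "b"), mw = c(100, 200),
                   stringsAsFactors = FALSE)
  phys <- default_physiology(cv_gfr = 0, cv_q_liver = 0,
                             cv_hepatocellularity = 0, cv_liver_mass = 0,
                             cv_fup = 0, cv_clint = 0, gfr = 0.1)
  expect_message(
    oed <- derive_oed(bio, pk, mw, phys = phys, n_samples = 100, seed = 1),
    "no OED")
  expect_identical(oed$chem_id, "a")
  # closed form: css = (1/24)/(0.1*0.5); oed = (1 * 100/1000)/css
  expect_equal(oed$ac50_p5_uM, 1)
  expect_equal(oed$oed_mg_kg_d, 0.1 / ((1 / 24) / 0.05))
})
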