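test_that("the four estimands reproduce the ICU cohort values", {
  h <- paper_hazards()
  expect_equal(round(a1(h), 2), 12.31)
  expect_equal(round(a2(h), 2), 2.12)
  expect_equal(round(a3(h), 2), 0.35)
  expect_equal(round(a4(h), 2), 1.77)
})

test_that("estimand behaviour at and across the hazard-ratio knife edge", {
  hr1 <- hazards(0.02, 0.08, 0.08)     # infection does not change discharge
  expect_equal(a2(hr1), 0)
  expect_equal(a4(hr1), 0)
  expect_equal(a3(hr1), 0, tolerance = 1e-14)
  expect_gt(a1(hr1), 0)                 # A1 stays positive: its known defect
  rev <- hazards(0.02, 0.08, 0.12)      # infection speeds discharge
  expect_lt(a2(rev), 0)
  expect_lt(a3(rev), 0)
  expect_lt(a4(rev), 0)
  expect_gt(a1(rev), 0)
})

test_that("a3 vanishes in the no-infection limit and matches its product form", {
  expect_identical(a3(hazards(0, 0.1, 0.08)), 0)
  for (tri in split(random_hazard_triples(50, seed = 11), seq_len(50))) {
    h <- hazards(tri$l01, tri$l02, tri$l12)
    prod_form <- risk_ni(h) * (1 / h$lambda12) *
      (h$lambda02 - h$lambda12) / h$lambda02
    expect_equal(a3(h), prod_form, tolerance = 1e-12)
  }
})

test_that("a4 equals the state-1 sojourn minus the cohort mean LOS", {
  for (tri in split(random_hazard_triples(50, seed = 12), seq_len(50))) {
    h <- hazards(tri$l01, tri$l02, tri$l12)
    expect_equal(a4(h), sojourn_time_state1(h) - mean_los(h),
                 tolerance = 1e-10)
  }
})

test_that("estimands raise domain errors on zero required hazards", {
  expect_error(a1(hazards(0.1, 0.1, 0)), class = "nilos_domain_error")
  expect_error(a2(hazards(0.1, 0, 0.1)), class = "nilos_domain_error")
  expect_error(a3(hazards(0.1, 0.1, 0)), class = "nilos_domain_error")
  expect_error(a4(hazards(0.1, 0, 0.1)), class = "nilos_domain_error")
})

test_that("direction diagnostics tie estimand signs to the hazard ratio", {
  d <- direction_diagnostics(paper_hazards())
  expect_equal(d$hazard_ratio, 0.0812050 / 0.0981062, tolerance = 1e-4)
  expect_true(all(d$signs == 1L))
  expect_true(d$consistent)

  d1 <- direction_diagnostics(hazards(0.02, 0.08, 0.08))
  expect_equal(d1$hazard_ratio, 1)
  expect_true(all(d1$signs == 0L))
  expect_true(d1$consistent)

  d2 <- direction_diagnostics(hazards(0.02, 0.08, 0.12))
  expect_true(all(d2$signs == -1L))
  expect_true(d2$consistent)
})

test_that("relationship table matches the published pairwise comparisons", {
  tab <- relationship_table(paper_hazards())
  expect_equal(nrow(tab), 12)
  get <- function(nm) tab$value[tab$name == nm]
  expect_equal(round(get("A1-A2"), 2), 10.19)
  expect_equal(round(get("A1-A3"), 2), 11.97)
  expect_equal(round(get("A1-A4"), 2), 10.54)
  expect_equal(round(get("A2-A3"), 2), 1.77)
  expect_equal(round(get("A2-A4"), 2), 0.35)
  expect_equal(round(get("A4-A3"), 2), 1.43)
  expect_equal(round(get("A1/A2"), 2), 5.80)
  expect_equal(round(get("A1/A3"), 1), 35.4)
  expect_equal(round(get("A1/A4"), 2), 6.94)
  expect_equal(round(get("A3/A2"), 3), 0.164)
  expect_equal(round(get("A3/A4"), 3), 0.196)
  expect_equal(round(get("A2/A4"), 2), 1.20)
})

test_that("relationship table agrees with closed forms and flags undefined ratios", {
  tab <- relationship_table(paper_hazards())
  expect_equal(tab$value, tab$closed_form, tolerance = 1e-10)
  expect_false(any(tab$undefined))

  # hazard ratio one: the attributable estimands vanish, so ratios with
  # them as denominator are undefined rather than infinite
  knife <- relationship_table(hazards(0.02, 0.08, 0.08))
  getr <- function(nm) knife[knife$name == nm, ]
  for (nm in c("A2-A3", "A2-A4", "A4-A3")) {
    expect_equal(getr(nm)$value, 0, tolerance = 1e-14)
  }
  for (nm in c("A1/A2", "A1/A3", "A1/A4", "A3/A2", "A3/A4", "A2/A4")) {
    den <- sub(".*/", "", nm)
    if (den %in% c("A2", "A3", "A4")) {
      expect_true(getr(nm)$undefined, label = paste(nm, "undefined"))
    }
  }
  expect_error(relationship_table(hazards(0, 0.1, 0.08)),
               class = "nilos_domain_error")
})

test_that("estimand report marks zero-hazard quantities undefined, not NaN", {
  rep0 <- estimand_report(hazards(0.02, 0.1, 0))   # no observed state-1 exits
  expect_true(rep0$undefined[rep0$quantity == "a1"])
  expect_true(rep0$undefined[rep0$quantity == "a2"])
  expect_true(rep0$undefined[rep0$quantity == "a4"])
  expect_false(any(is.nan(rep0$value)))
  # lambda01 = 0 keeps the limit quantities defined
  rep1 <- estimand_report(hazards(0, 0.1, 0.08))
  for (q in c("mean_los", "risk_ni", "odds_ni", "a3")) {
    expect_false(rep1$undefined[rep1$quantity == q], label = q)
  }
  expect_equal(rep1$value[rep1$quantity == "a3"], 0)
})
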