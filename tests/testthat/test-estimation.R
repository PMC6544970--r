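test_that("incidence densities reproduce the published hazard estimates", {
  h <- estimate_hazards(paper_counts())
  expect_equal(round(h$lambda01, 4), 0.0192)
  expect_equal(round(h$lambda02, 4), 0.0981)
  expect_equal(round(h$lambda12, 4), 0.0812)
})

test_that("zero event counts give zero hazards, not errors", {
  h <- estimate_hazards(cohort_counts(10, 0, 10, 0, 80, 0))
  expect_equal(h$lambda01, 0)
  expect_equal(h$lambda12, 0)
  expect_error(estimate_hazards(cohort_counts(0, 0, 0, 0, 0, 0)),
               "positive person-days")
})

test_that("hazard estimation recovers the truth on a simulated cohort", {
  h <- paper_hazards()
  sim <- simulate_cohort(sim_config(h, 1e5, seed = 31))
  cnt <- aggregate_counts(sim)
  est <- estimate_hazards(cnt)
  # Poisson-process standard error: sqrt(events) / person-days
  expect_within_se(est$lambda01, h$lambda01, sqrt(cnt$n01) / cnt$days0)
  expect_within_se(est$lambda02, h$lambda02, sqrt(cnt$n02) / cnt$days0)
  expect_within_se(est$lambda12, h$lambda12, sqrt(cnt$n12) / cnt$days1)
})

test_that("rescaling time rescales hazards and day-valued estimands", {
  sim <- as.data.frame(simulate_cohort(sim_config(paper_hazards(), 300, seed = 8)))
  scaled <- sim
  scaled$entry <- sim$entry * 24     # days to hours
  scaled$exit <- sim$exit * 24
  h <- estimate_hazards(aggregate_counts(sim))
  hs <- estimate_hazards(aggregate_counts(scaled))
  expect_equal(hs$lambda01, h$lambda01 / 24)
  expect_equal(hs$lambda02, h$lambda02 / 24)
  expect_equal(hs$lambda12, h$lambda12 / 24)
  for (f in list(a1, a2, a3, a4, mean_los)) {
    expect_equal(f(hs), 24 * f(h))
  }
})

test_that("fit composes aggregation, estimation and reporting", {
  f <- fit(paper_counts())
  expect_equal(f$input_form, "counts")
  r <- f$report
  expect_equal(round(r$value[r$quantity == "a1"], 2), 12.31)
  expect_equal(round(r$value[r$quantity == "a2"], 2), 2.12)
  expect_equal(round(r$value[r$quantity == "a3"], 2), 0.35)
  expect_equal(round(r$value[r$quantity == "a4"], 2), 1.77)
  expect_s3_class(f$relationships, "ni_relationships")

  sim <- simulate_cohort(sim_config(paper_hazards(), 500, seed = 3))
  f2 <- fit(sim)
  expect_equal(f2$input_form, "records")
  manual <- estimand_report(estimate_hazards(aggregate_counts(sim)))
  expect_equal(f2$report$value, manual$value)
})

test_that("fit on an exact knife-edge cohort gives zero attributable estimands", {
  # counts engineered so that lambda12 = lambda02 = 0.1 exactly
  cnt <- cohort_counts(30, 10, 20, 10, 200, 100)
  f <- fit(cnt)
  r <- f$report
  expect_equal(r$value[r$quantity == "a2"], 0)
  expect_equal(r$value[r$quantity == "a4"], 0)
  expect_equal(r$value[r$quantity == "a3"], 0, tolerance = 1e-14)
})

test_that("delta-method hazard intervals behave like log-scale Wald intervals", {
  ci <- hazard_ci_delta(paper_counts())
  expect_equal(ci$estimate, c(124 / 6442, 632 / 6442, 124 / 1527))
  expect_true(all(ci$lower < ci$estimate & ci$estimate < ci$upper))
  expect_equal(ci$upper[1] / ci$estimate[1], exp(qnorm(0.975) / sqrt(124)))
  none <- hazard_ci_delta(cohort_counts(5, 0, 5, 0, 40, 0))
  expect_true(is.na(none$lower[1]))
})

test_that("bootstrap resamples patients reproducibly", {
  sim <- simulate_cohort(sim_config(paper_hazards(), 200, seed = 17))
  b1 <- bootstrap_ci(sim, B = 50, seed = 99)
  b2 <- bootstrap_ci(sim, B = 50, seed = 99)
  expect_identical(attr(b1, "replicates"), attr(b2, "replicates"))
  expect_equal(b1$a4$lower, b2$a4$lower)
  b3 <- bootstrap_ci(sim, B = 50, seed = 100)
  expect_false(identical(attr(b1, "replicates"), attr(b3, "replicates")))
})

test_that("a single bootstrap replicate gives a degenerate interval", {
  sim <- simulate_cohort(sim_config(paper_hazards(), 120, seed = 40))
  b <- bootstrap_ci(sim, B = 1, seed = 7)
  expect_equal(b$a1$lower, b$a1$upper)
  expect_equal(b$a1$lower, attr(b, "replicates")[1, "a1"][[1]])
})

test_that("undefined bootstrap replicates are counted, not dropped", {
  # tiny cohort with a single infected patient: resamples often miss it
  ev <- event_history(id = c("i", "i", "u1", "u2", "u3"),
                      from = c(0, 1, 0, 0, 0),
                      to = c("1", "2", "2", "2", "2"),
                      entry = c(0, 2, 0, 0, 0),
                      exit = c(2, 9, 3, 4, 6))
  b <- bootstrap_ci(ev, B = 200, seed = 12)
  expect_gt(b$a1$n_undefined, 0)
  expect_equal(b$a1$n_undefined + sum(!is.na(attr(b, "replicates")[, "a1"])),
               200)
  # a3 is defined (limit 0) on replicates without infections
  expect_lt(b$a3$n_undefined, b$a1$n_undefined)
})

test_that("bootstrap from counts alone is refused", {
  expect_error(fit(paper_counts(), bootstrap = 10),
               "require patient-level records")
})
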