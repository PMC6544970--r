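test_that("cohort simulation is seed-reproducible and valid", {
  cfg <- sim_config(paper_hazards(), 500, seed = 42)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(sim_config(paper_hazards(), 500, seed = 43))
  expect_false(identical(s1, s3))
  # output passes the same validation applied to user-supplied files
  expect_silent(validate_event_history(as.data.frame(s1)))
})

test_that("no infections occur when the infection hazard is zero", {
  s <- simulate_cohort(sim_config(hazards(0, 0.1, 0.5), 300, seed = 1))
  expect_false(any(s$from == 1))
  expect_true(all(s$to == "2"))
  hypo <- simulate_hypothetical_world(sim_config(paper_hazards(), 300, seed = 1))
  expect_false(any(hypo$from == 1))
})

test_that("state-0 exit times are exponential with the summed exit rate", {
  h <- paper_hazards()
  s <- simulate_cohort(sim_config(h, 1e5, seed = 202))
  t0 <- s$exit[s$from == 0]
  ks <- suppressWarnings(ks.test(t0, "pexp", rate = h$lambda01 + h$lambda02))
  expect_gt(ks$p.value, 0.01)
})

test_that("infected fraction matches the competing-risks routing probability", {
  h <- paper_hazards()
  s <- simulate_cohort(sim_config(h, 1e5, seed = 7))
  cnt <- aggregate_counts(s)
  phat <- cnt$n01 / cnt$n_patients
  expect_within_se(phat, risk_ni(h),
                   sqrt(phat * (1 - phat) / cnt$n_patients))
})

test_that("the retrospective contrast on printed two-patient data is 3 days", {
  r <- empirical_retrospective_difference(two_patient_history())
  expect_equal(r$difference, 8 - 5)
  expect_equal(r$n_infected, 1)
  expect_equal(r$n_uninfected, 1)
})

test_that("empty strata yield an undefined outcome with a warning", {
  uninf_only <- simulate_cohort(sim_config(hazards(0, 0.1, 0.5), 50, seed = 2))
  expect_warning(r <- empirical_retrospective_difference(uninf_only),
                 "empty stratum")
  expect_true(is.na(r$difference))
  expect_warning(l <- landmark_residual_difference(uninf_only, 5),
                 "empty stratum")
  expect_true(is.na(l$difference))
})

test_that("retrospective contrast stays positive even at hazard ratio one", {
  h <- hazards(0.03, 0.08, 0.08)
  diffs <- vapply(1:20, function(i) {
    s <- simulate_cohort(sim_config(h, 2000, seed = 300 + i))
    empirical_retrospective_difference(s)$difference
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  # and its average sits near 1/lambda12, nowhere near zero
  expect_within_se(mean(diffs), a1(h), sd(diffs) / sqrt(length(diffs)))
})

test_that("landmark residual contrast is near zero at hazard ratio one", {
  h <- hazards(0.03, 0.08, 0.08)
  s <- simulate_cohort(sim_config(h, 5e4, seed = 55))
  lm <- landmark_residual_difference(s, 5)
  expect_within_se(lm$difference, 0, lm$mc_se)
})

test_that("full pipeline closure: simulate, estimate, and recover estimands", {
  h <- paper_hazards()
  s <- simulate_cohort(sim_config(h, 5e4, seed = 77))
  est <- estimate_hazards(aggregate_counts(s))
  # sampling error of each plug-in estimand taken from its bootstrap SD
  b <- bootstrap_ci(s, B = 100, seed = 770)
  reps <- attr(b, "replicates")
  for (q in c("a1", "a2", "a3", "a4", "mean_los")) {
    truth <- switch(q, a1 = a1(h), a2 = a2(h), a3 = a3(h), a4 = a4(h),
                    mean_los = mean_los(h))
    plug_in <- switch(q, a1 = a1(est), a2 = a2(est), a3 = a3(est),
                      a4 = a4(est), mean_los = mean_los(est))
    expect_within_se(plug_in, truth, sd(reps[, q], na.rm = TRUE))
  }
})

test_that("Monte-Carlo oracle suite passes at moderate cohort size", {
  cfg <- sim_config(paper_hazards(), 3e4, seed = 9, landmark_days = c(2, 5, 10))
  v <- validate_estimands_mc(cfg)
  expect_s3_class(v, "ni_validation")
  expect_true(all(v$pass), info = paste(v$check[!v$pass], collapse = "; "))
  # landmarks mutually consistent within MC error (memorylessness)
  lms <- v[grepl("landmark", v$check), ]
  spread <- max(lms$empirical) - min(lms$empirical)
  expect_lt(spread, 6 * max(lms$mc_se))
})
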