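# Shared fixtures: the published ICU cohort's sufficient statistics
# (756 patients, 124 nosocomial infections, 632 direct discharges,
# 6442 person-days uninfected, 1527 infected) and generators for random
# hazard triples and small hand-built event histories.

paper_counts <- function() cohort_counts(756, 124, 632, 124, 6442, 1527)

paper_hazards <- function() hazards(124 / 6442, 632 / 6442, 124 / 1527)

# strictly positive triples spanning slow to fast turnover, including
# both directions of the hazard ratio
random_hazard_triples <- function(n, seed) {
  set.seed(seed)
  data.frame(
    l01 = runif(n, 0.001, 0.3),
    l02 = runif(n, 0.001, 0.3),
    l12 = runif(n, 0.001, 0.3)
  )
}

two_patient_history <- function() {
  event_history(id = c("inf", "inf", "uninf"),
                from = c(0, 1, 0), to = c("1", "2", "2"),
                entry = c(0, 3, 0), exit = c(3, 8, 5))
}

expect_within_se <- function(empirical, truth, se, k = 3) {
  expect_lt(abs(empirical - truth), k * se)
}
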