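#' Simulation configuration for the illness-death cohort sampler
#'
#' @param hazards true transition rates, an [hazards()] object.
#'   \code{lambda01 = 0} is allowed (the hypothetical no-infection
#'   world); the exit rates must make every patient leave eventually.
#' @param n_patients cohort size, at least 1.
#' @param seed integer seed.
#' @param landmark_days optional landmark times (days) for residual-LOS
#'   comparisons; default \code{c(2, 5, 10)}.
#' @return A list of class \code{"ni_simconfig"}.
#' @export
sim_config <- function(hazards, n_patients, seed = 1L,
                       landmark_days = c(2, 5, 10)) {
  h <- as_hazards(hazards)
  if (n_patients < 1) stop("n_patients must be at least 1", call. = FALSE)
  if (h$lambda01 + h$lambda02 <= 0) {
    stop("lambda01 + lambda02 must be > 0: patients must leave state 0",
         call. = FALSE)
  }
  if (h$lambda01 > 0 && h$lambda12 <= 0) {
    stop("lambda12 must be > 0 when infections can occur", call. = FALSE)
  }
  structure(list(hazards = h, n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 landmark_days = as.numeric(landmark_days)),
            class = "ni_simconfig")
}

#' Simulate a cohort from the time-homogeneous illness-death model
#'
#' Draws one path per patient, all admitted at time 0.  The exit time
#' from state 0 is exponential with rate \eqn{\lambda_{01}+\lambda_{02}};
#' the destination is state 1 with probability
#' \eqn{\lambda_{01}/(\lambda_{01}+\lambda_{02})}, else state 2; infected
#' patients then stay an additional exponential sojourn at rate
#' \eqn{\lambda_{12}}.  No censoring is generated.
#'
#' Draws are inverse-transform exponentials (\code{-log(u)/rate}) from
#' R's default generator, in a fixed documented order so fixtures remain
#' stable: first the \code{n} state-0 exit uniforms, then the \code{n}
#' routing uniforms, then one sojourn uniform per infected patient in
#' patient order.  A fixed seed therefore reproduces the cohort exactly.
#'
#' @param config an [sim_config()] object, or an [hazards()] object if
#'   \code{n_patients} is supplied.
#' @param n_patients,seed convenience overrides when \code{config} is a
#'   bare hazards object.
#' @return A validated event history (\code{"ni_events"}) with patients
#'   \code{"p1" ... "pn"}.
#' @examples
#' h <- hazards(0.02, 0.1, 0.08)
#' sim <- simulate_cohort(sim_config(h, n_patients = 100, seed = 42))
#' aggregate_counts(sim)
#' @export
simulate_cohort <- function(config, n_patients = NULL, seed = 1L) {
  if (!inherits(config, "ni_simconfig")) {
    if (is.null(n_patients)) {
      stop("supply an sim_config() or hazards plus n_patients", call. = FALSE)
    }
    config <- sim_config(config, n_patients, seed)
  }
  h <- config$hazards
  n <- config$n_patients
  rate0 <- h$lambda01 + h$lambda02
  p_inf <- h$lambda01 / rate0
  set.seed(config$seed)
  u_exit <- stats::runif(n)
  u_route <- stats::runif(n)
  t0 <- -log(u_exit) / rate0
  infected <- u_route < p_inf
  n_inf <- sum(infected)
  t1 <- numeric(0)
  if (n_inf > 0) {
    u_soj <- stats::runif(n_inf)
    t1 <- -log(u_soj) / h$lambda12
  }
  ids <- paste0("p", seq_len(n))
  rec_id <- c(ids, ids[infected])
  rec_from <- c(rep(0L, n), rep(1L, n_inf))
  rec_to <- c(ifelse(infected, "1", "2"), rep("2", n_inf))
  rec_entry <- c(rep(0, n), t0[infected])
  rec_exit <- c(t0, t0[infected] + t1)
  ord <- order(match(rec_id, ids), rec_entry)
  out <- data.frame(id = rec_id[ord], from = rec_from[ord], to = rec_to[ord],
                    entry = rec_entry[ord], exit = rec_exit[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ni_events", class(out))
  out
}

#' Simulate the hypothetical world without nosocomial infections
#'
#' Identical to [simulate_cohort()] but with the infection hazard forced
#' to zero: every patient follows the direct 0 to 2 path at rate
#' \eqn{\lambda_{02}}.  Mean LOS in this world is \eqn{1/\lambda_{02}}.
#'
#' @inheritParams simulate_cohort
#' @return An event history with no state-1 rows.
#' @export
simulate_hypothetical_world <- function(config, n_patients = NULL, seed = 1L) {
  if (!inherits(config, "ni_simconfig")) {
    if (is.null(n_patients)) {
      stop("supply an sim_config() or hazards plus n_patients", call. = FALSE)
    }
    config <- sim_config(config, n_patients, seed)
  }
  h0 <- hazards(0, config$hazards$lambda02,
                max(config$hazards$lambda12, 1))  # lambda12 unused: no infections
  cfg <- sim_config(h0, config$n_patients, config$seed,
                    config$landmark_days)
  simulate_cohort(cfg)
}

## Per-patient total LOS and infection indicator, from an event history.
patient_los <- function(records) {
  if (!inherits(records, "ni_events")) records <- validate_event_history(records)
  ids <- unique(records$id)
  f <- factor(records$id, levels = ids)
  total <- tapply(records$exit, f, max) - tapply(records$entry, f, min)
  infected <- tapply(records$from == 0L & records$to == "1", f, any)
  data.frame(id = ids, los = as.numeric(total),
             infected = as.logical(infected),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Empirical retrospective LOS difference (Monte-Carlo A1)
#'
#' Mean total LOS of eventually infected patients minus that of
#' eventually uninfected patients, the naive retrospective contrast whose
#' model expectation is \eqn{1/\lambda_{12}}.
#'
#' @param records an event history.
#' @return A list: \code{difference} (days), stratum means, sizes, and
#'   \code{mc_se} (standard error of the difference).  \code{difference}
#'   is \code{NA} with a warning if either stratum is empty.
#' @export
empirical_retrospective_difference <- function(records) {
  pl <- patient_los(records)
  inf <- pl$los[pl$infected]
  uninf <- pl$los[!pl$infected]
  if (length(inf) == 0L || length(uninf) == 0L) {
    warning("empty stratum: need at least one infected and one uninfected patient")
    return(list(difference = NA_real_, mean_infected = NA_real_,
                mean_uninfected = NA_real_, n_infected = length(inf),
                n_uninfected = length(uninf), mc_se = NA_real_))
  }
  se <- sqrt(stats::var(inf) / length(inf) + stats::var(uninf) / length(uninf))
  list(difference = mean(inf) - mean(uninf),
       mean_infected = mean(inf), mean_uninfected = mean(uninf),
       n_infected = length(inf), n_uninfected = length(uninf),
       mc_se = se)
}

#' Landmark residual-LOS difference (Monte-Carlo A4)
#'
#' Conditions on the state occupied at landmark day \code{s}: patients
#' still in state 0 at \code{s} versus patients in state 1 at \code{s},
#' and compares their mean remaining LOS (final exit minus \code{s}).
#' Under time homogeneity the expectation equals A4 at every landmark
#' (memorylessness), so estimates at different \code{s} agree up to
#' Monte-Carlo error.
#'
#' @param records an event history.
#' @param s landmark time in days.
#' @return A list: \code{difference} (days), stratum means and sizes,
#'   \code{landmark}, \code{mc_se}; \code{difference} is \code{NA} with a
#'   warning if a stratum is empty at \code{s}.
#' @export
landmark_residual_difference <- function(records, s) {
  if (!inherits(records, "ni_events")) records <- validate_event_history(records)
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0)
  ids <- unique(records$id)
  f <- factor(records$id, levels = ids)
  final_exit <- as.numeric(tapply(records$exit, f, max))
  inf_rows <- records$from == 0L & records$to == "1"
  inf_time <- rep(Inf, length(ids))
  inf_time[match(records$id[inf_rows], ids)] <- records$exit[inf_rows]
  # state 0 at s: neither infected nor discharged by s
  in_state0 <- (inf_time > s) & (final_exit > s)
  in_state1 <- (inf_time <= s) & (final_exit > s)
  res0 <- final_exit[in_state0] - s
  res1 <- final_exit[in_state1] - s
  if (length(res0) == 0L || length(res1) == 0L) {
    warning(sprintf("empty stratum at landmark s = %g", s))
    return(list(difference = NA_real_, mean_state1 = NA_real_,
                mean_state0 = NA_real_, n_state1 = length(res1),
                n_state0 = length(res0), landmark = s, mc_se = NA_real_))
  }
  se <- sqrt(stats::var(res1) / length(res1) + stats::var(res0) / length(res0))
  list(difference = mean(res1) - mean(res0),
       mean_state1 = mean(res1), mean_state0 = mean(res0),
       n_state1 = length(res1), n_state0 = length(res0),
       landmark = s, mc_se = se)
}

#' Monte-Carlo validation of the closed-form estimands
#'
#' Runs the four empirical oracles on simulated cohorts at the given
#' hazards and compares each with its closed form: the retrospective
#' stratified difference against A1, the difference of mean state-1
#' sojourn and hypothetical-world LOS against A2, the real-versus-
#' hypothetical two-world mean-LOS difference against A3, and the
#' landmark residual difference (at each configured landmark) against
#' A4; plus the infected fraction against risk(NI).  Each comparison
#' passes when \eqn{|\mathrm{empirical} - \mathrm{closed\ form}|} is
#' within \code{k_se} Monte-Carlo standard errors.
#'
#' @param config an [sim_config()].
#' @param k_se tolerance multiplier in MC standard errors, default 3.
#' @return A data frame of class \code{"ni_validation"}: one row per
#'   check with \code{check}, \code{empirical}, \code{closed_form},
#'   \code{mc_se}, \code{pass}.
#' @export
validate_estimands_mc <- function(config, k_se = 3) {
  stopifnot(inherits(config, "ni_simconfig"))
  h <- config$hazards
  real <- simulate_cohort(config)
  hypo_cfg <- sim_config(h, config$n_patients, config$seed + 1L,
                         config$landmark_days)
  hypo <- simulate_hypothetical_world(hypo_cfg)

  rows <- list()
  add <- function(check, empirical, closed, se) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, empirical = empirical, closed_form = closed,
      mc_se = se, pass = is.finite(empirical) &&
        abs(empirical - closed) <= k_se * se,
      stringsAsFactors = FALSE)
  }

  pl <- patient_los(real)
  # risk(NI): binomial MC error
  phat <- mean(pl$infected)
  add("risk_ni (infected fraction)", phat, risk_ni(h),
      sqrt(phat * (1 - phat) / nrow(pl)))

  r1 <- empirical_retrospective_difference(real)
  add("a1 (retrospective stratification)", r1$difference, a1(h), r1$mc_se)

  # A2: mean state-1 sojourn minus hypothetical-world mean LOS
  s1_rows <- real[real$from == 1L, , drop = FALSE]
  soj1 <- s1_rows$exit - s1_rows$entry
  hypo_los <- patient_los(hypo)$los
  se_a2 <- sqrt(stats::var(soj1) / length(soj1) +
                stats::var(hypo_los) / length(hypo_los))
  add("a2 (sojourn vs hypothetical world)",
      mean(soj1) - mean(hypo_los), a2(h), se_a2)

  # A3: two-world mean-LOS difference
  se_a3 <- sqrt(stats::var(pl$los) / nrow(pl) +
                stats::var(hypo_los) / length(hypo_los))
  add("a3 (two-world comparison)", mean(pl$los) - mean(hypo_los), a3(h), se_a3)

  for (s in config$landmark_days) {
    lm <- landmark_residual_difference(real, s)
    add(sprintf("a4 (landmark s = %g)", s), lm$difference, a4(h), lm$mc_se)
  }

  out <- do.call(rbind, rows)
  class(out) <- c("ni_validation", "data.frame")
  out
}
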