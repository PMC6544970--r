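#' Constant transition hazards of the illness-death model
#'
#' Bundle of the three daily transition rates of the time-homogeneous
#' three-state model for hospital stay: state 0 (admitted, uninfected),
#' state 1 (nosocomial infection, NI), state 2 (discharge or death,
#' combined endpoint).  \code{lambda01} is the infection hazard (incidence
#' density of NI), \code{lambda02} the discharge/death hazard while
#' uninfected, \code{lambda12} the discharge/death hazard after infection.
#' All rates are per day.
#'
#' Rates must be finite and non-negative; most estimands additionally
#' require strict positivity and signal a domain error otherwise.  A zero
#' infection hazard (\code{lambda01 = 0}) is a meaningful limit -- the
#' hypothetical world in which NI has been eliminated -- and is accepted
#' by [mean_los()], [risk_ni()], [odds_ni()] and [a3()].
#'
#' @param lambda01 infection hazard, state 0 to 1 (per day).
#' @param lambda02 discharge/death hazard while uninfected, state 0 to 2
#'   (per day).
#' @param lambda12 discharge/death hazard after infection, state 1 to 2
#'   (per day).
#' @return An object of class \code{"ni_hazards"}: a named list with the
#'   three rates.
#' @examples
#' h <- hazards(124 / 6442, 632 / 6442, 124 / 1527)
#' mean_los(h)
#' @export
hazards <- function(lambda01, lambda02, lambda12) {
  rates <- c(lambda01 = lambda01, lambda02 = lambda02, lambda12 = lambda12)
  if (length(rates) != 3L || !is.numeric(rates)) {
    stop("hazards() expects three numeric scalars", call. = FALSE)
  }
  if (any(!is.finite(rates))) {
    stop("all hazard rates must be finite", call. = FALSE)
  }
  if (any(rates < 0)) {
    stop("hazard rates must be non-negative", call. = FALSE)
  }
  structure(as.list(rates), class = "ni_hazards")
}

#' @export
print.ni_hazards <- function(x, digits = 4, ...) {
  cat("Constant transition hazards (per day)\n")
  cat(sprintf("  lambda01 (0 -> 1, infection):        %.*f\n", digits, x$lambda01))
  cat(sprintf("  lambda02 (0 -> 2, discharge/death):  %.*f\n", digits, x$lambda02))
  cat(sprintf("  lambda12 (1 -> 2, discharge/death):  %.*f\n", digits, x$lambda12))
  invisible(x)
}

as_hazards <- function(h) {
  if (inherits(h, "ni_hazards")) return(h)
  if (is.numeric(h) && length(h) == 3L) {
    return(hazards(h[[1L]], h[[2L]], h[[3L]]))
  }
  stop("expected an 'ni_hazards' object or a numeric vector of length 3",
       call. = FALSE)
}

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("nilos_domain_error", "error")))
}

#' Mean sojourn time in the admission state
#'
#' Time spent in state 0 before either infection or discharge/death.  The
#' waiting time in state 0 is exponential with rate
#' \eqn{\lambda_{01}+\lambda_{02}}, so the mean sojourn is
#' \eqn{1/(\lambda_{01}+\lambda_{02})}.
#'
#' @param h an [hazards()] object.
#' @return Mean sojourn time in state 0, in days.
#' @export
sojourn_time_state0 <- function(h) {
  h <- as_hazards(h)
  rate <- h$lambda01 + h$lambda02
  if (rate <= 0) stop_domain("sojourn_time_state0: lambda01 + lambda02 must be > 0")
  1 / rate
}

#' Mean sojourn time in the infected state
#'
#' Post-infection stay is exponential with rate \eqn{\lambda_{12}}; its
#' mean is \eqn{1/\lambda_{12}}.
#'
#' @inheritParams sojourn_time_state0
#' @return Mean sojourn time in state 1, in days.
#' @export
sojourn_time_state1 <- function(h) {
  h <- as_hazards(h)
  if (h$lambda12 <= 0) stop_domain("sojourn_time_state1: lambda12 must be > 0")
  1 / h$lambda12
}

#' Probability of acquiring a nosocomial infection
#'
#' Competing-risks routing probability out of state 0:
#' \eqn{\lambda_{01}/(\lambda_{01}+\lambda_{02})}.  Zero when the
#' infection hazard is zero.
#'
#' @inheritParams sojourn_time_state0
#' @return Probability in \eqn{[0, 1)}.
#' @export
risk_ni <- function(h) {
  h <- as_hazards(h)
  if (h$lambda02 <= 0) stop_domain("risk_ni: lambda02 must be > 0")
  h$lambda01 / (h$lambda01 + h$lambda02)
}

#' Odds of acquiring a nosocomial infection
#'
#' \eqn{\lambda_{01}/\lambda_{02}}, i.e. \code{risk_ni / (1 - risk_ni)}.
#'
#' @inheritParams sojourn_time_state0
#' @return Odds (dimensionless, non-negative).
#' @export
odds_ni <- function(h) {
  h <- as_hazards(h)
  if (h$lambda02 <= 0) stop_domain("odds_ni: lambda02 must be > 0")
  h$lambda01 / h$lambda02
}

#' Discharge-hazard ratio of infected versus uninfected patients
#'
#' \eqn{\lambda_{12}/\lambda_{02}}.  Values below one mean infection slows
#' discharge (prolongs stay); one means no effect.  Only this orientation
#' is exposed; no reciprocal convention is offered.
#'
#' @inheritParams sojourn_time_state0
#' @return Hazard ratio (dimensionless).
#' @export
hazard_ratio <- function(h) {
  h <- as_hazards(h)
  if (h$lambda02 <= 0) stop_domain("hazard_ratio: lambda02 must be > 0")
  if (h$lambda12 <= 0) stop_domain("hazard_ratio: lambda12 must be > 0")
  h$lambda12 / h$lambda02
}

#' Mean length of stay of the cohort
#'
#' Decomposition of the average total length of stay (LOS) under the
#' illness-death model: the mean sojourn in state 0 plus the probability
#' of infection times the mean sojourn in state 1,
#' \deqn{\overline{LOS} = \frac{1}{\lambda_{01}+\lambda_{02}}
#'   + \frac{\lambda_{01}}{\lambda_{01}+\lambda_{02}}
#'     \times \frac{1}{\lambda_{12}}.}
#' Whenever \eqn{\lambda_{12} < \lambda_{02}} and \eqn{\lambda_{01} > 0}
#' the mean LOS lies strictly between \eqn{1/\lambda_{02}} (the
#' hypothetical no-infection world) and \eqn{1/\lambda_{12}}.
#'
#' @inheritParams sojourn_time_state0
#' @return Mean LOS in days.
#' @export
mean_los <- function(h) {
  h <- as_hazards(h)
  if (h$lambda02 <= 0) stop_domain("mean_los: lambda02 must be > 0")
  if (h$lambda01 > 0 && h$lambda12 <= 0) {
    stop_domain("mean_los: lambda12 must be > 0 when lambda01 > 0")
  }
  s0 <- sojourn_time_state0(h)
  if (h$lambda01 == 0) return(s0)
  s0 + risk_ni(h) * sojourn_time_state1(h)
}

#' Mean length of stay in the hypothetical world without infections
#'
#' With the infection hazard removed (\eqn{\lambda_{01} = 0}) every
#' patient leaves state 0 at rate \eqn{\lambda_{02}}, so the mean LOS is
#' \eqn{1/\lambda_{02}}.  This is a counterfactual, not an observable
#' stratum mean.
#'
#' @inheritParams sojourn_time_state0
#' @return Mean LOS in days in the no-infection world.
#' @export
los_no_ni <- function(h) {
  h <- as_hazards(h)
  if (h$lambda02 <= 0) stop_domain("los_no_ni: lambda02 must be > 0")
  1 / h$lambda02
}
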