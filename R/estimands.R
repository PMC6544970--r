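#' Retrospective length-of-stay difference (estimand A1)
#'
#' Difference between the mean total LOS of eventually infected patients
#' and that of eventually uninfected patients, with the strata formed
#' retrospectively at the end of stay.  Under the time-homogeneous model
#' both strata share the state-0 sojourn, so
#' \deqn{A_1 = \frac{1}{\lambda_{12}}.}
#' A1 is always strictly positive -- even when the hazard ratio
#' \eqn{\lambda_{12}/\lambda_{02}} equals or exceeds one -- because it
#' counts the pre-infection stay of infected patients as if it were
#' attributable to infection.  This time-dependent (immortal-time) bias
#' is the reason the retrospective comparison is discouraged.
#'
#' @inheritParams sojourn_time_state0
#' @return A1 in days.
#' @export
a1 <- function(h) {
  h <- as_hazards(h)
  if (h$lambda12 <= 0) stop_domain("a1: lambda12 must be > 0")
  1 / h$lambda12
}

#' Attributable length of stay (estimand A2)
#'
#' Mean post-infection sojourn minus the mean LOS of the hypothetical
#' no-infection world:
#' \deqn{A_2 = \frac{1}{\lambda_{12}} - \frac{1}{\lambda_{02}}.}
#' Its sign matches the sign of \eqn{\lambda_{02}-\lambda_{12}}: zero at
#' hazard ratio one, positive when infection slows discharge.
#'
#' @inheritParams sojourn_time_state0
#' @return A2 in days (may be negative).
#' @export
a2 <- function(h) {
  h <- as_hazards(h)
  if (h$lambda12 <= 0) stop_domain("a2: lambda12 must be > 0")
  if (h$lambda02 <= 0) stop_domain("a2: lambda02 must be > 0")
  1 / h$lambda12 - 1 / h$lambda02
}

#' Population-attributable length of stay (estimand A3)
#'
#' Mean LOS of the real-world population minus the mean LOS of a
#' hypothetical population in which all infections are eliminated:
#' \deqn{A_3 = \overline{LOS} - \frac{1}{\lambda_{02}}
#'  = \frac{\lambda_{01}}{\lambda_{01}+\lambda_{02}}
#'    \times \frac{1}{\lambda_{12}}
#'    \times \frac{\lambda_{02}-\lambda_{12}}{\lambda_{02}}.}
#' A population-level measure: it dilutes the per-patient excess by the
#' infection risk.  Tends to 0 as \eqn{\lambda_{01} \to 0}; the limit
#' \eqn{\lambda_{01} = 0} is permitted and returns exactly 0.
#'
#' @inheritParams sojourn_time_state0
#' @return A3 in days (may be negative).
#' @export
a3 <- function(h) {
  h <- as_hazards(h)
  if (h$lambda02 <= 0) stop_domain("a3: lambda02 must be > 0")
  if (h$lambda01 == 0) return(0)
  if (h$lambda12 <= 0) stop_domain("a3: lambda12 must be > 0")
  mean_los(h) - 1 / h$lambda02
}

#' Change in residual length of stay (estimand A4)
#'
#' Difference in mean residual LOS between currently infected and
#' currently uninfected patients, conditioning (landmarking) on the state
#' occupied at a given day in hospital.  Under time homogeneity the
#' difference is the same at every landmark and equals
#' \deqn{A_4 = \left(\frac{\lambda_{02}}{\lambda_{12}} - 1\right)
#'   \times \frac{1}{\lambda_{01}+\lambda_{02}},}
#' which is also the state-1 sojourn minus the cohort mean LOS.  This is
#' the established multistate ("change in LOS") estimand, a difference
#' per infected patient.
#'
#' @inheritParams sojourn_time_state0
#' @return A4 in days (may be negative).
#' @export
a4 <- function(h) {
  h <- as_hazards(h)
  if (h$lambda12 <= 0) stop_domain("a4: lambda12 must be > 0")
  if (h$lambda01 + h$lambda02 <= 0) {
    stop_domain("a4: lambda01 + lambda02 must be > 0")
  }
  if (h$lambda02 <= 0) stop_domain("a4: lambda02 must be > 0")
  (h$lambda02 / h$lambda12 - 1) / (h$lambda01 + h$lambda02)
}

#' Sign diagnostics for the hazard ratio and the estimands
#'
#' The direction of the effect of infection on discharge is carried by
#' the hazard ratio \eqn{\lambda_{12}/\lambda_{02}}: A2, A3 and A4 are
#' all positive iff it is below one, all zero iff it equals one, and all
#' negative iff it exceeds one, whereas A1 is positive regardless.  This
#' helper evaluates the four estimands, reports their signs, and flags
#' whether the sign equivalence holds (it must, for every valid input).
#'
#' @inheritParams sojourn_time_state0
#' @return A list of class \code{"ni_direction"} with elements
#'   \code{hazard_ratio}, \code{signs} (named integer vector for A2, A3,
#'   A4), \code{a1_positive} and \code{consistent}.
#' @export
direction_diagnostics <- function(h) {
  h <- as_hazards(h)
  hr <- hazard_ratio(h)
  vals <- c(a2 = a2(h), a3 = a3(h), a4 = a4(h))
  ref <- sign(h$lambda02 - h$lambda12)
  signs <- vapply(vals, function(v) {
    # rounding noise around the HR = 1 knife edge must not flip a sign
    if (abs(v) < 1e-12 * max(1, abs(1 / h$lambda12))) 0L else as.integer(sign(v))
  }, integer(1))
  structure(list(
    hazard_ratio = hr,
    estimands = vals,
    signs = signs,
    a1_positive = a1(h) > 0,
    consistent = all(signs == ref) && a1(h) > 0
  ), class = "ni_direction")
}

#' @export
print.ni_direction <- function(x, ...) {
  cat(sprintf("Hazard ratio lambda12/lambda02 = %.4f\n", x$hazard_ratio))
  dir <- c("-1" = "negative", "0" = "zero", "1" = "positive")
  for (nm in names(x$signs)) {
    cat(sprintf("  %s: %8.4f (%s)\n", toupper(nm), x$estimands[[nm]],
                dir[[as.character(x$signs[[nm]])]]))
  }
  cat(sprintf("  A1 > 0: %s; sign equivalence holds: %s\n",
              x$a1_positive, x$consistent))
  invisible(x)
}

## Closed forms of the twelve pairwise relationships, in terms of the
## hazards alone.  Each returns NA_real_ when the expression's own
## denominator vanishes.
relationship_closed_forms <- function(h) {
  l01 <- h$lambda01; l02 <- h$lambda02; l12 <- h$lambda12
  list(
    "A1-A2" = 1 / l02,
    "A1-A3" = (1 / l02) * (l02^2 + l12 * l01) / (l12 * l02 + l12 * l01),
    "A1-A4" = (1 / l12) * (l01 + l12) / (l01 + l02),
    "A2-A3" = (l02 - l12) / (l12 * (l01 + l02)),
    "A2-A4" = (l01 / l02) * (l02 - l12) / (l12 * (l01 + l02)),
    "A4-A3" = ((l02 - l01) / l02) * (l02 - l12) / (l12 * (l01 + l02)),
    "A1/A2" = if (l02 == l12) NA_real_ else l02 / (l02 - l12),
    "A1/A3" = if (l01 == 0 || l02 == l12) NA_real_ else
      l02 * (l01 + l02) / (l01 * (l02 - l12)),
    "A1/A4" = if (l02 == l12) NA_real_ else (l01 + l02) / (l02 - l12),
    "A3/A2" = l01 / (l01 + l02),
    "A3/A4" = l01 / l02,
    "A2/A4" = (l01 + l02) / l02
  )
}

#' Additive and multiplicative relationships between the four estimands
#'
#' Tabulates all six pairwise differences (A1-A2, A1-A3, A1-A4, A2-A3,
#' A2-A4, A4-A3) and all six ratios (A1/A2, A1/A3, A1/A4, A3/A2, A3/A4,
#' A2/A4), each computed two independent ways: directly from the
#' estimand values and from its closed form in the hazards.  Several
#' entries have familiar interpretations: A1-A2 is the hypothetical-world
#' mean LOS \eqn{1/\lambda_{02}}, A1-A4 is the cohort mean LOS, A2-A3
#' equals A4, A2-A4 equals A3, A3/A2 is the infection risk, A3/A4 the
#' infection odds, and A2/A4 their quotient.  The identity
#' \eqn{A_3 + A_4 = A_2} ties the rows together.
#'
#' Ratio entries whose denominator estimand is zero (e.g. at hazard ratio
#' one) are reported as undefined rather than infinite.
#'
#' @inheritParams sojourn_time_state0
#' @return A data frame of class \code{"ni_relationships"} with columns
#'   \code{name}, \code{type} (\code{"difference"} or \code{"ratio"}),
#'   \code{value} (from the estimands), \code{closed_form} (from the
#'   hazards), \code{undefined} (logical) and \code{label}.
#' @export
relationship_table <- function(h) {
  h <- as_hazards(h)
  if (h$lambda01 <= 0 || h$lambda02 <= 0 || h$lambda12 <= 0) {
    stop_domain("relationship_table: all three hazards must be > 0")
  }
  A <- c(A1 = a1(h), A2 = a2(h), A3 = a3(h), A4 = a4(h))
  direct <- c(
    "A1-A2" = A[["A1"]] - A[["A2"]],
    "A1-A3" = A[["A1"]] - A[["A3"]],
    "A1-A4" = A[["A1"]] - A[["A4"]],
    "A2-A3" = A[["A2"]] - A[["A3"]],
    "A2-A4" = A[["A2"]] - A[["A4"]],
    "A4-A3" = A[["A4"]] - A[["A3"]],
    "A1/A2" = if (A[["A2"]] == 0) NA_real_ else A[["A1"]] / A[["A2"]],
    "A1/A3" = if (A[["A3"]] == 0) NA_real_ else A[["A1"]] / A[["A3"]],
    "A1/A4" = if (A[["A4"]] == 0) NA_real_ else A[["A1"]] / A[["A4"]],
    "A3/A2" = if (A[["A2"]] == 0) NA_real_ else A[["A3"]] / A[["A2"]],
    "A3/A4" = if (A[["A4"]] == 0) NA_real_ else A[["A3"]] / A[["A4"]],
    "A2/A4" = if (A[["A4"]] == 0) NA_real_ else A[["A2"]] / A[["A4"]]
  )
  closed <- relationship_closed_forms(h)
  labels <- c(
    "A1-A2" = "hypothetical-world mean LOS, 1/lambda02",
    "A1-A3" = "retrospective minus population-attributable",
    "A1-A4" = "cohort mean LOS",
    "A2-A3" = "equals A4",
    "A2-A4" = "equals A3",
    "A4-A3" = "individual minus population attributable",
    "A1/A2" = "lambda02 / (lambda02 - lambda12)",
    "A1/A3" = "lambda02 (lambda01 + lambda02) / (lambda01 (lambda02 - lambda12))",
    "A1/A4" = "(lambda01 + lambda02) / (lambda02 - lambda12)",
    "A3/A2" = "risk(NI)",
    "A3/A4" = "odds(NI)",
    "A2/A4" = "odds(NI) / risk(NI)"
  )
  nms <- names(direct)
  out <- data.frame(
    name = nms,
    type = ifelse(grepl("/", nms, fixed = TRUE), "ratio", "difference"),
    value = unname(direct[nms]),
    closed_form = unname(unlist(closed)[nms]),
    undefined = is.na(unname(direct[nms])),
    label = unname(labels[nms]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ni_relationships", "data.frame")
  out
}

#' Full estimand report from hazards
#'
#' Evaluates the four estimands and all derived quantities (sojourn
#' times, cohort mean LOS, hypothetical-world LOS, infection risk and
#' odds, hazard ratio) for a set of hazards.  Quantities whose required
#' hazards are zero are reported as undefined (\code{NA} value with
#' \code{undefined = TRUE}) instead of erroring, so that estimates from
#' cohorts with empty transition counts still produce a report.
#'
#' @inheritParams sojourn_time_state0
#' @param ci optional named list of confidence intervals as produced by
#'   [bootstrap_ci()]; merged into the report.
#' @return A data frame of class \code{"ni_report"} with one row per
#'   quantity: \code{quantity}, \code{value}, \code{units},
#'   \code{undefined}, and (when \code{ci} is given) \code{lower},
#'   \code{upper}, \code{level}.
#' @export
estimand_report <- function(h, ci = NULL) {
  h <- as_hazards(h)
  eval_q <- function(f) {
    tryCatch(f(h), nilos_domain_error = function(e) NA_real_)
  }
  quantities <- list(
    a1 = a1, a2 = a2, a3 = a3, a4 = a4,
    mean_los = mean_los,
    sojourn0 = sojourn_time_state0,
    sojourn1 = sojourn_time_state1,
    los_no_ni = los_no_ni,
    risk_ni = risk_ni,
    odds_ni = odds_ni,
    hazard_ratio = hazard_ratio
  )
  vals <- vapply(quantities, eval_q, numeric(1))
  units <- c(a1 = "days", a2 = "days", a3 = "days", a4 = "days",
             mean_los = "days", sojourn0 = "days", sojourn1 = "days",
             los_no_ni = "days", risk_ni = "probability",
             odds_ni = "dimensionless", hazard_ratio = "dimensionless")
  out <- data.frame(
    quantity = names(vals),
    value = unname(vals),
    units = unname(units[names(vals)]),
    undefined = is.na(unname(vals)),
    stringsAsFactors = FALSE
  )
  if (!is.null(ci)) {
    out$lower <- NA_real_
    out$upper <- NA_real_
    out$level <- NA_real_
    for (nm in intersect(names(ci), out$quantity)) {
      i <- match(nm, out$quantity)
      out$lower[i] <- ci[[nm]]$lower
      out$upper[i] <- ci[[nm]]$upper
      out$level[i] <- ci[[nm]]$level
    }
  }
  attr(out, "hazards") <- h
  class(out) <- c("ni_report", "data.frame")
  out
}

#' @export
print.ni_report <- function(x, ...) {
  cat("Length-of-stay estimand report\n")
  h <- attr(x, "hazards")
  if (!is.null(h)) {
    cat(sprintf("  hazards: lambda01 = %.4f, lambda02 = %.4f, lambda12 = %.4f\n",
                h$lambda01, h$lambda02, h$lambda12))
  }
  days <- x$units == "days"
  shown <- x
  shown$rounded <- ifelse(days, round(x$value, 2), round(x$value, 4))
  has_ci <- "lower" %in% names(x) && any(!is.na(x$lower))
  for (i in seq_len(nrow(shown))) {
    line <- sprintf("  %-12s %12.6f  (%s %s)", shown$quantity[i],
                    shown$value[i], format(shown$rounded[i]), shown$units[i])
    if (shown$undefined[i]) line <- sprintf("  %-12s    undefined", shown$quantity[i])
    if (has_ci && !is.na(x$lower[i])) {
      line <- paste0(line, sprintf("  [%.4f, %.4f] @%.0f%%",
                                   x$lower[i], x$upper[i], 100 * x$level[i]))
    }
    cat(line, "\n")
  }
  invisible(x)
}
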