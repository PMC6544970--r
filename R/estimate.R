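#' Maximum-likelihood hazard estimates (incidence densities)
#'
#' Under constant hazards the maximum-likelihood estimator of each rate
#' is the classical incidence density: events divided by person-days at
#' risk in the origin state,
#' \deqn{\hat\lambda_{01} = n_{01}/d_0,\quad
#'       \hat\lambda_{02} = n_{02}/d_0,\quad
#'       \hat\lambda_{12} = n_{12}/d_1.}
#' Zero event counts yield zero hazard estimates; downstream estimands
#' that require the missing rate are then reported as undefined.
#'
#' @param counts an [cohort_counts()] object (or an event history, which
#'   is aggregated first).
#' @return An [hazards()] object.
#' @examples
#' estimate_hazards(cohort_counts(756, 124, 632, 124, 6442, 1527))
#' @export
estimate_hazards <- function(counts) {
  if (inherits(counts, "ni_events") ||
      (is.data.frame(counts) && all(c("id", "from", "to") %in% names(counts)))) {
    counts <- aggregate_counts(counts)
  }
  if (!inherits(counts, "ni_counts")) {
    stop("estimate_hazards() expects 'ni_counts' or an event history",
         call. = FALSE)
  }
  if (counts$days0 <= 0) {
    stop("estimation requires positive person-days in state 0", call. = FALSE)
  }
  if (counts$n12 > 0 && counts$days1 <= 0) {
    stop("lambda12 requested with zero person-days in state 1", call. = FALSE)
  }
  l12 <- if (counts$days1 > 0) counts$n12 / counts$days1 else 0
  hazards(counts$n01 / counts$days0, counts$n02 / counts$days0, l12)
}

#' Delta-method confidence intervals for the hazards
#'
#' Wald intervals on the log scale: with \eqn{d} events the standard
#' error of \eqn{\log\hat\lambda} is \eqn{1/\sqrt{d}}, giving
#' \eqn{\hat\lambda \exp(\pm z_{1-\alpha/2}/\sqrt{d})}.  A cheap
#' large-sample alternative to the bootstrap, available for the hazards
#' only; intervals for the estimands (ratios of dependent estimates) are
#' bootstrap-only.
#'
#' @param counts an [cohort_counts()] object.
#' @param level confidence level, default 0.95.
#' @return A data frame with one row per hazard: estimate, lower, upper,
#'   events, person-days.  Rows with zero events have \code{NA} limits.
#' @export
hazard_ci_delta <- function(counts, level = 0.95) {
  if (!inherits(counts, "ni_counts")) {
    stop("hazard_ci_delta() expects 'ni_counts'", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  events <- c(lambda01 = counts$n01, lambda02 = counts$n02, lambda12 = counts$n12)
  atrisk <- c(counts$days0, counts$days0, counts$days1)
  est <- ifelse(atrisk > 0, events / atrisk, NA_real_)
  half <- ifelse(events > 0, z / sqrt(events), NA_real_)
  data.frame(
    hazard = names(events),
    estimate = unname(est),
    lower = unname(est * exp(-half)),
    upper = unname(est * exp(half)),
    events = unname(events),
    person_days = atrisk,
    level = level,
    stringsAsFactors = FALSE
  )
}

## Per-patient sufficient-statistic contributions; the unit of
## resampling for the bootstrap.  One row per patient.
patient_summaries <- function(records) {
  if (!inherits(records, "ni_events")) records <- validate_event_history(records)
  dur <- records$exit - records$entry
  s0 <- records$from == 0L
  s1 <- records$from == 1L
  ids <- unique(records$id)
  f <- factor(records$id, levels = ids)
  sum_by <- function(x) {
    out <- rowsum(x, f)
    out[match(ids, rownames(out)), 1L]
  }
  data.frame(
    id = ids,
    n01 = sum_by(as.numeric(s0 & records$to == "1")),
    n02 = sum_by(as.numeric(s0 & records$to == "2")),
    n12 = sum_by(as.numeric(s1 & records$to == "2")),
    days0 = sum_by(dur * s0),
    days1 = sum_by(dur * s1),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

## Vectorised estimand evaluation over B hazard triples, with explicit
## undefined-ness masks mirroring the scalar domain rules.
estimands_vectorised <- function(l01, l02, l12) {
  s0 <- ifelse(l01 + l02 > 0, 1 / (l01 + l02), NA_real_)
  s1 <- ifelse(l12 > 0, 1 / l12, NA_real_)
  risk <- ifelse(l02 > 0, l01 / (l01 + l02), NA_real_)
  mlos <- ifelse(l02 > 0 & (l01 == 0 | l12 > 0),
                 s0 + ifelse(l01 == 0, 0, risk * s1), NA_real_)
  list(
    a1 = s1,
    a2 = ifelse(l12 > 0 & l02 > 0, 1 / l12 - 1 / l02, NA_real_),
    a3 = ifelse(l02 > 0, ifelse(l01 == 0, 0,
                ifelse(l12 > 0, mlos - 1 / l02, NA_real_)), NA_real_),
    a4 = ifelse(l12 > 0 & l02 > 0, (l02 / l12 - 1) / (l01 + l02), NA_real_),
    mean_los = mlos,
    sojourn0 = s0,
    sojourn1 = s1,
    los_no_ni = ifelse(l02 > 0, 1 / l02, NA_real_),
    risk_ni = risk,
    odds_ni = ifelse(l02 > 0, l01 / l02, NA_real_),
    hazard_ratio = ifelse(l02 > 0 & l12 > 0, l12 / l02, NA_real_)
  )
}

#' Patient-level bootstrap confidence intervals for all estimands
#'
#' Nonparametric bootstrap that resamples \emph{patients} (entire paths,
#' never individual rows) with replacement, recomputes the hazards and
#' every reported quantity on each replicate, and returns percentile
#' intervals.  Replicates on which a quantity is undefined (e.g. no
#' infections resampled, so \eqn{\hat\lambda_{12}} has no events) are
#' counted and reported per quantity, not silently dropped; if every
#' replicate is undefined the interval itself is undefined.
#'
#' Reproducibility: draws use R's default Mersenne-Twister generator,
#' seeded once with \code{seed}; a fixed seed gives bit-identical
#' intervals across runs.
#'
#' @param records an event history with patient-level paths (aggregated
#'   counts alone cannot be resampled by patient).
#' @param B number of bootstrap replicates, default 1000.
#' @param level confidence level, default 0.95.
#' @param seed integer seed for the resampling generator.
#' @return A list of class \code{"ni_bootstrap"}: per quantity a list
#'   with \code{lower}, \code{upper}, \code{level}, \code{n_undefined},
#'   \code{B}; plus a \code{replicates} matrix (B rows) for inspection.
#' @export
bootstrap_ci <- function(records, B = 1000, level = 0.95, seed = 1L) {
  stopifnot(B >= 1, level > 0, level < 1)
  ps <- patient_summaries(records)
  n <- nrow(ps)
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  resample_sum <- function(x) {
    m <- matrix(x[idx], nrow = B)
    rowSums(m)
  }
  n01 <- resample_sum(ps$n01); n02 <- resample_sum(ps$n02)
  n12 <- resample_sum(ps$n12)
  d0 <- resample_sum(ps$days0); d1 <- resample_sum(ps$days1)
  l01 <- ifelse(d0 > 0, n01 / d0, NA_real_)
  l02 <- ifelse(d0 > 0, n02 / d0, NA_real_)
  l12 <- ifelse(d1 > 0, n12 / d1, ifelse(n01 == 0, 0, NA_real_))
  reps <- estimands_vectorised(l01, l02, l12)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- lapply(reps, function(v) {
    bad <- sum(is.na(v))
    if (bad == B) {
      list(lower = NA_real_, upper = NA_real_, level = level,
           n_undefined = bad, B = B, undefined = TRUE)
    } else {
      q <- stats::quantile(v, probs = probs, na.rm = TRUE, names = FALSE,
                           type = 7)
      list(lower = q[1L], upper = q[2L], level = level,
           n_undefined = bad, B = B, undefined = FALSE)
    }
  })
  attr(out, "replicates") <- do.call(cbind, reps)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- "ni_bootstrap"
  out
}

#' @export
print.ni_bootstrap <- function(x, ...) {
  cat(sprintf("Patient-level bootstrap (B = %d, seed = %d)\n",
              x[[1L]]$B, attr(x, "seed")))
  for (nm in names(x)) {
    ci <- x[[nm]]
    if (isTRUE(ci$undefined)) {
      cat(sprintf("  %-12s undefined in all replicates\n", nm))
    } else {
      extra <- if (ci$n_undefined > 0)
        sprintf("  (%d undefined replicates)", ci$n_undefined) else ""
      cat(sprintf("  %-12s [%.4f, %.4f] @%.0f%%%s\n", nm, ci$lower, ci$upper,
                  100 * ci$level, extra))
    }
  }
  invisible(x)
}

#' Fit the illness-death length-of-stay model
#'
#' One-stop composition: aggregates an event history (or accepts
#' pre-aggregated counts), estimates the hazards by maximum likelihood,
#' evaluates the full estimand report and the relationship table, and
#' optionally attaches patient-level bootstrap intervals.
#'
#' @param data an event history (data frame with \code{id,from,to,entry,exit})
#'   or an [cohort_counts()] object.
#' @param bootstrap number of bootstrap replicates for confidence
#'   intervals; 0 (default) disables them.  Requires patient-level
#'   records.
#' @param level confidence level for bootstrap intervals.
#' @param seed seed for the bootstrap resampler.
#' @return A list of class \code{"ni_fit"}: \code{counts},
#'   \code{hazards}, \code{report} (an [estimand_report()]),
#'   \code{relationships} (a [relationship_table()], or \code{NULL} when
#'   a hazard is zero), \code{bootstrap} (or \code{NULL}),
#'   \code{input_form} (\code{"records"} or \code{"counts"}).
#' @examples
#' fit(cohort_counts(756, 124, 632, 124, 6442, 1527))
#' @export
fit <- function(data, bootstrap = 0, level = 0.95, seed = 1L) {
  if (inherits(data, "ni_counts")) {
    counts <- data
    input_form <- "counts"
    records <- NULL
  } else {
    records <- if (inherits(data, "ni_events")) data else validate_event_history(data)
    counts <- aggregate_counts(records)
    input_form <- "records"
  }
  h <- estimate_hazards(counts)
  boot <- NULL
  if (bootstrap > 0) {
    if (is.null(records)) {
      stop("bootstrap intervals require patient-level records, not counts",
           call. = FALSE)
    }
    boot <- bootstrap_ci(records, B = bootstrap, level = level, seed = seed)
  }
  report <- estimand_report(h, ci = boot)
  rel <- if (h$lambda01 > 0 && h$lambda02 > 0 && h$lambda12 > 0) {
    relationship_table(h)
  } else NULL
  structure(list(counts = counts, hazards = h, report = report,
                 relationships = rel, bootstrap = boot,
                 input_form = input_form),
            class = "ni_fit")
}

#' @export
print.ni_fit <- function(x, ...) {
  cat(sprintf("Illness-death LOS fit (input: %s)\n\n", x$input_form))
  print(x$counts)
  cat("\n")
  print(x$hazards)
  cat("\n")
  print(x$report)
  if (!is.null(x$relationships)) {
    cat("\nRelationships (value | closed form):\n")
    r <- x$relationships
    for (i in seq_len(nrow(r))) {
      cat(sprintf("  %-6s %10.4f | %10.4f  %s\n", r$name[i], r$value[i],
                  r$closed_form[i], r$label[i]))
    }
  }
  invisible(x)
}
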