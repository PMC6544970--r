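## Event histories are plain data frames in the long multistate format
## used throughout hospital epidemiology: one row per observed transition
## interval, columns id, from, to, entry, exit.  States are coded 0
## (admitted, uninfected), 1 (infected) and 2 (discharge/death); "cens"
## as a destination marks administrative censoring in the origin state.

CENS <- "cens"

#' Construct an event-history table
#'
#' Builds and validates a long-format multistate event history.  Each row
#' is one transition interval for one patient: origin state \code{from}
#' (0 or 1), destination \code{to} (1, 2 or \code{"cens"}), and the entry
#' and exit times in days with \code{exit > entry} strictly.  Patients
#' may have at most one infection (0 to 1) row, and a state-1 row must
#' start exactly where that row ended.
#'
#' @param id patient identifiers (coerced to character).
#' @param from origin states, 0 or 1.
#' @param to destination states: 1, 2 or \code{"cens"}.
#' @param entry,exit interval endpoints in days, \code{exit > entry}.
#' @return A validated data frame of class \code{"ni_events"}.
#' @examples
#' event_history(id = c("p1", "p1", "p2"),
#'               from = c(0, 1, 0), to = c(1, 2, 2),
#'               entry = c(0, 3, 0), exit = c(3, 8, 5))
#' @export
event_history <- function(id, from, to, entry, exit) {
  df <- data.frame(id = as.character(id), from = as.integer(from),
                   to = as.character(to), entry = as.numeric(entry),
                   exit = as.numeric(exit), stringsAsFactors = FALSE)
  validate_event_history(df)
}

#' Validate an event-history table
#'
#' Enforces the multistate path invariants row by row and patient by
#' patient; error messages name the offending row or patient.
#'
#' @param records a data frame with columns \code{id}, \code{from},
#'   \code{to}, \code{entry}, \code{exit}.
#' @return The records, with class \code{"ni_events"} prepended.
#' @export
validate_event_history <- function(records) {
  required <- c("id", "from", "to", "entry", "exit")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop(sprintf("event history is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  records$id <- as.character(records$id)
  records$to <- as.character(records$to)
  if (!is.numeric(records$from)) records$from <- as.integer(records$from)
  if (!is.numeric(records$entry) || !is.numeric(records$exit)) {
    stop("entry and exit must be numeric days", call. = FALSE)
  }
  if (any(!is.finite(records$entry)) || any(!is.finite(records$exit))) {
    bad <- which(!is.finite(records$entry) | !is.finite(records$exit))[1L]
    stop(sprintf("row %d (patient %s): non-finite time", bad, records$id[bad]),
         call. = FALSE)
  }
  if (any(records$entry < 0)) {
    bad <- which(records$entry < 0)[1L]
    stop(sprintf("row %d (patient %s): negative entry time", bad, records$id[bad]),
         call. = FALSE)
  }
  zero <- records$exit <= records$entry
  if (any(zero)) {
    bad <- which(zero)[1L]
    stop(sprintf("row %d (patient %s): exit (%g) must exceed entry (%g)",
                 bad, records$id[bad], records$exit[bad], records$entry[bad]),
         call. = FALSE)
  }
  key <- paste(records$from, records$to, sep = "->")
  ok <- key %in% c("0->1", "0->2", "1->2", paste0("0->", CENS), paste0("1->", CENS))
  if (any(!ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("row %d (patient %s): invalid transition %s -> %s",
                 bad, records$id[bad], records$from[bad], records$to[bad]),
         call. = FALSE)
  }
  for (pid in unique(records$id)) {
    rows <- records[records$id == pid, , drop = FALSE]
    rows <- rows[order(rows$entry), , drop = FALSE]
    inf <- rows$from == 0L & rows$to == "1"
    if (sum(inf) > 1L) {
      stop(sprintf("patient %s: more than one 0 -> 1 transition", pid),
           call. = FALSE)
    }
    s0 <- rows$from == 0L
    if (sum(s0) > 1L) {
      stop(sprintf("patient %s: more than one state-0 interval", pid),
           call. = FALSE)
    }
    s1 <- rows$from == 1L
    if (any(s1)) {
      if (sum(s1) > 1L) {
        stop(sprintf("patient %s: more than one state-1 interval", pid),
             call. = FALSE)
      }
      if (!any(inf)) {
        stop(sprintf("patient %s: state-1 row without a prior 0 -> 1 row", pid),
             call. = FALSE)
      }
      if (abs(rows$entry[s1] - rows$exit[inf]) > 1e-9) {
        stop(sprintf(
          "patient %s: state-1 entry (%g) does not match infection time (%g)",
          pid, rows$entry[s1], rows$exit[inf]), call. = FALSE)
      }
    }
  }
  if (!inherits(records, "ni_events")) {
    class(records) <- c("ni_events", class(records))
  }
  records
}

#' Construct cohort sufficient statistics directly
#'
#' The constant-hazard likelihood depends on the event history only
#' through six numbers: the cohort size, the three transition counts and
#' the person-days at risk in states 0 and 1.  This constructor accepts
#' them directly, e.g. from a published table.
#'
#' @param n_patients number of patients.
#' @param n01 number of infections (0 to 1 transitions).
#' @param n02 number of discharges/deaths from state 0.
#' @param n12 number of discharges/deaths from state 1.
#' @param days0 summed person-days at risk in state 0.
#' @param days1 summed person-days at risk in state 1.
#' @return An object of class \code{"ni_counts"}.
#' @examples
#' cohort_counts(756, 124, 632, 124, 6442, 1527)
#' @export
cohort_counts <- function(n_patients, n01, n02, n12, days0, days1) {
  cnt <- c(n_patients = n_patients, n01 = n01, n02 = n02, n12 = n12)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!is.finite(days0) || !is.finite(days1) || days0 < 0 || days1 < 0) {
    stop("person-days must be non-negative and finite", call. = FALSE)
  }
  if (n12 > n01) {
    stop("n12 cannot exceed n01: only infected patients can leave state 1",
         call. = FALSE)
  }
  if (n01 > 0 && days1 <= 0) {
    stop("days1 must be positive when infections occurred", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), n01 = as.integer(n01),
                 n02 = as.integer(n02), n12 = as.integer(n12),
                 days0 = as.numeric(days0), days1 = as.numeric(days1)),
            class = "ni_counts")
}

#' @export
print.ni_counts <- function(x, ...) {
  cat("Cohort sufficient statistics\n")
  cat(sprintf("  patients: %d;  infections (0->1): %d\n", x$n_patients, x$n01))
  cat(sprintf("  discharge/death from state 0: %d;  from state 1: %d\n",
              x$n02, x$n12))
  cat(sprintf("  person-days at risk: state 0 = %g, state 1 = %g\n",
              x$days0, x$days1))
  invisible(x)
}

#' Aggregate an event history into cohort sufficient statistics
#'
#' Sums person-days at risk per state and counts transitions by type.
#' Censored rows contribute their risk time but no event count.
#'
#' @param records an event history (validated with
#'   [validate_event_history()] if not already of class
#'   \code{"ni_events"}).
#' @return An \code{"ni_counts"} object.
#' @examples
#' ev <- event_history(id = c("p1", "p1"), from = c(0, 1), to = c(1, 2),
#'                     entry = c(0, 3), exit = c(3, 8))
#' aggregate_counts(ev)
#' @export
aggregate_counts <- function(records) {
  if (!inherits(records, "ni_events")) records <- validate_event_history(records)
  dur <- records$exit - records$entry
  s0 <- records$from == 0L
  s1 <- records$from == 1L
  cohort_counts(
    n_patients = length(unique(records$id)),
    n01 = sum(s0 & records$to == "1"),
    n02 = sum(s0 & records$to == "2"),
    n12 = sum(s1 & records$to == "2"),
    days0 = sum(dur[s0]),
    days1 = sum(dur[s1])
  )
}
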