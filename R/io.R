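## File formats
##
## Event-history CSV: header `id,from,to,entry,exit`; states 0/1/2,
## censoring coded `cens`; times in decimal days; UTF-8, comma-separated.
## Counts form: either a JSON object or a one-row CSV with fields
## `n_patients,n01,n02,n12,days0,days1`.

#' Read a long-format event-history CSV
#'
#' Parses and validates the `id,from,to,entry,exit` dialect.  Parse and
#' validation errors name the offending column, row or patient.
#'
#' @param path path to a CSV file.
#' @return A validated \code{"ni_events"} data frame.
#' @export
read_event_history <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character"))
  required <- c("id", "from", "to", "entry", "exit")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("entry", "exit")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric %s on line %d (patient %s)", path, col,
                   bad[1L] + 1L, df$id[bad[1L]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  bad_from <- which(!df$from %in% c("0", "1"))
  if (length(bad_from)) {
    stop(sprintf("%s: invalid origin state '%s' on line %d", path,
                 df$from[bad_from[1L]], bad_from[1L] + 1L), call. = FALSE)
  }
  df$from <- as.integer(df$from)
  bad_to <- which(!df$to %in% c("1", "2", CENS))
  if (length(bad_to)) {
    stop(sprintf("%s: invalid destination state '%s' on line %d", path,
                 df$to[bad_to[1L]], bad_to[1L] + 1L), call. = FALSE)
  }
  validate_event_history(df)
}

#' Write an event history to CSV
#'
#' @param records an event history.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_event_history <- function(records, path) {
  if (!inherits(records, "ni_events")) records <- validate_event_history(records)
  df <- as.data.frame(records)[, c("id", "from", "to", "entry", "exit")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cohort counts from JSON or one-row CSV
#'
#' Accepts either a JSON object or a one-row CSV providing
#' \code{n_patients,n01,n02,n12,days0,days1}, the sufficient statistics
#' of the constant-hazard model.
#'
#' @param path path to a \code{.json} or \code{.csv} file.
#' @return An [cohort_counts()] object.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(sub(".*\\.", "", path))
  vals <- if (ext == "json") {
    as.list(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) != 1L) {
      stop(sprintf("%s: counts CSV must have exactly one row", path),
           call. = FALSE)
    }
    as.list(df[1L, ])
  }
  required <- c("n_patients", "n01", "n02", "n12", "days0", "days1")
  missing_f <- setdiff(required, names(vals))
  if (length(missing_f)) {
    stop(sprintf("%s: missing field(s): %s", path,
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  cohort_counts(vals$n_patients, vals$n01, vals$n02, vals$n12,
                vals$days0, vals$days1)
}

## Flat one-row-per-quantity view shared by the CSV and JSON writers:
## name, value, closed_form, lower, upper.
flatten_fit <- function(object) {
  rep <- object$report
  out <- data.frame(
    name = rep$quantity,
    value = rep$value,
    closed_form = rep$value,
    lower = if ("lower" %in% names(rep)) rep$lower else NA_real_,
    upper = if ("upper" %in% names(rep)) rep$upper else NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(object$relationships)) {
    r <- object$relationships
    out <- rbind(out, data.frame(
      name = r$name, value = r$value, closed_form = r$closed_form,
      lower = NA_real_, upper = NA_real_, stringsAsFactors = FALSE))
  }
  out
}

#' Serialise a fit to JSON and CSV reports
#'
#' Writes \code{report.json} (hazards, counts, estimands with unrounded
#' and paper-precision rounded values, relationships, bootstrap
#' settings) and \code{report.csv} (flat: one row per quantity with
#' name, value, closed_form, lower, upper) into a directory.  Day-valued
#' quantities are rounded to 2 decimals and rates/ratios to 4 in the
#' \code{rounded} fields; unrounded values are always retained.
#'
#' @param object an \code{"ni_fit"} from [fit()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_report <- function(object, dir) {
  stopifnot(inherits(object, "ni_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rep <- object$report
  days <- rep$units == "days"
  json <- list(
    input_form = object$input_form,
    counts = unclass(object$counts),
    hazards = list(
      lambda01 = object$hazards$lambda01,
      lambda02 = object$hazards$lambda02,
      lambda12 = object$hazards$lambda12,
      rounded = as.list(round(c(lambda01 = object$hazards$lambda01,
                                lambda02 = object$hazards$lambda02,
                                lambda12 = object$hazards$lambda12), 4))
    ),
    estimands = lapply(seq_len(nrow(rep)), function(i) {
      e <- list(name = rep$quantity[i], value = rep$value[i],
                rounded = round(rep$value[i], if (days[i]) 2L else 4L),
                units = rep$units[i], undefined = rep$undefined[i])
      if ("lower" %in% names(rep) && !is.na(rep$lower[i])) {
        e$lower <- rep$lower[i]; e$upper <- rep$upper[i]
        e$level <- rep$level[i]
      }
      e
    }),
    relationships = if (is.null(object$relationships)) NULL else
      object$relationships[, c("name", "type", "value", "closed_form",
                               "undefined", "label")]
  )
  if (!is.null(object$bootstrap)) {
    json$bootstrap <- list(B = object$bootstrap[[1L]]$B,
                           level = object$bootstrap[[1L]]$level,
                           seed = attr(object$bootstrap, "seed"),
                           method = "patient-level nonparametric, percentile")
  }
  json_path <- file.path(dir, "report.json")
  csv_path <- file.path(dir, "report.csv")
  jsonlite::write_json(json, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  utils::write.csv(flatten_fit(object), csv_path, row.names = FALSE)
  invisible(c(json = json_path, csv = csv_path))
}
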