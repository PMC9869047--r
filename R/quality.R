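#' Data-quality report for a clinical event log
#'
#' Screens every trace for the recording errors that surfaced during data
#' curation of prostate-cancer care logs:
#' \describe{
#'   \item{treatment-after-exitus}{any non-Exitus event strictly after an
#'     Exitus event;}
#'   \item{pre-diagnosis-treatment}{a treatment event strictly before the
#'     (first) Diagnosis event;}
#'   \item{missing-diagnosis}{trace with no Diagnosis event at all;}
#'   \item{invalid-psa-value}{a PSA-type episode with a missing or negative
#'     value.}
#' }
#' A diagnosis and a treatment sharing a date is a known recording artifact
#' of day-resolution EHR extraction, not an error: it is reported as an
#' informational `same-date-diagnosis-treatment` note.
#'
#' @param log An [eventlog()].
#' @param treatments Character vector of activity labels counted as
#'   treatments for the pre-diagnosis rule.
#' @param diagnosis,exitus,psa Activity labels used by the rules.
#' @return A `validation_report`: list with `issues` (tibble of `case_id`,
#'   `rule`, `severity`, `description`, `event_index`) and `counts` (named
#'   per-rule totals, errors only).
#' @examples
#' log <- eventlog(data.frame(
#'   case_id = "p1",
#'   timestamp = as.Date("2020-01-01") + c(0, 10, 20),
#'   activity = c("Diagnosis", "Exitus", "Chemotherapy")
#' ))
#' quality_report(log)
#' @export
quality_report <- function(log,
                           treatments = default_treatments(),
                           diagnosis = "Diagnosis",
                           exitus = "Exitus",
                           psa = "PSA") {
  issues <- list()
  add <- function(case_id, rule, severity, description, event_index) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      case_id = case_id, rule = rule, severity = severity,
      description = description, event_index = as.integer(event_index)
    )
  }
  ev <- log$events
  for (cid in case_ids(log)) {
    idx <- which(ev$case_id == cid)
    acts <- ev$activity[idx]
    dates <- ev$timestamp[idx]

    ex_at <- which(acts == exitus)
    if (length(ex_at)) {
      ex_date <- min(dates[ex_at])
      late <- which(acts != exitus & dates > ex_date)
      for (i in late) {
        add(cid, "treatment-after-exitus", "error",
            sprintf("'%s' on %s is after exitus on %s",
                    acts[i], dates[i], ex_date), i)
      }
    }

    dx_at <- which(acts == diagnosis)
    if (!length(dx_at)) {
      add(cid, "missing-diagnosis", "error", "trace has no Diagnosis event",
          NA_integer_)
    } else {
      dx_date <- min(dates[dx_at])
      early <- which(acts %in% treatments & dates < dx_date)
      for (i in early) {
        add(cid, "pre-diagnosis-treatment", "error",
            sprintf("'%s' on %s precedes diagnosis on %s",
                    acts[i], dates[i], dx_date), i)
      }
      same_day <- which(acts %in% treatments & dates == dx_date)
      if (length(same_day)) {
        add(cid, "same-date-diagnosis-treatment", "info",
            "diagnosis and treatment recorded on the same date",
            same_day[1])
      }
    }

    bad_psa <- which(acts == psa & (is.na(ev$value[idx]) | ev$value[idx] < 0))
    for (i in bad_psa) {
      add(cid, "invalid-psa-value", "error",
          "PSA episode with missing or negative value", i)
    }
  }
  issues <- if (length(issues)) dplyr::bind_rows(issues) else
    tibble::tibble(case_id = character(), rule = character(),
                   severity = character(), description = character(),
                   event_index = integer())
  errors <- issues[issues$severity == "error", , drop = FALSE]
  counts <- table(factor(errors$rule, levels = c(
    "treatment-after-exitus", "pre-diagnosis-treatment",
    "missing-diagnosis", "invalid-psa-value"
  )))
  structure(list(issues = issues, counts = c(counts)),
            class = "validation_report")
}

#' Default treatment activity set
#'
#' The care steps counted as treatments by the pre-diagnosis quality rule.
#' @return Character vector of activity labels.
#' @export
default_treatments <- function() {
  c("Radical Prostatectomy", "Hormonal Therapy", "Chemotherapy",
    "Radiotherapy")
}

#' @export
print.validation_report <- function(x, ...) {
  n_err <- sum(x$issues$severity == "error")
  n_info <- sum(x$issues$severity == "info")
  cat(sprintf("<validation_report: %d error(s), %d note(s)>\n", n_err, n_info))
  if (n_err) print(x$counts[x$counts > 0])
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A `validation_report`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @return JSON string or `path` invisibly.
#' @export
report_to_json <- function(report, path = NULL) {
  obj <- list(counts = as.list(report$counts), issues = report$issues)
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
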