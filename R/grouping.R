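#' Partition a log by a trace metadata field
#'
#' Cohort grouping: splits the log into disjoint sublogs by the value of a
#' diagnosis-level metadata field (e.g. ISUP `Grade`, `PSA Range`). Traces
#' where the field is missing go to a reserved `"unknown"` group, so the
#' sublogs always cover the input log.
#'
#' @param log An [eventlog()].
#' @param field Metadata field name (see [metadata_fields()]).
#' @return Named list of `eventlog` objects, keyed by field value.
#' @examples
#' log <- simulate_care_log(n_patients = 20, seed = 1)
#' sapply(group_by_metadata(log, "Grade"), n_traces)
#' @export
group_by_metadata <- function(log, field) {
  if (!field %in% metadata_fields(log)) {
    stop("unknown metadata field '", field, "'; available: ",
         paste(metadata_fields(log), collapse = ", "))
  }
  values <- as.character(log$cases[[field]])
  values[is.na(values) | values == ""] <- "unknown"
  keys <- unique(values)
  out <- lapply(keys, function(k) subset_log(log, log$cases$case_id[values == k]))
  names(out) <- keys
  out
}

#' Extract traces traversing a node or a consecutive node pair
#'
#' The declare-style filter: given an activity name, returns the sub-cohort
#' of traces containing that activity; given an ordered pair of activities,
#' returns the traces where the second directly follows the first. Trace
#' order is preserved; an empty result is valid.
#'
#' @param log An [eventlog()].
#' @param element Character scalar (node form) or length-2 character vector
#'   (ordered consecutive pair form).
#' @return An `eventlog` with the matching traces.
#' @examples
#' log <- simulate_care_log(n_patients = 30, seed = 2)
#' n_traces(filter_traverses(log, "Exitus"))
#' n_traces(filter_traverses(log, c("Diagnosis", "Radical Prostatectomy")))
#' @export
filter_traverses <- function(log, element) {
  element <- as.character(element)
  if (!length(element) %in% 1:2 || any(!nzchar(element))) {
    stop("element must be one activity name or an ordered pair of names")
  }
  seqs <- trace_sequences(log)
  keep <- if (length(element) == 1) {
    vapply(seqs, function(s) element %in% s, logical(1))
  } else {
    vapply(seqs, function(s) {
      n <- length(s)
      n >= 2 && any(s[-n] == element[1] & s[-1] == element[2])
    }, logical(1))
  }
  subset_log(log, names(seqs)[keep])
}

#' Derive state traces from a measured value
#'
#' Re-expresses each trace as the evolution of a measured quantity (PSA by
#' default): every event of `value_activity` is mapped to a state label by
#' binning its value, and consecutive repeats of the same state are collapsed
#' to one state event (timestamp of the first event of the run), so that
#' repeated stable measurements do not dominate downstream edit distances.
#' Traces without any `value_activity` event are dropped with a warning.
#'
#' Binning convention: with breakpoints `b1 < ... < bk` the bins are
#' `(-Inf, b1)`, `[b1, b2)`, ..., `[b_{k-1}, bk]`, `(bk, Inf)` — interior
#' boundaries left-closed, the top breakpoint included in the bin below it,
#' matching the printed "10–20" range style where both endpoints belong to
#' the middle bin. Set `rightmost_closed = FALSE` for strict left-closed
#' binning throughout.
#'
#' @param log An [eventlog()].
#' @param value_activity Activity carrying the measured value.
#' @param breakpoints Strictly increasing numeric breakpoints.
#' @param labels State labels; `length(breakpoints) + 1` of them.
#' @param collapse Collapse consecutive identical states (default TRUE).
#' @param rightmost_closed Include the largest breakpoint in the bin below it.
#' @return An `eventlog` of state events (activity = state label); trace
#'   metadata carried through. Events missing a value are skipped and
#'   reported via a warning.
#' @examples
#' log <- simulate_care_log(n_patients = 10, seed = 3)
#' derive_state_traces(log)
#' @export
derive_state_traces <- function(log, value_activity = "PSA",
                                breakpoints = c(10, 20),
                                labels = c("<10", "10-20", ">20"),
                                collapse = TRUE,
                                rightmost_closed = TRUE) {
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing")
  }
  if (length(labels) != length(breakpoints) + 1) {
    stop("need exactly length(breakpoints) + 1 labels")
  }
  ev <- log$events
  target <- ev[ev$activity == value_activity, , drop = FALSE]
  n_missing <- sum(is.na(target$value))
  if (n_missing) {
    warning(n_missing, " ", value_activity,
            " event(s) without a value skipped")
    target <- target[!is.na(target$value), , drop = FALSE]
  }
  target$activity <- labels[bin_value(target$value, breakpoints,
                                      rightmost_closed)]
  target$value <- NA_real_
  kept <- list()
  for (cid in unique(target$case_id)) {
    rows <- target[target$case_id == cid, , drop = FALSE]
    if (collapse && nrow(rows) > 1) {
      run_start <- c(TRUE, rows$activity[-1] != rows$activity[-nrow(rows)])
      rows <- rows[run_start, , drop = FALSE]
    }
    kept[[cid]] <- rows
  }
  dropped <- setdiff(case_ids(log), names(kept))
  if (length(dropped)) {
    warning(length(dropped), " trace(s) without any ", value_activity,
            " event dropped")
  }
  if (!length(kept)) stop("no ", value_activity, " events in the log")
  out_events <- dplyr::bind_rows(kept)
  cases <- log$cases[log$cases$case_id %in% out_events$case_id, , drop = FALSE]
  eventlog(out_events, cases, schema = log$schema)
}

bin_value <- function(x, breakpoints, rightmost_closed = TRUE) {
  findInterval(x, breakpoints, rightmost.closed = rightmost_closed) + 1L
}
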