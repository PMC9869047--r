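#' Discover the timed workflow model of an event log
#'
#' Builds the timed directly-follows graph that underlies every process view:
#' one node per distinct activity label plus the artificial `@Start` and
#' `@End` nodes always present, one directed arc per observed consecutive
#' activity pair (including `@Start` to each trace's first activity and each
#' trace's last activity to `@End`), and per-element execution records with
#' durations in days.
#'
#' Sojourn (time spent in a node occurrence) is the gap to the trace's next
#' event start; a trace's final event gets sojourn 0 so duration statistics
#' stay total, unless the event carries an `end_timestamp`, in which case the
#' sojourn is `end - start`. Each arc execution records both endpoint start
#' dates: the arc's own duration is the sojourn in its source occurrence,
#' while the full duration (start of source to start of target) is kept
#' separately — for day-dated point events the two coincide.
#'
#' @param log A non-empty [eventlog()].
#' @return A `workflow_model`: list with `node_exec` (tibble `label`,
#'   `case_id`, `start`, `sojourn`), `arc_exec` (tibble `from`, `to`,
#'   `case_id`, `source_start`, `target_start`, `sojourn`), and `n_traces`.
#' @examples
#' log <- simulate_care_log(n_patients = 25, seed = 4)
#' model <- discover_workflow(log)
#' model_nodes(model)
#' model_arcs(model)
#' @export
discover_workflow <- function(log) {
  if (n_traces(log) == 0) stop("nothing to discover: the log is empty")
  ev <- log$events
  n <- nrow(ev)
  same_next <- c(ev$case_id[-1] == ev$case_id[-n], FALSE)
  if (n == 1) same_next <- FALSE
  next_start <- c(ev$timestamp[-1], as.Date(NA))
  sojourn <- ifelse(same_next, as.numeric(next_start - ev$timestamp), 0)
  has_end <- !same_next & !is.na(ev$end_timestamp)
  sojourn[has_end] <- as.numeric(ev$end_timestamp[has_end] -
                                 ev$timestamp[has_end])

  first_of_case <- !duplicated(ev$case_id)
  last_of_case <- !same_next

  node_exec <- tibble::tibble(
    label = ev$activity, case_id = ev$case_id,
    start = ev$timestamp, sojourn = sojourn
  )
  start_rows <- tibble::tibble(
    label = "@Start", case_id = ev$case_id[first_of_case],
    start = ev$timestamp[first_of_case], sojourn = 0
  )
  end_rows <- tibble::tibble(
    label = "@End", case_id = ev$case_id[last_of_case],
    start = ev$timestamp[last_of_case] + sojourn[last_of_case], sojourn = 0
  )
  node_exec <- dplyr::bind_rows(node_exec, start_rows, end_rows)

  inner <- which(same_next)
  arc_exec <- tibble::tibble(
    from = ev$activity[inner], to = ev$activity[inner + 1L],
    case_id = ev$case_id[inner],
    source_start = ev$timestamp[inner],
    target_start = ev$timestamp[inner + 1L],
    sojourn = sojourn[inner]
  )
  arc_start <- tibble::tibble(
    from = "@Start", to = ev$activity[first_of_case],
    case_id = ev$case_id[first_of_case],
    source_start = ev$timestamp[first_of_case],
    target_start = ev$timestamp[first_of_case],
    sojourn = 0
  )
  arc_end <- tibble::tibble(
    from = ev$activity[last_of_case], to = "@End",
    case_id = ev$case_id[last_of_case],
    source_start = ev$timestamp[last_of_case],
    target_start = ev$timestamp[last_of_case] + sojourn[last_of_case],
    sojourn = sojourn[last_of_case]
  )
  arc_exec <- dplyr::bind_rows(arc_exec, arc_start, arc_end)

  structure(
    list(node_exec = node_exec, arc_exec = arc_exec,
         n_traces = n_traces(log)),
    class = "workflow_model"
  )
}

#' Workflow model of a single trace
#'
#' Identical to [discover_workflow()] on a one-trace log; used by the
#' topological trace distance and by the individual-patient view.
#'
#' @param log An [eventlog()].
#' @param case_id Which trace.
#' @return A `workflow_model`.
#' @export
trace_model <- function(log, case_id) {
  sub <- subset_log(log, case_id)
  if (n_traces(sub) == 0) stop("no such trace: ", case_id)
  discover_workflow(sub)
}

#' @export
print.workflow_model <- function(x, ...) {
  cat(sprintf("<workflow_model: %d nodes, %d arcs, %d traces>\n",
              nrow(model_nodes(x)), nrow(model_arcs(x)), x$n_traces))
  invisible(x)
}

#' Node summary of a workflow model
#' @param model A `workflow_model`.
#' @return Tibble `label`, `executions`, `traces` sorted by label.
#' @export
model_nodes <- function(model) {
  model$node_exec |>
    dplyr::group_by(label = .data$label) |>
    dplyr::summarise(executions = dplyr::n(),
                     traces = dplyr::n_distinct(.data$case_id),
                     .groups = "drop") |>
    dplyr::arrange(.data$label)
}

#' Arc summary of a workflow model
#' @param model A `workflow_model`.
#' @return Tibble `from`, `to`, `executions`, `traces` sorted by endpoints.
#' @export
model_arcs <- function(model) {
  model$arc_exec |>
    dplyr::group_by(from = .data$from, to = .data$to) |>
    dplyr::summarise(executions = dplyr::n(),
                     traces = dplyr::n_distinct(.data$case_id),
                     .groups = "drop") |>
    dplyr::arrange(.data$from, .data$to)
}

#' Activity labels of a model
#' @param model A `workflow_model`.
#' @param artificial Include `@Start`/`@End`.
#' @return Character vector of node labels.
#' @export
model_activities <- function(model, artificial = FALSE) {
  labs <- sort(unique(model$node_exec$label))
  if (!artificial) labs <- setdiff(labs, c("@Start", "@End"))
  labs
}

is_artificial <- function(label) label %in% c("@Start", "@End")

#' Serialize a workflow model to canonical JSON
#'
#' Canonical form: node and arc summaries with execution counts, trace
#' counts and median durations, sorted by label, so identical models give
#' byte-identical JSON.
#'
#' @param model A `workflow_model`.
#' @param path Optional output file.
#' @return JSON string, or `path` invisibly.
#' @export
model_to_json <- function(model, path = NULL) {
  nodes <- model_nodes(model)
  nodes$median_sojourn <- vapply(nodes$label, function(l) {
    stats::median(model$node_exec$sojourn[model$node_exec$label == l])
  }, numeric(1))
  arcs <- model_arcs(model)
  arcs$median_sojourn <- mapply(function(f, t) {
    sel <- model$arc_exec$from == f & model$arc_exec$to == t
    stats::median(model$arc_exec$sojourn[sel])
  }, arcs$from, arcs$to)
  obj <- list(n_traces = model$n_traces, nodes = nodes, arcs = arcs)
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
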