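#' Clinical event logs
#'
#' An event log is the input of process mining: a set of timestamped care
#' episodes (events), grouped by patient into chronologically ordered traces
#' (cases). `eventlog()` builds a log from a data frame of events plus an
#' optional per-case metadata table; [read_log()] builds one from a delimited
#' file in the tabular dialect used throughout (Patient ID / Date / Episode /
#' Type / Value plus diagnosis-level cohort columns).
#'
#' Internally a log holds two tibbles:
#' \describe{
#'   \item{events}{one row per event: `case_id`, `timestamp` (Date),
#'     `end_timestamp` (Date or NA for point events), `activity`, `detail`,
#'     `value` (non-negative, PSA in ng/ml where applicable), plus any extra
#'     attribute columns carried through from the source.}
#'   \item{cases}{one row per trace: `case_id` plus metadata fields
#'     (by default `Age`, `PSA Range`, `Grade`, `Tr1`, `TR1 detail`).}
#' }
#' Events are stored sorted by case, date and the same-day activity priority
#' (see [read_log()]).
#'
#' @param events Data frame with at least `case_id`, `timestamp`, `activity`.
#' @param cases Optional data frame of per-case metadata keyed by `case_id`.
#' @param schema Character vector of source column names (kept for round-trip
#'   writing).
#' @param priority Named numeric vector of same-day activity priorities;
#'   smaller sorts earlier, unlisted activities get 0 and keep input order.
#' @return An object of class `eventlog`.
#' @seealso [read_log()], [write_log()], [quality_report()]
#' @export
eventlog <- function(events, cases = NULL, schema = character(),
                     priority = default_day_priority()) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("case_id", "timestamp", "activity") %in% names(events)))
  events$case_id <- as.character(events$case_id)
  events$timestamp <- as.Date(events$timestamp)
  if (!"end_timestamp" %in% names(events)) {
    events$end_timestamp <- as.Date(NA)
  }
  if (!"detail" %in% names(events)) events$detail <- NA_character_
  if (!"value" %in% names(events)) events$value <- NA_real_
  events$value <- as.numeric(events$value)
  events <- sort_events(events, priority)

  if (is.null(cases)) {
    cases <- tibble::tibble(case_id = unique(events$case_id))
  } else {
    cases <- tibble::as_tibble(cases)
    cases$case_id <- as.character(cases$case_id)
  }
  missing_cases <- setdiff(unique(events$case_id), cases$case_id)
  if (length(missing_cases)) {
    cases <- dplyr::bind_rows(cases, tibble::tibble(case_id = missing_cases))
  }
  log <- structure(
    list(events = events, cases = cases, schema = schema),
    class = "eventlog"
  )
  validate_eventlog(log)
  log
}

#' Default same-day ordering priorities
#'
#' Dates are day-resolution and diagnosis and first treatment are routinely
#' recorded on the same day, so within a day events are ordered by an
#' activity-priority list: Diagnosis first, Exitus last, everything else by
#' file order.
#'
#' @return Named numeric vector (lower = earlier).
#' @export
default_day_priority <- function() {
  c("Diagnosis" = -1, "Exitus" = 1)
}

sort_events <- function(events, priority = default_day_priority()) {
  prio <- priority[events$activity]
  prio[is.na(prio)] <- 0
  events[order(events$case_id, events$timestamp, prio,
               seq_len(nrow(events))), , drop = FALSE]
}

validate_eventlog <- function(log) {
  ev <- log$events
  if (anyNA(ev$timestamp)) stop("event timestamps must be valid dates")
  with_end <- !is.na(ev$end_timestamp)
  if (any(ev$end_timestamp[with_end] < ev$timestamp[with_end])) {
    stop("end_timestamp must be >= timestamp")
  }
  if (any(ev$value < 0, na.rm = TRUE)) stop("event values must be >= 0")
  if (anyDuplicated(log$cases$case_id)) stop("case ids must be unique")
  invisible(log)
}

#' @export
print.eventlog <- function(x, ...) {
  cat(sprintf("<eventlog: %d traces, %d events, %d activities>\n",
              n_traces(x), nrow(x$events),
              length(unique(x$events$activity))))
  invisible(x)
}

#' Number of traces in a log
#' @param log An `eventlog`.
#' @return Integer count of cases.
#' @export
n_traces <- function(log) nrow(log$cases)

#' Case identifiers of a log
#' @param log An `eventlog`.
#' @return Character vector of case ids in storage order.
#' @export
case_ids <- function(log) log$cases$case_id

#' Activity sequences per trace
#'
#' @param log An `eventlog`.
#' @return Named list (by case id) of character vectors of activity labels in
#'   chronological order.
#' @export
trace_sequences <- function(log) {
  split(log$events$activity, factor(log$events$case_id,
                                    levels = log$cases$case_id))
}

#' Extract one trace
#' @param log An `eventlog`.
#' @param case_id Case identifier.
#' @return An `eventlog` containing only that case.
#' @export
get_trace <- function(log, case_id) {
  subset_log(log, case_id)
}

subset_log <- function(log, keep_ids) {
  structure(
    list(
      events = log$events[log$events$case_id %in% keep_ids, , drop = FALSE],
      cases = log$cases[log$cases$case_id %in% keep_ids, , drop = FALSE],
      schema = log$schema
    ),
    class = "eventlog"
  )
}

# canonical source-dialect column names
.dialect_columns <- c(
  case_id = "Patient ID", timestamp = "Date", activity = "Episode",
  detail = "Type", value = "Value"
)
.metadata_columns <- c("Age", "PSA Range", "Grade", "Tr1", "TR1 detail")

#' Read an event log from delimited text
#'
#' Parses a comma-delimited, UTF-8, headered file in the episode/cohort
#' dialect: required columns Patient ID, Date and Episode (matched
#' case-insensitively, or through `aliases`), optional Type (drug detail),
#' Value (PSA, ng/ml) and the per-patient cohort columns Age, PSA Range,
#' Grade, Tr1 and TR1 detail, whose first-seen value per patient becomes trace
#' metadata. Any remaining columns are kept verbatim as per-event attributes.
#'
#' Dates are parsed tolerantly: ISO-8601 (`2021-05-18`), `18 May 2021` and
#' `18/05/2021` styles are accepted and stored as calendar dates; durations
#' downstream are measured in days. Duplicate identical rows are dropped with
#' a warning. Within one day, events are ordered by `priority`
#' (see [default_day_priority()]).
#'
#' @param source Path to a CSV file, or a connection readable by
#'   [readr::read_csv()].
#' @param aliases Named character vector mapping dialect column names to the
#'   names actually used in the file, e.g. `c("Patient ID" = "pid")`.
#' @param priority Same-day activity priority, as in [eventlog()].
#' @return An [eventlog()].
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "Patient ID,Date,Episode,Type,Value,Age,PSA Range,Grade,Tr1,TR1 detail",
#'   "24972,18 May 2021,Chemotherapy,Abiraterona,,65,10-20,Grade group 1,OBS,ADT + QT"
#' ), path)
#' read_log(path)
#' @export
read_log <- function(source, aliases = NULL, priority = default_day_priority()) {
  raw <- readr::read_csv(source, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  resolve <- function(canon) {
    target <- if (!is.null(aliases) && canon %in% names(aliases)) {
      aliases[[canon]]
    } else {
      canon
    }
    hit <- which(tolower(names(raw)) == tolower(target))
    if (length(hit)) names(raw)[hit[1]] else NA_character_
  }
  req <- c("Patient ID", "Date", "Episode")
  src <- vapply(names(.dialect_columns), function(f) resolve(.dialect_columns[[f]]),
                character(1))
  missing_req <- req[is.na(src[match(req, .dialect_columns)])]
  if (length(missing_req)) {
    stop("required column(s) missing from input: ",
         paste(missing_req, collapse = ", "))
  }

  dup <- duplicated(raw)
  if (any(dup)) {
    warning(sum(dup), " duplicate identical row(s) removed")
    raw <- raw[!dup, , drop = FALSE]
  }

  dates <- parse_mixed_date(raw[[src[["timestamp"]]]])
  if (anyNA(dates)) {
    bad <- which(is.na(dates))
    stop("unparseable date(s) at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value: '", raw[[src[["timestamp"]]]][bad[1]], "')")
  }

  events <- tibble::tibble(
    case_id = as.character(raw[[src[["case_id"]]]]),
    timestamp = dates,
    activity = raw[[src[["activity"]]]],
    detail = if (!is.na(src[["detail"]])) raw[[src[["detail"]]]] else NA_character_,
    value = if (!is.na(src[["value"]])) suppressWarnings(as.numeric(raw[[src[["value"]]]])) else NA_real_
  )

  meta_src <- vapply(.metadata_columns, resolve, character(1))
  found_meta <- .metadata_columns[!is.na(meta_src)]
  cases <- NULL
  if (length(found_meta)) {
    meta <- raw[, meta_src[found_meta], drop = FALSE]
    names(meta) <- found_meta
    meta$case_id <- events$case_id
    cases <- meta |>
      dplyr::group_by(.data$case_id) |>
      dplyr::summarise(dplyr::across(
        dplyr::all_of(found_meta),
        ~ dplyr::first(stats::na.omit(.x)) %||% NA_character_
      ), .groups = "drop")
  }

  known <- stats::na.omit(c(src, meta_src))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    for (col in extra) events[[col]] <- raw[[col]]
  }
  eventlog(events, cases, schema = names(raw), priority = priority)
}

`%||%` <- function(a, b) if (length(a) == 0 || is.null(a)) b else a

.month_map <- stats::setNames(sprintf("%02d", 1:12),
                              tolower(month.name))

#' Parse dates in mixed styles
#'
#' Accepts ISO-8601 (`2021-05-18`), verbose (`18 May 2021`, full or
#' abbreviated English month names, locale independent) and `dd/mm/yyyy`.
#'
#' @param x Character vector.
#' @return Date vector, NA where unparseable.
#' @export
parse_mixed_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_integer_, length(x)), origin = "1970-01-01")
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  verbose <- grepl("^\\d{1,2} [A-Za-z]+ \\d{4}$", x) & !iso
  if (any(verbose)) {
    parts <- strsplit(x[verbose], " ", fixed = TRUE)
    conv <- vapply(parts, function(p) {
      mon <- .month_map[tolower(p[2])]
      if (is.na(mon)) {
        hit <- which(startsWith(tolower(month.name), tolower(p[2])))
        if (length(hit) == 1) mon <- sprintf("%02d", hit)
      }
      if (is.na(mon)) return(NA_character_)
      sprintf("%s-%s-%02d", p[3], mon, as.integer(p[1]))
    }, character(1))
    out[verbose] <- as.Date(conv, format = "%Y-%m-%d")
  }
  slash <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[slash] <- as.Date(x[slash], format = "%d/%m/%Y")
  out
}

#' Write an event log back to delimited text
#'
#' Emits the same dialect [read_log()] consumes, so read-write-read
#' round-trips are identity on traces, event order and metadata. Output is
#' deterministic (storage order, ISO dates).
#'
#' @param log An `eventlog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(log, path) {
  ev <- log$events
  meta_cols <- intersect(.metadata_columns, names(log$cases))
  out <- tibble::tibble(
    `Patient ID` = ev$case_id,
    Date = format(ev$timestamp, "%Y-%m-%d"),
    Episode = ev$activity,
    Type = ev$detail,
    Value = ifelse(is.na(ev$value), "", format_num(ev$value))
  )
  if (length(meta_cols)) {
    meta <- log$cases[match(ev$case_id, log$cases$case_id), meta_cols,
                      drop = FALSE]
    out <- dplyr::bind_cols(out, meta)
  }
  extra <- setdiff(names(ev), c("case_id", "timestamp", "end_timestamp",
                                "activity", "detail", "value"))
  for (col in extra) out[[col]] <- ev[[col]]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Metadata fields available on a log
#' @param log An `eventlog`.
#' @return Character vector of metadata column names (excluding `case_id`).
#' @export
metadata_fields <- function(log) setdiff(names(log$cases), "case_id")
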