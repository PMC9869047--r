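#' Descriptive statistics for a model element
#'
#' The node/transition information block: execution and trace counts plus
#' duration statistics (days) over all executions of the selected node or
#' transition. `duration_by_trace` is the total execution time divided by the
#' number of traces traversing the element. Variance is the population
#' variance by default (the block describes the observed executions, not an
#' estimate); set `variance = "sample"` for the n-1 denominator. An element
#' with zero executions yields an all-zero block.
#'
#' @param model A `workflow_model`.
#' @param element Node label (length-1 character) or arc (length-2
#'   `c(from, to)`).
#' @param variance `"population"` (default) or `"sample"`.
#' @return A `stat_block`: named list with `execution_number`,
#'   `trace_number`, `duration_average`, `duration_median`,
#'   `duration_by_trace`, `duration_max`, `duration_min`,
#'   `duration_variance`, `duration_stddev`, `duration_summation`.
#' @examples
#' log <- simulate_care_log(n_patients = 30, seed = 5)
#' model <- discover_workflow(log)
#' element_statistics(model, "Diagnosis")
#' @export
element_statistics <- function(model, element,
                               variance = c("population", "sample")) {
  variance <- match.arg(variance)
  durs <- element_durations(model, element)
  n <- length(durs$sojourn)
  if (n == 0) {
    block <- as.list(stats::setNames(rep(0, 10), .stat_fields))
    return(structure(block, class = "stat_block"))
  }
  x <- durs$sojourn
  n_tr <- length(unique(durs$case_id))
  varv <- if (variance == "population") mean((x - mean(x))^2) else
    stats::var(x) %||% 0
  if (is.na(varv)) varv <- 0
  block <- list(
    execution_number = n,
    trace_number = n_tr,
    duration_average = mean(x),
    duration_median = stats::median(x),
    duration_by_trace = sum(x) / n_tr,
    duration_max = max(x),
    duration_min = min(x),
    duration_variance = varv,
    duration_stddev = sqrt(varv),
    duration_summation = sum(x)
  )
  structure(block, class = "stat_block")
}

.stat_fields <- c("execution_number", "trace_number", "duration_average",
                  "duration_median", "duration_by_trace", "duration_max",
                  "duration_min", "duration_variance", "duration_stddev",
                  "duration_summation")

#' @export
print.stat_block <- function(x, ...) {
  vals <- unlist(x)
  cat(paste(sprintf("%-20s %g", names(vals), vals), collapse = "\n"), "\n")
  invisible(x)
}

element_durations <- function(model, element) {
  element <- as.character(element)
  if (length(element) == 1) {
    known <- unique(model$node_exec$label)
    if (!element %in% known) {
      stop("unknown node '", element, "'; available: ",
           paste(sort(known), collapse = ", "))
    }
    sel <- model$node_exec$label == element
    list(sojourn = model$node_exec$sojourn[sel],
         case_id = model$node_exec$case_id[sel],
         full = model$node_exec$sojourn[sel])
  } else if (length(element) == 2) {
    arcs <- model$arc_exec
    sel <- arcs$from == element[1] & arcs$to == element[2]
    if (!any(sel)) {
      known <- unique(paste(arcs$from, "->", arcs$to))
      stop("unknown arc '", paste(element, collapse = " -> "),
           "'; available: ", paste(sort(known), collapse = ", "))
    }
    list(sojourn = arcs$sojourn[sel], case_id = arcs$case_id[sel],
         full = as.numeric(arcs$target_start[sel] - arcs$source_start[sel]))
  } else {
    stop("element must be a node label or a c(from, to) arc")
  }
}

#' Duration histogram with Gaussian overlay
#'
#' Equal-width bins spanning the observed duration range of a node or
#' transition, with a normal curve fitted by the sample mean and standard
#' deviation, scaled by `n * bin_width` so it overlays the count histogram.
#' Degenerate all-equal durations produce a single occupied bin and the
#' overlay is suppressed.
#'
#' @param model A `workflow_model`.
#' @param element Node label or `c(from, to)` arc.
#' @param bins Number of equal-width bins (>= 1).
#' @return A `duration_histogram`: list with `edges`, `counts`, `mean`,
#'   `sd`, `scale` (overlay factor, NA when suppressed), `durations`.
#' @export
duration_histogram <- function(model, element, bins = 10) {
  stopifnot(bins >= 1)
  x <- element_durations(model, element)$sojourn
  if (!length(x)) stop("element has no executions")
  lo <- min(x); hi <- max(x)
  if (lo == hi) {
    out <- list(edges = c(lo - 0.5, lo + 0.5), counts = length(x),
                mean = lo, sd = 0, scale = NA_real_, durations = x)
    return(structure(out, class = "duration_histogram"))
  }
  edges <- seq(lo, hi, length.out = bins + 1)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  s <- stats::sd(x)
  out <- list(edges = edges, counts = counts, mean = mean(x), sd = s,
              scale = if (s > 0) length(x) * diff(edges)[1] else NA_real_,
              durations = x)
  structure(out, class = "duration_histogram")
}

#' Plot a duration histogram
#'
#' @param x A `duration_histogram`.
#' @param ... Unused.
#' @return A ggplot object: count histogram with the scaled Gaussian overlay
#'   when the fit is defined.
#' @export
plot.duration_histogram <- function(x, ...) {
  df <- data.frame(
    mid = (x$edges[-1] + x$edges[-length(x$edges)]) / 2,
    count = x$counts,
    width = diff(x$edges)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = df$width, fill = "steelblue",
                      colour = "grey30") +
    ggplot2::labs(x = "duration (days)", y = "executions")
  if (!is.na(x$scale) && x$sd > 0) {
    gauss <- data.frame(xx = seq(min(x$edges), max(x$edges), length.out = 200))
    gauss$yy <- x$scale * stats::dnorm(gauss$xx, x$mean, x$sd)
    p <- p + ggplot2::geom_line(
      data = gauss, ggplot2::aes(x = .data$xx, y = .data$yy),
      colour = "firebrick", linewidth = 0.8
    )
  }
  p
}

#' Cohort breakdown table
#'
#' Aggregates a categorical field into counts and percentages (half-up
#' rounding to one decimal, the printed style of cohort tables), sorted by
#' count descending then label.
#'
#' @param x Either a named numeric vector / 1-column table of counts, or an
#'   [eventlog()] (then `field` selects the metadata column).
#' @param field Metadata field name when `x` is an eventlog.
#' @return A `breakdown_table`: tibble `category`, `count`, `percent`, plus
#'   attribute `total`.
#' @examples
#' metadata_breakdown(c(Female = 41, Male = 15, `Not specified` = 1))
#' @export
metadata_breakdown <- function(x, field = NULL) {
  if (inherits(x, "eventlog")) {
    stopifnot(!is.null(field))
    values <- as.character(x$cases[[field]])
    values[is.na(values) | values == ""] <- "unknown"
    counts <- table(values)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  } else {
    counts <- stats::setNames(as.numeric(x), names(x))
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stop("total count is zero")
  tbl <- tibble::tibble(
    category = names(counts),
    count = unname(counts),
    percent = unname(round_half_up(100 * counts / total, 1))
  )
  tbl <- tbl[order(-tbl$count, tbl$category), , drop = FALSE]
  structure(tbl, total = total, class = c("breakdown_table", class(tbl)))
}

#' Half-up decimal rounding
#'
#' Rounds away from the banker's rule: 0.05 at the last kept digit always
#' rounds up, matching printed percentage tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
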