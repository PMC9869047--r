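#' Colour palette registry for model enhancement
#'
#' Nine frozen palettes: heat palettes carry three gradient colour stops,
#' difference palettes carry four colours — three for the gradient plus a
#' dedicated colour for elements absent from one of the compared models.
#' Five of the nine are designed for colour-blind users: their gradient
#' stops are monotone in luminance with a minimum adjacent-stop luminance
#' separation of 40 (0-255 scale, Rec. 709 weights), so the gradient stays
#' readable without hue discrimination.
#'
#' @return List of `palette` objects; each has `id`, `kind` (`"heat"` or
#'   `"difference"`), `stops` (matrix of RGB rows; for difference palettes
#'   the last row is the absent-element colour), `colorblind_safe`.
#' @examples
#' length(palette_registry())
#' sum(vapply(palette_registry(), function(p) p$colorblind_safe, logical(1)))
#' @export
palette_registry <- function() {
  pal <- function(id, kind, hexes, cb) {
    stops <- t(vapply(hexes, hex_to_rgb, numeric(3)))
    rownames(stops) <- NULL
    structure(list(id = id, kind = kind, stops = stops,
                   colorblind_safe = cb), class = "palette")
  }
  list(
    # classic green-to-red heat: low green, high red
    pal("heat_traffic", "heat", c("#1A9850", "#FEE08B", "#D73027"), FALSE),
    # blue-to-orange heat of the main-process view
    pal("heat_thermal", "heat", c("#2166AC", "#F7F7F7", "#E66101"), FALSE),
    # luminance-monotone colour-blind heat palettes
    pal("heat_viridis", "heat", c("#440154", "#21918C", "#FDE725"), TRUE),
    pal("heat_cividis", "heat", c("#00204D", "#7B7B78", "#FFEA46"), TRUE),
    pal("heat_blues", "heat", c("#F7FBFF", "#6BAED6", "#08306B"), TRUE),
    # difference palettes: near-zero white, large delta saturated; 4th
    # colour marks elements absent from one model
    pal("diff_purple", "difference",
        c("#F7F7F7", "#A6DBA0", "#762A83", "#BEBEBE"), FALSE),
    pal("diff_ember", "difference",
        c("#FFFFFF", "#FDAE61", "#A50026", "#4575B4"), FALSE),
    pal("diff_teal", "difference",
        c("#F7F7F7", "#5AB4AC", "#01665E", "#D8B365"), TRUE),
    pal("diff_amber", "difference",
        c("#F7F7F7", "#FDB863", "#B35806", "#8073AC"), TRUE)
  )
}

#' Look up one palette by id
#' @param palette_id Palette identifier (see [palette_registry()]).
#' @return A `palette` object.
#' @export
get_palette <- function(palette_id) {
  reg <- palette_registry()
  ids <- vapply(reg, function(p) p$id, character(1))
  hit <- match(palette_id, ids)
  if (is.na(hit)) {
    stop("unknown palette '", palette_id, "'; available: ",
         paste(ids, collapse = ", "))
  }
  reg[[hit]]
}

hex_to_rgb <- function(hex) as.numeric(grDevices::col2rgb(hex))

rgb_to_hex <- function(rgb) {
  grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
}

#' Relative luminance of an RGB colour
#' @param rgb Numeric RGB triple on 0-255.
#' @return Luminance on 0-255 (Rec. 709 weights).
#' @export
rgb_luminance <- function(rgb) {
  sum(c(0.2126, 0.7152, 0.0722) * rgb)
}

gradient_stops <- function(palette) {
  if (palette$kind == "difference") {
    palette$stops[-nrow(palette$stops), , drop = FALSE]
  } else {
    palette$stops
  }
}

#' Interpolate a colour along a palette gradient
#'
#' Piecewise-linear interpolation in RGB across the palette's gradient
#' stops: `t = 0` gives the first stop, `t = 1` the last gradient stop (the
#' absent-element colour of difference palettes never participates).
#'
#' @param palette A `palette` or palette id.
#' @param t Normalized value in \[0, 1\].
#' @return Integer RGB triple.
#' @examples
#' interpolate_color("heat_traffic", 0.5)
#' @export
interpolate_color <- function(palette, t) {
  if (is.character(palette)) palette <- get_palette(palette)
  if (is.na(t) || t < 0 || t > 1) stop("t must be in [0, 1]")
  stops <- gradient_stops(palette)
  k <- nrow(stops)
  pos <- t * (k - 1)
  lo <- min(floor(pos) + 1, k - 1)
  frac <- pos - (lo - 1)
  round(stops[lo, ] * (1 - frac) + stops[lo + 1, ] * frac)
}

# ---- enhancement criteria -------------------------------------------------

.node_criteria <- c("execution_number", "trace_number", "duration_summation",
                    "duration_by_trace", "duration_fraction_of_trace",
                    "duration_average", "duration_median")
.arc_criteria <- c("execution_number", "trace_number", "duration_summation",
                   "duration_by_trace", "duration_average", "duration_median",
                   "full_duration_average", "full_duration_median")

#' Enhancement criteria identifiers
#' @param kind `"node"` or `"arc"`.
#' @return Character vector of criterion ids applicable to that kind.
#' @export
enhancement_criteria <- function(kind = c("node", "arc")) {
  kind <- match.arg(kind)
  if (kind == "node") .node_criteria else .arc_criteria
}

#' Criterion value for a model element
#'
#' Evaluates one enhancement criterion on a node or transition: counts
#' (`execution_number`, `trace_number`), sojourn-duration aggregates
#' (`duration_summation`, `duration_by_trace`, `duration_average`,
#' `duration_median` — for arcs, durations are the time spent in the source
#' node), the node-only `duration_fraction_of_trace` (time in the node
#' divided by the total time of the traversing traces), and the arc-only
#' `full_duration_average` / `full_duration_median` over start-of-source to
#' start-of-target gaps. Zero-execution elements give 0.
#'
#' @param model A `workflow_model`.
#' @param element Node label or `c(from, to)` arc.
#' @param criterion Criterion identifier (see [enhancement_criteria()]).
#' @return Numeric scalar.
#' @export
criterion_value <- function(model, element, criterion) {
  is_node <- length(element) == 1
  valid <- enhancement_criteria(if (is_node) "node" else "arc")
  if (!criterion %in% valid) {
    stop("criterion '", criterion, "' not applicable to ",
         if (is_node) "nodes" else "arcs")
  }
  durs <- tryCatch(element_durations(model, element), error = function(e) NULL)
  if (is.null(durs) || !length(durs$sojourn)) return(0)
  x <- durs$sojourn
  n_tr <- length(unique(durs$case_id))
  switch(
    criterion,
    execution_number = length(x),
    trace_number = n_tr,
    duration_summation = sum(x),
    duration_by_trace = sum(x) / n_tr,
    duration_average = mean(x),
    duration_median = stats::median(x),
    duration_fraction_of_trace = {
      tot <- trace_total_times(model)
      denom <- sum(tot[unique(durs$case_id)])
      if (denom > 0) sum(x) / denom else 0
    },
    full_duration_average = mean(durs$full),
    full_duration_median = stats::median(durs$full)
  )
}

trace_total_times <- function(model) {
  ne <- model$node_exec
  starts <- ne[ne$label == "@Start", , drop = FALSE]
  ends <- ne[ne$label == "@End", , drop = FALSE]
  tot <- as.numeric(ends$start[match(starts$case_id, ends$case_id)] -
                    starts$start)
  stats::setNames(tot, starts$case_id)
}

#' Build a heat-map enhancement layer
#'
#' Computes a criterion per node and per arc, normalizes per element kind
#' with low/high clamping, and maps through a heat palette. The clamp points
#' are percentages of the maximum criterion value of that kind: with the
#' default 20/80, elements at or below 20% of the maximum take the first
#' stop colour, elements at or above 80% take the last, and values in
#' between interpolate linearly. Artificial `@Start`/`@End` are coloured but
#' excluded from the normalization extremes.
#'
#' @param model A `workflow_model`.
#' @param node_criterion,arc_criterion Criterion ids.
#' @param palette_id A heat palette id.
#' @param low_pct,high_pct Clamp percentages, `0 <= low < high <= 100`.
#' @param include_artificial Let `@Start`/`@End` participate in the
#'   normalization maximum (default FALSE).
#' @return An `enhancement_map`: list with `nodes` and `arcs` tibbles
#'   (`raw`, `normalized`, `color` hex) plus the settings.
#' @examples
#' log <- simulate_care_log(n_patients = 30, seed = 6)
#' model <- discover_workflow(log)
#' enh <- build_enhancement(model, "duration_median", "execution_number",
#'                          "heat_traffic")
#' enh$nodes
#' @export
build_enhancement <- function(model, node_criterion = "duration_median",
                              arc_criterion = "execution_number",
                              palette_id = "heat_traffic",
                              low_pct = 20, high_pct = 80,
                              include_artificial = FALSE) {
  palette <- get_palette(palette_id)
  if (palette$kind != "heat") {
    stop("palette kind mismatch: '", palette$id, "' is a ", palette$kind,
         " palette; a heat palette is required")
  }
  stopifnot(low_pct >= 0, high_pct <= 100, low_pct < high_pct)

  nodes <- model_nodes(model)
  nodes_raw <- vapply(nodes$label, function(l)
    criterion_value(model, l, node_criterion), numeric(1))
  arcs <- model_arcs(model)
  arcs_raw <- mapply(function(f, t)
    criterion_value(model, c(f, t), arc_criterion), arcs$from, arcs$to)

  colour_kind <- function(labels, raw, artificial) {
    anchor <- if (include_artificial) raw else raw[!artificial]
    maxv <- if (length(anchor)) max(anchor) else 0
    lo <- low_pct / 100 * maxv
    hi <- high_pct / 100 * maxv
    normalized <- if (hi > lo) pmin(pmax((raw - lo) / (hi - lo), 0), 1)
      else rep(0, length(raw))
    color <- vapply(normalized, function(t)
      rgb_to_hex(interpolate_color(palette, t)), character(1))
    tibble::tibble(raw = unname(raw), normalized = unname(normalized),
                   color = color)
  }
  node_tbl <- dplyr::bind_cols(nodes["label"],
                               colour_kind(nodes$label, nodes_raw,
                                           is_artificial(nodes$label)))
  arc_tbl <- dplyr::bind_cols(
    arcs[c("from", "to")],
    colour_kind(paste(arcs$from, arcs$to),
                arcs_raw,
                is_artificial(arcs$from) | is_artificial(arcs$to))
  )
  structure(
    list(nodes = node_tbl, arcs = arc_tbl,
         node_criterion = node_criterion, arc_criterion = arc_criterion,
         palette_id = palette_id, low_pct = low_pct, high_pct = high_pct),
    class = "enhancement_map"
  )
}

#' @export
print.enhancement_map <- function(x, ...) {
  cat(sprintf("<enhancement_map: palette %s, nodes by %s, arcs by %s, clamps %g/%g>\n",
              x$palette_id, x$node_criterion, x$arc_criterion,
              x$low_pct, x$high_pct))
  invisible(x)
}

#' Serialize an enhancement map to JSON
#' @param enh An `enhancement_map` or `difference_result`.
#' @param path Optional output path.
#' @return JSON string or `path` invisibly.
#' @export
enhancement_to_json <- function(enh, path = NULL) {
  json <- jsonlite::toJSON(unclass(enh), dataframe = "rows",
                           auto_unbox = TRUE, na = "null", digits = NA,
                           pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
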