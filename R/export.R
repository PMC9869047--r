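#' Export a workflow model as DOT
#'
#' Deterministic Graphviz DOT rendering of a process view: one node
#' statement per model node (labels escaped), one edge per arc annotated
#' with its execution count and median duration in days. An optional
#' overlay supplies fill colours ([build_enhancement()] heat layer or
#' [difference_map()] colours, with absent elements in the palette's fourth
#' colour); nodes flagged significant by the overlay's verdicts get a
#' yellow border. Elements are emitted sorted, so the same model always
#' produces byte-identical text.
#'
#' @param model A `workflow_model`.
#' @param overlay Optional `enhancement_map` or `difference_result` built
#'   from this model.
#' @param min_arc_count Hide arcs with fewer executions (display filter
#'   only; default 0 shows everything).
#' @param path Optional output file.
#' @return DOT text (character scalar), or `path` invisibly.
#' @export
export_dot <- function(model, overlay = NULL, min_arc_count = 0,
                       path = NULL) {
  nodes <- model_nodes(model)
  arcs <- model_arcs(model)
  arcs$median <- mapply(function(f, t) {
    sel <- model$arc_exec$from == f & model$arc_exec$to == t
    stats::median(model$arc_exec$sojourn[sel])
  }, arcs$from, arcs$to)
  arcs <- arcs[arcs$executions >= min_arc_count, , drop = FALSE]

  fill <- stats::setNames(rep("#FFFFFF", nrow(nodes)), nodes$label)
  arc_color <- NULL
  significant <- character()
  if (!is.null(overlay)) {
    if (inherits(overlay, "enhancement_map")) {
      ov_nodes <- overlay$nodes
      ov_arcs <- overlay$arcs
    } else if (inherits(overlay, "difference_result")) {
      ov_nodes <- overlay$nodes
      ov_arcs <- overlay$arcs
      significant <- overlay$significant
    } else {
      stop("overlay must be an enhancement_map or difference_result")
    }
    if (!all(nodes$label %in% ov_nodes$label)) {
      stop("overlay does not reference this model")
    }
    fill[ov_nodes$label] <- ov_nodes$color
    arc_color <- stats::setNames(
      ov_arcs$color, paste(ov_arcs$from, ov_arcs$to, sep = "\r"))
  }

  esc <- function(s) gsub('"', '\\\\"', s)
  node_lines <- vapply(seq_len(nrow(nodes)), function(i) {
    l <- nodes$label[i]
    border <- if (l %in% significant) ', color="#FFD700", penwidth=3' else ""
    sprintf('  "%s" [label="%s\\n%d", style=filled, fillcolor="%s"%s];',
            esc(l), esc(l), nodes$executions[i], fill[[l]], border)
  }, character(1))
  edge_lines <- vapply(seq_len(nrow(arcs)), function(i) {
    key <- paste(arcs$from[i], arcs$to[i], sep = "\r")
    col <- if (!is.null(arc_color) && key %in% names(arc_color)) {
      sprintf(', color="%s"', arc_color[[key]])
    } else ""
    sprintf('  "%s" -> "%s" [label="%d (md %g d)"%s];',
            esc(arcs$from[i]), esc(arcs$to[i]), arcs$executions[i],
            arcs$median[i], col)
  }, character(1))
  txt <- paste(c("digraph workflow {", "  rankdir=LR;", node_lines,
                 edge_lines, "}"), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Export a workflow model as GraphML
#'
#' Interchange format toward generic graph tools: nodes carry execution and
#' trace counts, edges carry execution counts, written via igraph.
#'
#' @param model A `workflow_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(model, path) {
  nodes <- model_nodes(model)
  arcs <- model_arcs(model)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = arcs$from, to = arcs$to,
                   executions = arcs$executions),
    vertices = data.frame(name = nodes$label,
                          executions = nodes$executions,
                          traces = nodes$traces)
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

# minimal structural check of emitted JSON artifacts against the shipped
# schema descriptors (inst/schemas): required top-level keys must be present
check_artifact <- function(path, schema_name) {
  schema_path <- system.file("schemas", paste0(schema_name, ".json"),
                             package = "careflowr")
  schema <- jsonlite::fromJSON(schema_path)
  obj <- jsonlite::fromJSON(path)
  missing <- setdiff(schema$required, names(obj))
  if (length(missing)) {
    stop("artifact ", path, " is missing required key(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
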