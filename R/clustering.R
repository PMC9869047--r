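#' Quality-threshold clustering of traces
#'
#' Classic quality-threshold procedure over a trace-distance matrix: every
#' remaining trace seeds a candidate cluster that grows greedily, at each
#' step adding the trace that minimizes the resulting diameter (maximum
#' pairwise distance within the cluster) while the diameter stays within the
#' quality threshold `q`; the largest candidate is committed (ties broken by
#' the smallest seed index), its members removed, and the procedure repeats
#' until no candidate reaches `min_size`. Leftover traces are reported
#' unassigned rather than forced into clusters. Every greedy tie is broken
#' by the smallest trace index, so runs are reproducible without randomness.
#'
#' @param log An [eventlog()] with at least one trace.
#' @param q Quality threshold in (0, 1]: maximum allowed within-cluster
#'   pairwise distance.
#' @param distance_id Distance id or function (see [get_distance()]).
#' @param min_size Smallest committed cluster (default 2).
#' @return A `cluster_set`: list with `clusters` (list of case-id character
#'   vectors, ordered by size descending), `unassigned`, `q`, `distance_id`,
#'   `min_size`, and `models` (one discovered `workflow_model` per cluster).
#' @examples
#' log <- simulate_care_log(n_patients = 30, seed = 8)
#' cs <- qt_cluster(log, q = 0.3, distance_id = "levenshtein")
#' lengths(cs$clusters)
#' @export
qt_cluster <- function(log, q, distance_id = "levenshtein", min_size = 2) {
  if (!is.numeric(q) || q <= 0) stop("q must be a positive threshold")
  if (n_traces(log) < 1) stop("log has no traces")
  d <- distance_matrix(log, distance_id)
  ids <- rownames(d)
  remaining <- seq_along(ids)
  clusters <- list()

  grow_candidate <- function(seed, remaining) {
    members <- seed
    diameter <- 0
    pool <- setdiff(remaining, seed)
    # max distance from each pool trace to the current members
    to_members <- d[pool, seed, drop = FALSE]
    max_to <- if (length(pool)) apply(to_members, 1, max) else numeric(0)
    while (length(pool)) {
      new_diam <- pmax(diameter, max_to)
      best <- min(new_diam)
      if (best > q) break
      pick_i <- which(new_diam == best)[1]  # pool is index-ordered: smallest wins
      pick <- pool[pick_i]
      members <- c(members, pick)
      diameter <- best
      pool <- pool[-pick_i]
      max_to <- max_to[-pick_i]
      if (length(pool)) {
        max_to <- pmax(max_to, d[pool, pick])
      }
    }
    members
  }

  repeat {
    if (!length(remaining)) break
    candidates <- lapply(remaining, grow_candidate, remaining = remaining)
    sizes <- lengths(candidates)
    if (max(sizes) < min_size) break
    commit <- candidates[[which.max(sizes)]]  # which.max: smallest seed wins ties
    clusters[[length(clusters) + 1]] <- sort(commit)
    remaining <- setdiff(remaining, commit)
  }

  clusters <- clusters[order(-lengths(clusters), seq_along(clusters))]
  cluster_ids <- lapply(clusters, function(ix) ids[ix])
  cs <- structure(
    list(clusters = cluster_ids, unassigned = ids[remaining],
         q = q,
         distance_id = if (is.function(distance_id)) "custom" else distance_id,
         min_size = min_size),
    class = "cluster_set"
  )
  cs$models <- cluster_models(cs, log)
  cs
}

#' Discover one workflow model per cluster
#' @param cs A `cluster_set`.
#' @param log The [eventlog()] the clustering was run on.
#' @return List of `workflow_model`s, one per cluster, in cluster order.
#' @export
cluster_models <- function(cs, log) {
  lapply(cs$clusters, function(ids) discover_workflow(subset_log(log, ids)))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d cluster(s) (sizes %s), %d unassigned, q = %g, %s>\n",
              length(x$clusters),
              paste(lengths(x$clusters), collapse = ", "),
              length(x$unassigned), x$q, x$distance_id))
  invisible(x)
}

#' Serialize a cluster set to JSON
#' @param cs A `cluster_set`.
#' @param path Optional output path.
#' @return JSON string or `path` invisibly.
#' @export
clusters_to_json <- function(cs, path = NULL) {
  obj <- list(q = cs$q, distance = cs$distance_id, min_size = cs$min_size,
              clusters = cs$clusters, unassigned = cs$unassigned)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
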