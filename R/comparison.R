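#' Two-sample Mann-Whitney U test
#'
#' Rank-sum test used for per-node significance between cohorts. For small
#' samples (both sizes <= 8 by default) the exact null distribution of U is
#' obtained by full enumeration of all group assignments of the pooled
#' values, which handles ties without approximation; otherwise a
#' tie-corrected normal approximation (no continuity correction) is used.
#' The two-sided p-value is `min(1, 2 * min(P(U <= u), P(U >= u)))`, so two
#' fully tied (exchangeable) samples give p = 1.
#'
#' @param x,y Numeric samples.
#' @param exact Force exact enumeration (TRUE), approximation (FALSE), or
#'   decide by sample size (NULL, the default).
#' @param exact_max Largest per-group size for the automatic exact mode.
#' @return List with `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, method = "undefined"))
  }
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- if (is.null(exact)) (n1 <= exact_max && n2 <= exact_max) else exact
  if (use_exact) {
    combos <- utils::combn(n1 + n2, n1)
    rank_mat <- matrix(r[combos], nrow = n1)
    u_all <- colSums(rank_mat) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
    list(statistic = u_obs, p_value = p, method = "exact enumeration")
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      return(list(statistic = u_obs, p_value = 1,
                  method = "normal approximation (tie-corrected)"))
    }
    z <- (u_obs - n1 * n2 / 2) / sqrt(sigma2)
    list(statistic = u_obs, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation (tie-corrected)")
  }
}

#' Per-node significance between two workflow models
#'
#' Tests whether a node behaves differently in two cohorts. The default
#' `duration` test compares the two sojourn-duration samples with a
#' two-sided Mann-Whitney U test ([mann_whitney_u()]); the `frequency` test
#' compares the fractions of traces traversing the node with a two-proportion
#' z-test. The node is flagged significant when p < alpha.
#'
#' @param reference,other `workflow_model`s sharing the node.
#' @param node Node label, present in both models.
#' @param alpha Significance threshold (default 0.05).
#' @param test `"duration"` (default) or `"frequency"`.
#' @return A `significance_verdict`: list with `node`, `test`, `p_value`,
#'   `alpha`, `significant`, `n_ref`, `n_other`, `method`.
#' @export
node_significance <- function(reference, other, node, alpha = 0.05,
                              test = c("duration", "frequency")) {
  test <- match.arg(test)
  for (m in list(reference, other)) {
    if (!node %in% m$node_exec$label) {
      stop("node '", node, "' absent from one model; ",
           "absence is a difference-map concern, not a test")
    }
  }
  if (test == "duration") {
    x <- reference$node_exec$sojourn[reference$node_exec$label == node]
    y <- other$node_exec$sojourn[other$node_exec$label == node]
    res <- mann_whitney_u(x, y)
    n_ref <- length(x); n_other <- length(y)
    p <- res$p_value
    method <- paste("Mann-Whitney U,", res$method)
  } else {
    k1 <- length(unique(reference$node_exec$case_id[
      reference$node_exec$label == node]))
    k2 <- length(unique(other$node_exec$case_id[
      other$node_exec$label == node]))
    n_ref <- reference$n_traces; n_other <- other$n_traces
    p_pool <- (k1 + k2) / (n_ref + n_other)
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n_ref + 1 / n_other))
    p <- if (se > 0) {
      z <- (k1 / n_ref - k2 / n_other) / se
      min(1, 2 * stats::pnorm(-abs(z)))
    } else 1
    method <- "two-proportion z-test"
  }
  structure(
    list(node = node, test = test, p_value = p, alpha = alpha,
         significant = !is.na(p) && p < alpha,
         n_ref = n_ref, n_other = n_other, method = method),
    class = "significance_verdict"
  )
}

#' Significance verdicts over all shared nodes
#'
#' Runs [node_significance()] on every non-artificial node present in both
#' models and returns all verdicts plus the significant subset. No
#' multiple-testing correction is applied by default (the plain per-node
#' 0.05 threshold); set `adjust = "BH"` for Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param reference,other `workflow_model`s.
#' @param alpha Significance threshold.
#' @param test Passed to [node_significance()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `verdicts` (tibble), `significant` (character labels).
#' @export
significant_nodes <- function(reference, other, alpha = 0.05,
                              test = "duration", adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  shared <- intersect(model_activities(reference), model_activities(other))
  if (!length(shared)) {
    warning("models share no non-artificial nodes")
    return(list(verdicts = tibble::tibble(
      node = character(), test = character(), p_value = numeric(),
      alpha = numeric(), significant = logical(),
      n_ref = integer(), n_other = integer()
    ), significant = character()))
  }
  verdicts <- lapply(sort(shared), function(nd)
    node_significance(reference, other, nd, alpha = alpha, test = test))
  tbl <- dplyr::bind_rows(lapply(verdicts, function(v)
    tibble::tibble(node = v$node, test = v$test, p_value = v$p_value,
                   alpha = v$alpha, significant = v$significant,
                   n_ref = v$n_ref, n_other = v$n_other)))
  if (adjust == "BH") {
    tbl$p_value <- stats::p.adjust(tbl$p_value, method = "BH")
    tbl$significant <- !is.na(tbl$p_value) & tbl$p_value < alpha
  }
  list(verdicts = tbl, significant = tbl$node[tbl$significant])
}

#' Difference map between two workflow models
#'
#' Element-wise comparison of two process views: for every node and arc
#' present in both models the absolute criterion delta is computed,
#' normalized by the maximum delta of that element kind and mapped across
#' the palette's three gradient stops (near-zero differences take the first
#' stop); elements present in exactly one model are flagged absent and take
#' the palette's dedicated fourth colour. Per-node Mann-Whitney significance
#' verdicts over shared non-artificial nodes are attached.
#'
#' @param reference,other `workflow_model`s.
#' @param criterion Criterion id applied to both kinds (counts and shared
#'   duration criteria; default `execution_number`).
#' @param palette_id A difference palette id.
#' @param alpha Significance threshold for the attached verdicts.
#' @param significance Attach per-node verdicts (default TRUE).
#' @return A `difference_result`: list with `nodes` and `arcs` tibbles
#'   (`value_ref`, `value_other`, `delta`, `normalized`, `absent_in`,
#'   `color`), `verdicts`, `significant`, and the settings.
#' @examples
#' log <- simulate_care_log(n_patients = 40, seed = 7)
#' groups <- group_by_metadata(log, "Grade")
#' @export
difference_map <- function(reference, other, criterion = "execution_number",
                           palette_id = "diff_purple", alpha = 0.05,
                           significance = TRUE) {
  palette <- get_palette(palette_id)
  if (palette$kind != "difference") {
    stop("palette kind mismatch: '", palette$id, "' is a ", palette$kind,
         " palette; a difference palette is required")
  }
  absent_color <- rgb_to_hex(palette$stops[nrow(palette$stops), ])

  compare_kind <- function(keys_ref, keys_other, value_fn) {
    all_keys <- sort(union(keys_ref, keys_other))
    v_ref <- vapply(all_keys, function(k)
      if (k %in% keys_ref) value_fn(reference, k) else NA_real_, numeric(1))
    v_oth <- vapply(all_keys, function(k)
      if (k %in% keys_other) value_fn(other, k) else NA_real_, numeric(1))
    v_ref <- unname(v_ref); v_oth <- unname(v_oth)
    absent <- ifelse(is.na(v_ref), "ref", ifelse(is.na(v_oth), "other", "none"))
    delta <- ifelse(absent == "none", abs(v_oth - v_ref), NA_real_)
    maxd <- suppressWarnings(max(delta, na.rm = TRUE))
    if (!is.finite(maxd) || maxd == 0) maxd <- NA_real_
    normalized <- ifelse(is.na(delta), NA_real_,
                         if (is.na(maxd)) 0 else delta / maxd)
    color <- vapply(seq_along(all_keys), function(i) {
      if (absent[i] != "none") absent_color
      else rgb_to_hex(interpolate_color(palette, normalized[i]))
    }, character(1))
    tibble::tibble(key = all_keys, value_ref = unname(v_ref),
                   value_other = unname(v_oth), delta = unname(delta),
                   normalized = unname(normalized),
                   absent_in = absent, color = color)
  }

  node_keys_ref <- model_nodes(reference)$label
  node_keys_other <- model_nodes(other)$label
  nodes <- compare_kind(node_keys_ref, node_keys_other,
                        function(m, k) criterion_value(m, k, criterion))
  names(nodes)[1] <- "label"

  arc_key <- function(m) {
    a <- model_arcs(m)
    paste(a$from, a$to, sep = "\r")
  }
  arcs <- compare_kind(arc_key(reference), arc_key(other), function(m, k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    criterion_value(m, parts, criterion)
  })
  parts <- strsplit(arcs$key, "\r", fixed = TRUE)
  arcs$from <- vapply(parts, `[`, character(1), 1)
  arcs$to <- vapply(parts, `[`, character(1), 2)
  arcs$key <- NULL
  arcs <- arcs[, c("from", "to", setdiff(names(arcs), c("from", "to")))]

  sig <- if (significance) significant_nodes(reference, other, alpha = alpha)
    else list(verdicts = NULL, significant = character())
  structure(
    list(nodes = nodes, arcs = arcs, criterion = criterion,
         palette_id = palette_id, alpha = alpha,
         verdicts = sig$verdicts, significant = sig$significant),
    class = "difference_result"
  )
}

#' @export
print.difference_result <- function(x, ...) {
  cat(sprintf(
    "<difference_result: criterion %s, %d node(s), %d arc(s), %d significant node(s)>\n",
    x$criterion, nrow(x$nodes), nrow(x$arcs), length(x$significant)))
  invisible(x)
}
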