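#' Trace distances
#'
#' Three normalized trace distances drive the quality-threshold clustering;
#' each maps a pair of traces (activity-label sequences) into \[0, 1\], is
#' symmetric and is zero on identical sequences.
#'
#' \describe{
#'   \item{levenshtein}{unit-cost edit distance (insert, delete, substitute)
#'     between the label sequences, divided by the longer length.}
#'   \item{topological}{1 minus the Jaccard similarity of the
#'     directly-follows arc sets of the two single-trace workflow models,
#'     artificial `@Start`/`@End` arcs included, so it compares process
#'     structure rather than alignment.}
#'   \item{heuristic}{arithmetic mean of the activity-multiset Jaccard
#'     distance (content) and the normalized Levenshtein distance (order).}
#' }
#'
#' @param a,b Character vectors of activity labels (non-empty).
#' @return Numeric distance in \[0, 1\].
#' @name trace-distances
NULL

#' @rdname trace-distances
#' @examples
#' levenshtein_distance(c("A", "B", "C"), c("A", "C"))
#' @export
levenshtein_distance <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  alphabet <- unique(c(a, b))
  chars <- intToUtf8(seq(161, by = 1, length.out = length(alphabet)),
                     multiple = TRUE)
  encode <- function(s) paste(chars[match(s, alphabet)], collapse = "")
  d <- utils::adist(encode(a), encode(b))[1, 1]
  d / max(length(a), length(b))
}

#' @rdname trace-distances
#' @export
topological_distance <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  arcs_of <- function(s) {
    chain <- c("@Start", s, "@End")
    unique(paste(chain[-length(chain)], chain[-1], sep = "\r"))
  }
  aa <- arcs_of(a); bb <- arcs_of(b)
  1 - length(intersect(aa, bb)) / length(union(aa, bb))
}

#' @rdname trace-distances
#' @export
heuristic_distance <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  ta <- table(a); tb <- table(b)
  labs <- union(names(ta), names(tb))
  ca <- as.numeric(ta[labs]); ca[is.na(ca)] <- 0
  cb <- as.numeric(tb[labs]); cb[is.na(cb)] <- 0
  multiset_jaccard <- 1 - sum(pmin(ca, cb)) / sum(pmax(ca, cb))
  (multiset_jaccard + levenshtein_distance(a, b)) / 2
}

#' Look up a trace distance function by id
#' @param distance_id One of `"levenshtein"`, `"topological"`, `"heuristic"`,
#'   or a function `(a, b) -> [0, 1]` used as-is (pluggable distances).
#' @return A distance function.
#' @export
get_distance <- function(distance_id) {
  if (is.function(distance_id)) return(distance_id)
  switch(distance_id,
         levenshtein = levenshtein_distance,
         topological = topological_distance,
         heuristic = heuristic_distance,
         stop("unknown distance '", distance_id,
              "'; available: levenshtein, topological, heuristic"))
}

#' Pairwise trace-distance matrix of a log
#' @param log An [eventlog()].
#' @param distance_id Distance id or function (see [get_distance()]).
#' @return Symmetric numeric matrix with case ids as dimnames.
#' @export
distance_matrix <- function(log, distance_id = "levenshtein") {
  f <- get_distance(distance_id)
  seqs <- trace_sequences(log)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d[i, j] <- d[j, i] <- f(seqs[[i]], seqs[[j]])
      }
    }
  }
  d
}
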