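# Test helpers: fixture builders and independent oracles.
# Oracles are deliberately naive (loops, full enumeration) and share no code
# with the implementation paths they check.

# build an eventlog from a list of activity sequences; events are spaced by
# `gaps` days (recycled) starting at `origin`
make_log <- function(seqs, gaps = 7, origin = as.Date("2020-01-01"),
                     meta = NULL) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("c%02d", seq_along(seqs))
  rows <- lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    g <- rep_len(gaps, max(length(s) - 1, 0))
    data.frame(case_id = id,
               timestamp = origin + cumsum(c(0, g)),
               activity = s, stringsAsFactors = FALSE)
  })
  careflowr::eventlog(do.call(rbind, rows), cases = meta)
}

random_sequences <- function(n, alphabet = LETTERS[1:6], len = 2:8) {
  lapply(seq_len(n), function(i) {
    sample(alphabet, sample(len, 1), replace = TRUE)
  })
}

# brute-force consecutive-bigram counter over raw sequences (with the
# artificial endpoints), independent of discover_workflow
oracle_bigram_counts <- function(seqs) {
  counts <- new.env(parent = emptyenv())
  for (s in seqs) {
    chain <- c("@Start", s, "@End")
    for (i in seq_len(length(chain) - 1)) {
      key <- paste(chain[i], chain[i + 1], sep = "\r")
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# textbook dynamic-programming Levenshtein over label vectors
oracle_levenshtein <- function(a, b) {
  n <- length(a); m <- length(b)
  d <- matrix(0, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (a[i] == b[j]) 0 else 1
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + cost)
    }
  }
  d[n + 1, m + 1]
}

# exhaustive two-sided permutation p-value for the rank-sum test, computing
# U by direct pair counting (no ranks)
oracle_permutation_p <- function(x, y) {
  u_stat <- function(xx, yy) {
    u <- 0
    for (xi in xx) for (yi in yy) {
      u <- u + (xi > yi) + 0.5 * (xi == yi)
    }
    u
  }
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# one-pass bucketing partition oracle
oracle_partition <- function(ids, labels) {
  out <- list()
  for (i in seq_along(ids)) {
    key <- if (is.na(labels[i]) || labels[i] == "") "unknown" else labels[i]
    out[[key]] <- c(out[[key]], ids[i])
  }
  out
}

# tiny CSV fixture in the episode/cohort dialect
write_dialect_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "Patient ID,Date,Episode,Type,Value,Age,PSA Range,Grade,Tr1,TR1 detail"
  writeLines(c(header, rows), path)
  path
}
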