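## Independent oracles used by the tests. These deliberately re-derive each
## quantity by a different route (plain loops, recursion, closed forms) from
## the implementation they check.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

## count (possibly overlapping) occurrences of `pat` in `subject` by direct
## substring comparison
oracle_substring_count <- function(pat, subject) {
  w <- nchar(pat)
  n <- nchar(subject)
  if (n < w) return(0L)
  sum(vapply(seq_len(n - w + 1L), function(i) {
    substr(subject, i, i + w - 1L) == pat
  }, logical(1)))
}

## duplex scoring constants mirrored from the documented model
ORC_WC <- 5; ORC_GU <- 1; ORC_MM <- -3; ORC_OPEN <- -4; ORC_EXT <- -9

orc_pair_score <- function(qb, tb, mirna_pos) {
  wc <- (qb == "A" && tb == "T") || (qb == "T" && tb == "A") ||
    (qb == "C" && tb == "G") || (qb == "G" && tb == "C")
  gu <- (qb == "G" && tb == "T") || (qb == "T" && tb == "G")
  s <- if (wc) ORC_WC else if (gu) ORC_GU else ORC_MM
  if (mirna_pos >= 2 && mirna_pos <= 8) 2 * s else s
}

## pure exhaustive enumeration of local alignments (every start pair, every
## move sequence); exponential, for very small toys only
oracle_align_exhaustive <- function(mirna, target) {
  n <- nchar(mirna)
  w <- nchar(target)
  q <- rev(strsplit(mirna, "")[[1]])
  qpos <- n - seq_len(n) + 1L
  tv <- strsplit(target, "")[[1]]
  best <- 0
  explore <- function(qi, ti, prev, sc) {
    if (prev == "M" && sc > best) best <<- sc
    if (qi < n && ti < w) {
      explore(qi + 1L, ti + 1L, "M",
              sc + orc_pair_score(q[qi + 1L], tv[ti + 1L], qpos[qi + 1L]))
    }
    if (ti < w) {
      explore(qi, ti + 1L, "X",
              sc + ORC_EXT + if (prev != "X") ORC_OPEN else 0)
    }
    if (qi < n) {
      explore(qi + 1L, ti, "Y",
              sc + ORC_EXT + if (prev != "Y") ORC_OPEN else 0)
    }
  }
  for (i in seq_len(w)) {
    for (j in seq_len(n)) {
      explore(j, i, "M", orc_pair_score(q[j], tv[i], qpos[j]))
    }
  }
  best
}

## top-down memoised recursion (independent direction from the bottom-up DP)
oracle_align_memo <- function(mirna, target) {
  n <- nchar(mirna)
  w <- nchar(target)
  q <- rev(strsplit(mirna, "")[[1]])
  qpos <- n - seq_len(n) + 1L
  tv <- strsplit(target, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i < 1 || j < 1) return(if (state == "M") 0 else -Inf)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (state == "M") {
      s <- orc_pair_score(q[j], tv[i], qpos[j])
      s + max(0, rec(i - 1L, j - 1L, "M"), rec(i - 1L, j - 1L, "X"),
              rec(i - 1L, j - 1L, "Y"))
    } else if (state == "X") {
      max(rec(i - 1L, j, "M") + ORC_OPEN + ORC_EXT,
          rec(i - 1L, j, "X") + ORC_EXT)
    } else {
      max(rec(i, j - 1L, "M") + ORC_OPEN + ORC_EXT,
          rec(i, j - 1L, "Y") + ORC_EXT)
    }
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_len(w)) for (j in seq_len(n)) best <- max(best, rec(i, j, "M"))
  best
}

## from-definition correlation formulas (explicit sums, no cor())
oracle_pearson <- function(x, y) {
  n <- length(x)
  xm <- sum(x) / n; ym <- sum(y) / n
  sxy <- sum((x - xm) * (y - ym))
  sxy / sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

## hypergeometric upper tail by explicit PMF summation
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## brute-force ceRNA triple enumeration over all id combinations
oracle_triples <- function(circ_mir, mir_mrna, circ_mrna) {
  cs <- unique(circ_mir$circ_id); ms <- unique(mir_mrna$mirna_id)
  gs <- unique(mir_mrna$mrna_id)
  out <- list()
  for (ci in cs) for (mi in ms) for (gi in gs) {
    if (any(circ_mir$circ_id == ci & circ_mir$mirna_id == mi) &&
        any(mir_mrna$mirna_id == mi & mir_mrna$mrna_id == gi) &&
        any(circ_mrna$circ_id == ci & circ_mrna$mrna_id == gi)) {
      out[[length(out) + 1L]] <- data.frame(circ_id = ci, mirna_id = mi,
                                            mrna_id = gi)
    }
  }
  if (length(out) == 0) {
    return(data.frame(circ_id = character(), mirna_id = character(),
                      mrna_id = character()))
  }
  do.call(rbind, out)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
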