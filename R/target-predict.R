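MIRANDA_WC <- 5
MIRANDA_GU <- 1
MIRANDA_MISMATCH <- -3
MIRANDA_GAP_OPEN <- -4
MIRANDA_GAP_EXTEND <- -9
ENERGY_GC <- -3
ENERGY_AT <- -2
ENERGY_GT <- -1

#' Seed of a mature miRNA
#'
#' Positions 2-8 (1-based, 5' to 3') of the mature strand.
#'
#' @param mirna miRNA sequence (DNA alphabet, length >= 8).
#' @return 7-mer seed string.
#' @examples
#' seed_of("TGAGGTAGTAGGTTGTATAGTT")  # let-7 family: "GAGGTAG"
#' @export
seed_of <- function(mirna) {
  if (nchar(mirna) < 8) abort("miRNA must be at least 8 nt to carry a 2-8 seed")
  substr(mirna, 2, 8)
}

pair_class <- function(q, t) {
  wc <- (q == "A" & t == "T") | (q == "T" & t == "A") |
    (q == "C" & t == "G") | (q == "G" & t == "C")
  gu <- (q == "G" & t == "T") | (q == "T" & t == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "mismatch"))
}

pair_energy <- function(q, t, state) {
  dplyr::case_when(
    state == "WC" & (q %in% c("C", "G")) ~ ENERGY_GC,
    state == "WC" ~ ENERGY_AT,
    state == "GU" ~ ENERGY_GT,
    TRUE ~ 0
  )
}

#' Seed-match scan of a target sequence
#'
#' Reports every (possibly overlapping) occurrence of the reverse complement
#' of the miRNA seed in the target: a `7mer-m8` site, upgraded to `8mer` when
#' the target base facing miRNA position 1 (immediately 3' of the match on
#' the target) is A.
#'
#' @param mirna miRNA sequence (DNA alphabet).
#' @param target_seq Target sequence over ACGT.
#' @return Tibble: `position` (0-based start of the 7-mer on the target),
#'   `site_type`.
#' @export
seedmatch_scan <- function(mirna, target_seq) {
  assert_dna(target_seq, "target")
  pat <- revcomp(seed_of(mirna))
  m <- Biostrings::matchPattern(Biostrings::DNAString(pat),
                                Biostrings::DNAString(target_seq))
  if (length(m) == 0) return(tibble(position = integer(), site_type = character()))
  pos <- Biostrings::start(m) - 1L
  facing <- substr(rep(target_seq, length(pos)), pos + 8L, pos + 8L)
  tibble(position = as.integer(pos),
         site_type = ifelse(facing == "A", "8mer", "7mer-m8"))
}

#' miRNA:target duplex alignment
#'
#' Local alignment of the miRNA (reversed, so the 3' end faces the target
#' window's 5' end) against a target window under miRanda-flavoured
#' constants: Watson-Crick pair +5, G:U wobble +1, mismatch -3, gap open -4,
#' gap extend -9 per gap position; pair scores at miRNA seed positions 2-8
#' are doubled (5' weighting). The duplex energy proxy sums -3 kcal/mol per
#' G:C pair, -2 per A:U and -1 per G:U. `seed_strict` is TRUE when miRNA
#' positions 2-8 are all Watson-Crick paired with no gaps.
#'
#' @param mirna miRNA sequence (DNA alphabet).
#' @param target_window Target subsequence (bounded, default use is ~50 nt).
#' @return List: `score`, `energy`, `seed_strict`, `target_start` (0-based
#'   offset of the aligned region in the window), `pairs` tibble
#'   (`mirna_pos`, `target_pos`, `state`).
#' @export
duplex_align <- function(mirna, target_window) {
  n <- nchar(mirna); w <- nchar(target_window)
  q <- rev(strsplit(mirna, "")[[1]])           # q[j] is miRNA position n-j+1
  tv <- strsplit(target_window, "")[[1]]
  qpos <- n - seq_len(n) + 1L
  wt <- ifelse(qpos >= 2 & qpos <= 8, 2, 1)

  sub <- matrix(MIRANDA_MISMATCH, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  sub["A", "T"] <- sub["T", "A"] <- sub["C", "G"] <- sub["G", "C"] <- MIRANDA_WC
  sub["G", "T"] <- sub["T", "G"] <- MIRANDA_GU

  NEG <- -1e9
  M <- matrix(0, w + 1, n + 1)        # best local score with (i, j) aligned
  X <- matrix(NEG, w + 1, n + 1)      # gap in miRNA (target base unpaired)
  Y <- matrix(NEG, w + 1, n + 1)      # gap in target (miRNA base unpaired)
  ptrM <- matrix(0L, w + 1, n + 1)    # 0 local start, 1 from M, 2 from X, 3 from Y
  ptrX <- matrix(0L, w + 1, n + 1)    # 1 open from M, 2 extend from X
  ptrY <- matrix(0L, w + 1, n + 1)
  for (i in seq_len(w)) {
    for (j in seq_len(n)) {
      s <- sub[tv[i], q[j]] * wt[j]
      cand <- c(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      k <- which.max(cand)
      M[i + 1, j + 1] <- cand[k]
      ptrM[i + 1, j + 1] <- k - 1L
      xo <- M[i, j + 1] + MIRANDA_GAP_OPEN + MIRANDA_GAP_EXTEND
      xe <- X[i, j + 1] + MIRANDA_GAP_EXTEND
      X[i + 1, j + 1] <- max(xo, xe)
      ptrX[i + 1, j + 1] <- if (xo >= xe) 1L else 2L
      yo <- M[i + 1, j] + MIRANDA_GAP_OPEN + MIRANDA_GAP_EXTEND
      ye <- Y[i + 1, j] + MIRANDA_GAP_EXTEND
      Y[i + 1, j + 1] <- max(yo, ye)
      ptrY[i + 1, j + 1] <- if (yo >= ye) 1L else 2L
    }
  }
  best <- which(M == max(M), arr.ind = TRUE)
  best <- best[nrow(best), ]          # favour the longest/rightmost extent
  score <- max(M)

  pairs <- list()
  i <- best[1]; j <- best[2]; state <- "M"
  while (i > 1 && j > 1) {
    if (state == "M") {
      if (M[i, j] <= 0 && ptrM[i, j] == 0L) break
      pairs[[length(pairs) + 1L]] <- tibble(mirna_pos = qpos[j - 1],
                                            target_pos = i - 2L,
                                            state = pair_class(q[j - 1], tv[i - 1]))
      from <- ptrM[i, j]
      i <- i - 1L; j <- j - 1L
      if (from == 0L) break
      state <- c("M", "X", "Y")[from]
    } else if (state == "X") {
      pairs[[length(pairs) + 1L]] <- tibble(mirna_pos = NA_integer_,
                                            target_pos = i - 2L, state = "gap")
      from <- ptrX[i, j]
      i <- i - 1L
      state <- if (from == 1L) "M" else "X"
    } else {
      pairs[[length(pairs) + 1L]] <- tibble(mirna_pos = qpos[j - 1],
                                            target_pos = NA_integer_, state = "gap")
      from <- ptrY[i, j]
      j <- j - 1L
      state <- if (from == 1L) "M" else "Y"
    }
  }
  pairs <- if (length(pairs)) bind_rows(rev(pairs)) else
    tibble(mirna_pos = integer(), target_pos = integer(), state = character())

  paired <- pairs[pairs$state %in% c("WC", "GU"), , drop = FALSE]
  energy <- if (nrow(paired) == 0) 0 else {
    qb <- q[n - paired$mirna_pos + 1L]
    tb <- tv[paired$target_pos + 1L]
    sum(pair_energy(qb, tb, paired$state))
  }
  in_seed <- !is.na(pairs$mirna_pos) & pairs$mirna_pos >= 2 & pairs$mirna_pos <= 8
  seed <- pairs[in_seed, , drop = FALSE]
  seed_strict <- sum(in_seed) == 7 && all(seed$state == "WC") &&
    all(diff(sort(seed$target_pos)) == 1)
  target_start <- if (nrow(paired)) min(paired$target_pos) else NA_integer_

  list(score = score, energy = energy, seed_strict = seed_strict,
       target_start = target_start, pairs = pairs)
}

## batched seed scan: all (miRNA, target) seed-match hits; circular targets
## are scanned on the doubled sequence and positions reported < L
scan_seed_hits <- function(mirnas, targets, target_kind) {
  scan_seqs <- if (target_kind == "circ") paste0(targets$sequence, targets$sequence)
  else targets$sequence
  subj <- Biostrings::DNAStringSet(scan_seqs)
  Lk <- nchar(targets$sequence)
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    pat <- revcomp(seed_of(mirnas$sequence[i]))
    st <- Biostrings::startIndex(Biostrings::vmatchPattern(pat, subj))
    for (k in which(lengths(st) > 0)) {
      pos <- as.integer(st[[k]] - 1L)
      if (target_kind == "circ") pos <- pos[pos < Lk[k]]
      if (length(pos) == 0) next
      facing <- substring(scan_seqs[k], pos + 8L, pos + 8L)
      rows[[length(rows) + 1L]] <-
        tibble(mirna_id = mirnas$mirna_id[i], target_id = targets$target_id[k],
               target_kind = target_kind, position = pos,
               site_type = ifelse(facing == "A", "8mer", "7mer-m8"))
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(mirna_id = character(), target_id = character(),
                  target_kind = character(), position = integer(),
                  site_type = character())
  }
  out
}

#' Seed-match target prediction over a target table
#'
#' @param mirnas Tibble (`mirna_id`, `sequence`).
#' @param targets Tibble (`target_id`, `sequence`).
#' @param target_kind `"utr3"` or `"circ"`. Circular targets are scanned on
#'   the doubled sequence so junction-straddling sites are found; positions
#'   are reported modulo the circular length and deduplicated.
#' @return TargetSite tibble with `source = "seedmatch"`.
#' @export
predict_seedmatch <- function(mirnas, targets, target_kind = "utr3") {
  out <- scan_seed_hits(mirnas, targets, target_kind)
  out$score <- NA_real_; out$energy <- NA_real_
  out$source <- rep("seedmatch", nrow(out))
  out
}

#' miRanda-style target prediction
#'
#' Candidate sites are anchored at seed matches (a site failing perfect seed
#' pairing cannot pass the strict-seed filter, so anchoring loses nothing); a
#' bounded window around each anchor is aligned with [duplex_align()] and a
#' site is kept iff `score >= score_thr`, `energy <= energy_thr` and the
#' seed is strictly Watson-Crick paired.
#'
#' @inheritParams predict_seedmatch
#' @param score_thr Alignment score threshold (default 140).
#' @param energy_thr Duplex energy threshold in kcal/mol (default -10).
#' @param flank Extra window bases on each side of the maximal site extent.
#' @return TargetSite tibble with `source = "miranda"`.
#' @export
predict_miranda <- function(mirnas, targets, target_kind = "utr3",
                            score_thr = 140, energy_thr = -10, flank = 6) {
  hits <- scan_seed_hits(mirnas, targets, target_kind)
  mir_seq <- setNames(mirnas$sequence, mirnas$mirna_id)
  tgt_seq <- setNames(targets$sequence, targets$target_id)
  rows <- list()
  for (h in seq_len(nrow(hits))) {
    mir <- mir_seq[[hits$mirna_id[h]]]
    n <- nchar(mir)
    seqk <- tgt_seq[[hits$target_id[h]]]
    Lk <- nchar(seqk)
    scan_seq <- if (target_kind == "circ") paste0(seqk, seqk) else seqk
    p0 <- hits$position[h]
    ## circular targets: when the upstream site context would clip at the
    ## doubled-sequence start, evaluate the equivalent anchor one turn later
    if (target_kind == "circ" && p0 - (n - 8L) - flank < 0) p0 <- p0 + Lk
    win_lo <- max(0L, p0 - (n - 8L) - flank)
    win_hi <- min(nchar(scan_seq), p0 + 8L + flank)
    aln <- duplex_align(mir, seq_slice(scan_seq, win_lo, win_hi))
    if (!aln$seed_strict) next
    if (aln$score < score_thr || aln$energy > energy_thr) next
    pos <- win_lo + aln$target_start
    if (target_kind == "circ") pos <- pos %% Lk
    rows[[length(rows) + 1L]] <- tibble(
      mirna_id = hits$mirna_id[h], target_id = hits$target_id[h],
      target_kind = target_kind, position = as.integer(pos),
      site_type = hits$site_type[h], score = aln$score, energy = aln$energy,
      source = "miranda")
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(mirna_id = character(), target_id = character(),
                  target_kind = character(), position = integer(),
                  site_type = character(), score = numeric(), energy = numeric(),
                  source = character()))
  }
  distinct(out, .data$mirna_id, .data$target_id, .data$target_kind,
           .data$position, .keep_all = TRUE)
}

#' Intersect the two predictors at pair level
#'
#' A (miRNA, target) pair survives iff it has at least one site from each
#' predictor; surviving sites are reported from the alignment-based predictor
#' (they carry score and energy) with `source = "both"`.
#'
#' @param miranda_sites,seedmatch_sites Site tibbles from the two predictors.
#' @return List with `sites` (source `"both"`) and `pairs` (distinct
#'   `mirna_id`, `target_id`, `target_kind`).
#' @export
intersect_predictions <- function(miranda_sites, seedmatch_sites) {
  key <- c("mirna_id", "target_id", "target_kind")
  pairs <- inner_join(distinct(miranda_sites[key]),
                      distinct(seedmatch_sites[key]), by = key) |>
    arrange(.data$mirna_id, .data$target_id)
  sites <- inner_join(miranda_sites, pairs, by = key) |>
    mutate(source = "both")
  list(sites = sites, pairs = pairs)
}

#' Dual target prediction over 3'UTRs and circRNA sequences
#'
#' Runs the seed-match scan and the duplex aligner over both target classes
#' and intersects per pair.
#'
#' @param mirnas Tibble (`mirna_id`, `sequence`).
#' @param utrs Tibble (`gene_id` or `target_id`, `sequence`) of 3'UTRs; may
#'   be NULL.
#' @param circs Tibble (`circ_id` or `target_id`, `sequence`) of circular
#'   sequences; may be NULL.
#' @inheritParams predict_miranda
#' @return A `cerna_targets` list: `sites`, `pairs`.
#' @export
predict_targets <- function(mirnas, utrs = NULL, circs = NULL,
                            score_thr = 140, energy_thr = -10) {
  std <- function(x, id_col) {
    if (is.null(x) || nrow(x) == 0) return(NULL)
    nm <- intersect(c(id_col, "target_id"), names(x))[1]
    tibble(target_id = x[[nm]], sequence = x$sequence)
  }
  utrs <- std(utrs, "gene_id"); circs <- std(circs, "circ_id")
  mir_sites <- list(); seed_sites <- list()
  if (!is.null(utrs)) {
    mir_sites$utr <- predict_miranda(mirnas, utrs, "utr3", score_thr, energy_thr)
    seed_sites$utr <- predict_seedmatch(mirnas, utrs, "utr3")
  }
  if (!is.null(circs)) {
    mir_sites$circ <- predict_miranda(mirnas, circs, "circ", score_thr, energy_thr)
    seed_sites$circ <- predict_seedmatch(mirnas, circs, "circ")
  }
  res <- intersect_predictions(bind_rows(mir_sites), bind_rows(seed_sites))
  structure(res, class = "cerna_targets")
}

#' @export
print.cerna_targets <- function(x, ...) {
  cat("<cerna_targets>\n")
  cat(sprintf("  intersected sites: %d\n", nrow(x$sites)))
  cat(sprintf("  pairs: %d (%d utr3, %d circ)\n", nrow(x$pairs),
              sum(x$pairs$target_kind == "utr3"), sum(x$pairs$target_kind == "circ")))
  invisible(x)
}
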