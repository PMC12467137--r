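ANCHOR_LEN <- 20L

#' Extract terminal anchors from a read
#'
#' @param read Read sequence (single string).
#' @param anchor_len Anchor length (default 20).
#' @return List with `left` (first `anchor_len` bases) and `right` (last
#'   `anchor_len` bases), or `NULL` when the read is shorter than
#'   `2 * anchor_len` (callers count such skips).
#' @export
extract_anchors <- function(read, anchor_len = ANCHOR_LEN) {
  L <- nchar(read)
  if (L < 2 * anchor_len) return(NULL)
  list(left = substr(read, 1L, anchor_len),
       right = substr(read, L - anchor_len + 1L, L))
}

#' Exact-match anchor alignment
#'
#' Searches an anchor against both strands of the genome (the reverse strand
#' is searched as the reverse complement on the forward sequence). An anchor
#' is `unique` when it has exactly one hit in total across strands and
#' chromosomes.
#'
#' @param anchor Anchor sequence over ACGT.
#' @param genome Named character vector or `DNAStringSet`.
#' @return Tibble of hits: `chrom`, `strand`, `position` (0-based start on
#'   the forward strand), `unique`. Zero rows when the anchor is absent.
#' @export
map_anchor <- function(anchor, genome) {
  assert_dna(anchor, "anchor")
  genome <- genome_as_character(genome)
  hit_rows <- list()
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") anchor else revcomp(anchor)
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj)
      if (length(m) > 0) {
        hit_rows[[length(hit_rows) + 1L]] <-
          tibble(chrom = ch, strand = strand,
                 position = as.integer(Biostrings::start(m) - 1L))
      }
    }
  }
  hits <- bind_rows(hit_rows)
  if (nrow(hits) == 0) {
    return(tibble(chrom = character(), strand = character(),
                  position = integer(), unique = logical()))
  }
  hits$unique <- nrow(hits) == 1L
  hits
}

## batched plus-strand exact matching of equal-width anchors; returns, per
## unique anchor string: the plus-strand hit count and (for single-hit
## anchors) the hit location
match_anchors_batch <- function(anchors, genome) {
  anchors <- unique(anchors)
  k <- length(anchors)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(anchors))
  n_plus <- integer(k)
  hit_chrom <- rep(NA_character_, k)
  hit_pos <- rep(NA_integer_, k)
  for (ch in names(genome)) {
    st <- Biostrings::startIndex(
      Biostrings::matchPDict(pd, Biostrings::DNAString(genome[[ch]])))
    ln <- lengths(st)
    nz <- which(ln > 0)
    n_plus[nz] <- n_plus[nz] + ln[nz]
    one <- nz[ln[nz] >= 1]
    hit_chrom[one] <- ch
    hit_pos[one] <- vapply(st[one], function(x) as.integer(x[1] - 1L), integer(1))
  }
  list(anchors = anchors, n_plus = setNames(n_plus, anchors),
       chrom = setNames(hit_chrom, anchors), pos = setNames(hit_pos, anchors))
}

longest_common_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- utf8ToInt(substr(a, 1, n)); bv <- utf8ToInt(substr(b, 1, n))
  neq <- which(av != bv)
  if (length(neq) == 0) n else neq[1] - 1L
}

longest_common_suffix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- utf8ToInt(substr(a, nchar(a) - n + 1L, nchar(a)))
  bv <- utf8ToInt(substr(b, nchar(b) - n + 1L, nchar(b)))
  neq <- which(rev(av != bv))
  if (length(neq) == 0) n else neq[1] - 1L
}

## core junction inference for one oriented read given unique plus-strand
## anchor positions; returns NULL or a one-row tibble
infer_junction <- function(read, chrom_seq, chrom, pL, r0, anchor_len) {
  L <- nchar(read)
  if (r0 >= pL) return(NULL)          # collinear or overlapping: not head-to-tail
  clen <- nchar(chrom_seq)

  ## donor side: how far the read prefix matches the genome from pL
  g <- seq_slice(chrom_seq, pL, min(pL + L, clen))
  m1 <- longest_common_prefix(read, g)

  ## acceptor side: genome window aligned to the read end (read position i
  ## maps to r0 + i - (L - anchor_len))
  h_start <- r0 - (L - anchor_len)
  h <- seq_slice(chrom_seq, max(h_start, 0L), r0 + anchor_len)
  m2 <- longest_common_suffix(read, h)
  i_min <- L - m2

  p <- max(anchor_len, i_min)          # leftmost-acceptor convention
  if (p > min(m1, L - anchor_len)) return(NULL)
  d <- pL + p
  a <- r0 + anchor_len - (L - p)
  if (a < 0 || a >= d) return(NULL)

  ## confirm: the read must be reproduced verbatim from the doubled segment
  recon <- paste0(seq_slice(chrom_seq, d - p, d), seq_slice(chrom_seq, a, a + L - p))
  if (recon != read) return(NULL)
  list(chrom = chrom, start = as.integer(a), end = as.integer(d))
}

#' Call a back-splice junction from a single read
#'
#' Extracts the two terminal anchors, aligns them exactly to the genome
#' (both strands via the reverse-complemented read), and reports a candidate
#' junction when the anchors map uniquely in head-to-tail orientation (the
#' right-end anchor upstream of the left-end anchor on the forward strand)
#' and the full read is reproduced exactly from the doubled circular segment.
#' Junction-ambiguous repeats are resolved by the leftmost-acceptor
#' convention.
#'
#' @param read Read sequence.
#' @param genome Named character vector or `DNAStringSet`.
#' @param anchor_len Anchor length.
#' @return One-row tibble (`chrom`, `start`, `end`, `strand`; 0-based
#'   half-open) or `NULL` (linear read, non-unique anchors, different
#'   chromosomes, or failed reconstruction).
#' @export
call_backsplice <- function(read, genome, anchor_len = ANCHOR_LEN) {
  genome <- genome_as_character(genome)
  anchors <- extract_anchors(read, anchor_len)
  if (is.null(anchors)) return(NULL)
  for (orient in c("+", "-")) {
    oriented <- if (orient == "+") read else revcomp(read)
    a <- extract_anchors(oriented, anchor_len)
    hl <- map_anchor(a$left, genome)
    hr <- map_anchor(a$right, genome)
    if (nrow(hl) != 1 || nrow(hr) != 1) next       # absent or non-unique
    if (hl$strand != "+" || hr$strand != "+") next # handled by the other orientation
    if (hl$chrom != hr$chrom) next
    j <- infer_junction(oriented, genome[[hl$chrom]], hl$chrom,
                        hl$position, hr$position, anchor_len)
    if (!is.null(j)) {
      return(tibble(chrom = j$chrom, start = j$start, end = j$end, strand = orient))
    }
  }
  NULL
}

#' Detect circRNAs from reads by anchor-based back-splice calling
#'
#' The pipeline caller: terminal 20-mer anchors of every read (and of its
#' reverse complement) are exact-matched against the genome in one batch;
#' reads whose two anchors map uniquely in head-to-tail orientation yield a
#' candidate junction, confirmed by reconstructing the read verbatim from the
#' doubled circular segment. Candidates are grouped by junction and strand;
#' support counts **distinct supporting read sequences** per sample, and a
#' call is retained when some sample reaches `min_support` (or, with
#' `per_sample = FALSE`, when the pooled distinct-read support does).
#'
#' @param reads Tibble with `read_id`, `sample_id`, `sequence` (e.g. from
#'   [simulate_reads()] or [read_reads_fastq()]).
#' @param genome Named character vector or `DNAStringSet`.
#' @param genes,exons Optional gene-model tibbles (see
#'   [simulate_reference()]); when supplied, calls are classified into
#'   annotation types.
#' @param anchor_len Anchor length (default 20).
#' @param min_support Minimum distinct-read support (default 2).
#' @param per_sample Apply `min_support` within the best single sample
#'   (default) or to the pooled support.
#' @return A `circ_calls` tibble: `circ_id`, `chrom`, `start`, `end`,
#'   `strand`, `length`, `circ_type` (if annotated), `support_<sample>`
#'   columns and `max_support`. Attributes `n_skipped_short` and
#'   `n_rejected_reconstruction` count discarded reads.
#' @export
detect_circrnas <- function(reads, genome, genes = NULL, exons = NULL,
                            anchor_len = ANCHOR_LEN, min_support = 2,
                            per_sample = TRUE) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sample_id", "sequence") %in% names(reads)))
  genome <- genome_as_character(genome)

  short <- nchar(reads$sequence) < 2 * anchor_len
  n_short <- sum(short)
  if (n_short > 0) {
    warn(sprintf("skipped %d read(s) shorter than 2 x anchor_len = %d",
                 n_short, 2 * anchor_len))
  }
  reads <- reads[!short, , drop = FALSE]
  samples <- sort(unique(reads$sample_id))

  cand <- NULL
  n_rejected <- 0L
  if (nrow(reads) > 0) {
    L <- nchar(reads$sequence)
    fwd <- reads$sequence
    rev <- revcomp(fwd)
    al_f <- substr(fwd, 1L, anchor_len)
    ar_f <- substr(fwd, L - anchor_len + 1L, L)
    al_r <- substr(rev, 1L, anchor_len)
    ar_r <- substr(rev, L - anchor_len + 1L, L)

    hits <- match_anchors_batch(c(al_f, ar_f, al_r, ar_r), genome)
    nhit <- hits$n_plus
    ## total hits across strands: plus hits of the anchor + plus hits of its rc
    rc_idx <- match(revcomp(hits$anchors), hits$anchors)
    total <- nhit + ifelse(is.na(rc_idx), 0L, nhit[rc_idx])
    names(total) <- hits$anchors

    ## vectorized screen: unique anchors (one hit counting both strands, on
    ## the plus strand for this orientation), same chromosome, head-to-tail
    screen <- function(left, right) {
      total[left] == 1L & total[right] == 1L &
        nhit[left] == 1L & nhit[right] == 1L &
        hits$chrom[left] == hits$chrom[right] &
        hits$pos[right] < hits$pos[left]
    }
    ok_f <- screen(al_f, ar_f)
    ok_r <- screen(al_r, ar_r)
    ok_f[is.na(ok_f)] <- FALSE; ok_r[is.na(ok_r)] <- FALSE

    idx <- integer(); chrom_v <- character(); a_v <- integer()
    d_v <- integer(); strand_v <- character()
    for (i in which(ok_f | ok_r)) {
      for (orient in c("+", "-")) {
        if (orient == "+" && !ok_f[i]) next
        if (orient == "-" && !ok_r[i]) next
        left <- if (orient == "+") al_f[i] else al_r[i]
        ch <- hits$chrom[[left]]
        pL <- hits$pos[[left]]
        r0 <- hits$pos[[if (orient == "+") ar_f[i] else ar_r[i]]]
        oriented <- if (orient == "+") fwd[i] else rev[i]
        j <- infer_junction(oriented, genome[[ch]], ch, pL, r0, anchor_len)
        if (is.null(j)) { n_rejected <- n_rejected + 1L; next }
        idx <- c(idx, i); chrom_v <- c(chrom_v, ch)
        a_v <- c(a_v, j$start); d_v <- c(d_v, j$end); strand_v <- c(strand_v, orient)
        break
      }
    }
    if (length(idx) > 0) {
      cand <- bind_cols(reads[idx, c("read_id", "sample_id", "sequence")],
                        tibble(chrom = chrom_v, start = a_v, end = d_v,
                               strand = strand_v))
    }
  }

  calls <- aggregate_candidates(cand, samples, min_support, per_sample)
  if (!is.null(genes) && nrow(calls) > 0) {
    calls$circ_type <- classify_circs(calls, genes, exons)
    calls <- relocate(calls, "circ_type", .after = "length")
  }
  structure(calls, class = c("circ_calls", class(calls)),
            n_skipped_short = n_short, n_rejected_reconstruction = n_rejected)
}

#' Aggregate junction candidates into supported circRNA calls
#'
#' @param candidates Tibble of per-read candidates (`read_id`, `sample_id`,
#'   `sequence`, `chrom`, `start`, `end`, `strand`).
#' @param samples Sample ids to report support columns for (defaults to those
#'   present).
#' @param min_support Minimum distinct-read-sequence support (default 2, as
#'   in "at least two unique back-spliced reads in at least one sample").
#' @param per_sample Threshold applies within a single sample (default) or to
#'   pooled distinct support.
#' @return Tibble of retained calls with per-sample `support_*` columns.
#' @export
aggregate_candidates <- function(candidates, samples = NULL, min_support = 2,
                                 per_sample = TRUE) {
  empty <- tibble(circ_id = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), length = integer(),
                  max_support = integer())
  if (is.null(candidates) || nrow(candidates) == 0) return(empty)
  if (is.null(samples)) samples <- sort(unique(candidates$sample_id))

  sup <- candidates |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand,
             .data$sample_id, .data$sequence) |>
    dplyr::count(.data$chrom, .data$start, .data$end, .data$strand,
                 .data$sample_id, name = "support") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "support",
                       values_fill = 0L, names_prefix = "support_")
  for (s in paste0("support_", samples)) if (!s %in% names(sup)) sup[[s]] <- 0L
  sup <- sup |> select("chrom", "start", "end", "strand",
                       all_of(paste0("support_", samples)))
  supmat <- as.matrix(sup[, -(1:4), drop = FALSE])
  sup$max_support <- as.integer(apply(supmat, 1, max))
  pooled <- candidates |>
    distinct(.data$chrom, .data$start, .data$end, .data$strand, .data$sequence) |>
    dplyr::count(.data$chrom, .data$start, .data$end, .data$strand,
                 name = "pooled_support")
  sup <- left_join(sup, pooled, by = c("chrom", "start", "end", "strand"))
  keep <- if (per_sample) sup$max_support >= min_support else
    sup$pooled_support >= min_support
  sup <- sup[keep, , drop = FALSE] |>
    arrange(.data$chrom, .data$start, .data$end)
  if (nrow(sup) == 0) return(empty)
  sup |>
    mutate(circ_id = sprintf("%s:%d|%d:%s", .data$chrom, .data$start,
                             .data$end, .data$strand),
           length = as.integer(.data$end - .data$start)) |>
    relocate("circ_id") |>
    relocate("length", .after = "strand")
}

#' Classify circRNA calls against gene models
#'
#' Types and precedence: `one-exon` (span equals a single annotated exon) >
#' `annot-exon` (both junction boundaries on exon boundaries of one
#' same-strand gene) > `exon-intron` (overlaps at least one exon and one
#' intron of a same-strand gene) > `intron` (inside one intron) > `antisense`
#' (within a gene on the opposite strand) > `intergenic`.
#'
#' @param calls Tibble with `chrom`, `start`, `end`, `strand`.
#' @param genes,exons Gene-model tibbles.
#' @return Character vector of types, one per call.
#' @export
classify_circs <- function(calls, genes, exons) {
  vapply(seq_len(nrow(calls)), function(i) {
    classify_one(calls$chrom[i], calls$start[i], calls$end[i],
                 calls$strand[i], genes, exons)
  }, character(1))
}

classify_one <- function(chrom, a, d, strand, genes, exons) {
  same <- genes[genes$chrom == chrom & genes$strand == strand, ]
  rank <- c("one-exon" = 1, "annot-exon" = 2, "exon-intron" = 3, "intron" = 4)
  best <- Inf; best_type <- NA_character_
  for (gid in same$gene_id) {
    ex <- exons[exons$gene_id == gid, ]
    type <- NA_character_
    if (any(ex$start == a & ex$end == d)) {
      type <- "one-exon"
    } else if (a %in% ex$start && d %in% ex$end) {
      type <- "annot-exon"
    } else {
      istart <- head(ex$end, -1); iend <- tail(ex$start, -1)
      ov_exon <- any(pmin(d, ex$end) > pmax(a, ex$start))
      ov_intr <- length(istart) > 0 && any(pmin(d, iend) > pmax(a, istart))
      if (ov_exon && ov_intr) {
        type <- "exon-intron"
      } else if (length(istart) > 0 && any(a >= istart & d <= iend)) {
        type <- "intron"
      }
    }
    if (!is.na(type) && rank[[type]] < best) { best <- rank[[type]]; best_type <- type }
  }
  if (!is.na(best_type)) return(best_type)
  anti <- genes[genes$chrom == chrom & genes$strand != strand, ]
  if (any(a >= anti$start & d <= anti$end)) return("antisense")
  "intergenic"
}

#' Per-sample support counts of circRNA calls as a counts tibble
#'
#' @param calls A `circ_calls` tibble.
#' @return Tibble `feature_id` + one column per sample (distinct-read
#'   support), suitable for [de_test()].
#' @export
circ_support_counts <- function(calls) {
  sup_cols <- grep("^support_", names(calls), value = TRUE)
  out <- calls |> select("circ_id", all_of(sup_cols)) |> rename(feature_id = "circ_id")
  names(out) <- sub("^support_", "", names(out))
  names(out)[1] <- "feature_id"
  out
}
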