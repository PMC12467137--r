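#' Simulate junction-spanning and linear reads
#'
#' Emits, per sample, reads that straddle each planted back-splice junction
#' with at least `anchor_len` bases on both sides (prefix from the donor side
#' of the circle, suffix from the acceptor side) plus contiguous linear
#' genomic reads. Reads from minus-strand features are reverse complemented.
#' Per-read truth labels are returned for scoring the caller.
#'
#' Reads are error-free by default; `error_rate` adds uniform substitutions,
#' which reduces caller recall by design (anchor matching is exact).
#'
#' @param ref A `cerna_reference`.
#' @param samples Sample sheet tibble (`sample_id`, `group`), e.g. from a
#'   `cerna_counts` object.
#' @param read_len Read length (>= `2 * anchor_len`).
#' @param junction_reads_per_circ Junction-spanning reads per circRNA per
#'   sample; breakpoint offsets are drawn without replacement so read
#'   sequences are distinct.
#' @param linear_reads_per_sample Contiguous genomic reads per sample.
#' @param error_rate Per-base substitution probability.
#' @param anchor_len Anchor length used downstream (fixed at 20 by the
#'   caller).
#' @param seed Integer seed.
#' @return A `cerna_reads` tibble: `read_id`, `sample_id`, `sequence`,
#'   `label` (`junction`/`linear`), `circ_id`, `breakpoint` (donor-side bases
#'   in the read).
#' @export
simulate_reads <- function(ref, samples,
                           read_len = 100,
                           junction_reads_per_circ = 4,
                           linear_reads_per_sample = 200,
                           error_rate = 0,
                           anchor_len = 20,
                           seed = NULL) {
  stopifnot(inherits(ref, "cerna_reference"), junction_reads_per_circ >= 0,
            linear_reads_per_sample >= 0)
  if (read_len < 2 * anchor_len) {
    abort(sprintf(
      "read_len (%d) must be >= 2 * anchor_len (2 * %d = %d) so junction reads can carry a full anchor on both sides",
      read_len, anchor_len, 2 * anchor_len))
  }
  if (!is.null(seed)) set.seed(seed)

  circs <- ref$circs
  n_junc <- if (nrow(circs) > 0) {
    min(junction_reads_per_circ, read_len - 2 * anchor_len + 1L)
  } else 0L
  parts <- list()

  if (n_junc > 0 && nrow(circs) > 0) {
    spans <- vapply(seq_len(nrow(circs)), function(i) {
      seq_slice(ref$genome[[circs$chrom[i]]], circs$start[i], circs$end[i])
    }, character(1))
    stopifnot(nchar(spans) >= read_len)
    doubled <- paste0(spans, spans)
    jn <- purrr::map_dfr(samples$sample_id, function(s) {
      purrr::map_dfr(seq_len(nrow(circs)), function(i) {
        ## breakpoint offsets drawn without replacement: distinct sequences
        offs <- sample(anchor_len:(read_len - anchor_len), n_junc)
        tibble(sample_id = s, circ_id = circs$circ_id[i],
               strand = circs$strand[i], breakpoint = as.integer(offs),
               ## last p bases of the circle followed by its first read_len - p
               sequence = substring(doubled[i], nchar(spans[i]) - offs + 1L,
                                    nchar(spans[i]) - offs + read_len))
      })
    })
    jn$read_id <- sprintf("%s_junc_%s_%d", jn$sample_id, jn$circ_id, jn$breakpoint)
    jn$label <- "junction"
    neg <- jn$strand == "-"
    if (any(neg)) jn$sequence[neg] <- revcomp(jn$sequence[neg])
    parts$junction <- jn[, c("read_id", "sample_id", "sequence", "label",
                             "circ_id", "breakpoint")]
  }

  if (linear_reads_per_sample > 0) {
    ln <- purrr::map_dfr(samples$sample_id, function(s) {
      ch <- sample(names(ref$genome), linear_reads_per_sample, replace = TRUE)
      pos <- vapply(ch, function(x) {
        sample.int(nchar(ref$genome[[x]]) - read_len, 1)
      }, integer(1))
      tibble(read_id = sprintf("%s_lin_%d", s, seq_len(linear_reads_per_sample)),
             sample_id = s,
             sequence = substring(unlist(ref$genome[ch], use.names = FALSE),
                                  pos, pos + read_len - 1L),
             label = "linear", circ_id = NA_character_, breakpoint = NA_integer_,
             flip = runif(linear_reads_per_sample) < 0.5)
    })
    if (any(ln$flip)) ln$sequence[ln$flip] <- revcomp(ln$sequence[ln$flip])
    parts$linear <- ln[, c("read_id", "sample_id", "sequence", "label",
                           "circ_id", "breakpoint")]
  }

  out <- bind_rows(parts)
  if (nrow(out) > 0) out$sequence <- unname(out$sequence)
  if (nrow(out) == 0) {
    out <- tibble(read_id = character(), sample_id = character(),
                  sequence = character(), label = character(),
                  circ_id = character(), breakpoint = integer())
  }
  if (error_rate > 0 && nrow(out) > 0) {
    out$sequence <- vapply(out$sequence, add_errors, character(1),
                           rate = error_rate, USE.NAMES = FALSE)
  }
  structure(out, class = c("cerna_reads", class(out)))
}

add_errors <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1)
  paste(b, collapse = "")
}
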