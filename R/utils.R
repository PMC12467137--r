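#' @importFrom rlang .data abort warn .env :=
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join distinct bind_rows bind_cols rename n
#'   row_number across all_of pull relocate transmute
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnbinom rlnorm runif setNames p.adjust pnorm pt phyper
#'   cor median var rbinom
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()];
#' sequences are stored in the DNA alphabet throughout (miRNA U is stored
#' as T).
#'
#' @param x Character vector of sequences over ACGT.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## in-place replacement of bases [at, at + nchar(site)) (0-based) of seq
overwrite_seq <- function(seq, site, at) {
  stopifnot(at >= 0, at + nchar(site) <= nchar(seq))
  paste0(substr(seq, 1L, at), site, substr(seq, at + nchar(site) + 1L, nchar(seq)))
}

## 0-based half-open substring
seq_slice <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

assert_dna <- function(x, what = "sequence") {
  if (any(grepl("[^ACGT]", x))) {
    abort(paste0(what, " must be over the ACGT alphabet"))
  }
  invisible(x)
}

genome_as_character <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    genome
  } else {
    abort("genome must be a named character vector or a DNAStringSet")
  }
}

#' Two-group sample sheet
#'
#' Builds the control/grazing (C/G) sample sheet used throughout the
#' simulations: `n_per_group` replicates per group.
#'
#' @param n_per_group Biological replicates per group.
#' @return Tibble with `sample_id` (C1..Cn, G1..Gn) and `group`.
#' @export
sample_sheet <- function(n_per_group) {
  tibble(
    sample_id = c(paste0("C", seq_len(n_per_group)), paste0("G", seq_len(n_per_group))),
    group = rep(c("C", "G"), each = n_per_group)
  )
}

counts_to_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), names(counts)[1] == "feature_id")
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  m
}

matrix_to_counts <- function(m) {
  bind_cols(tibble(feature_id = rownames(m)), as_tibble(m))
}
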