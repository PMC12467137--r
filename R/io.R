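#' Write a simulated reference and reads to standard formats
#'
#' Emits genome FASTA, annotation GTF (gene/exon/three_prime_utr features,
#' 1-based closed coordinates), mature miRNA FASTA, per-sample FASTQ, count
#' TSVs and a truth JSON under one directory.
#'
#' @param ref A `cerna_reference`.
#' @param outdir Output directory (created if absent).
#' @param truth Optional `cerna_truth` (written as `truth.json`).
#' @param counts Optional `cerna_counts` (written as `<class>_counts.tsv` and
#'   `samples.tsv`).
#' @param reads Optional `cerna_reads` (written as `<sample>.fastq`).
#' @return `outdir`, invisibly.
#' @export
write_reference <- function(ref, outdir, truth = NULL, counts = NULL,
                            reads = NULL) {
  stopifnot(inherits(ref, "cerna_reference"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$genome),
                              file.path(outdir, "genome.fa"))
  if (nrow(ref$mirnas) > 0) {
    mir <- setNames(ref$mirnas$sequence, ref$mirnas$mirna_id)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(mir),
                                file.path(outdir, "mirna.fa"))
  }
  write_gtf(ref, file.path(outdir, "annotation.gtf"))
  write_circ_bed(ref$circs, file.path(outdir, "circ_truth.bed"))

  if (!is.null(truth)) {
    jsonlite::write_json(lapply(unclass(truth), as.data.frame),
                         file.path(outdir, "truth.json"), digits = NA)
  }
  if (!is.null(counts)) {
    for (cls in c("circ", "mirna", "mrna")) {
      readr::write_tsv(counts[[cls]], file.path(outdir, paste0(cls, "_counts.tsv")))
    }
    readr::write_tsv(counts$samples, file.path(outdir, "samples.tsv"))
  }
  if (!is.null(reads)) write_reads_fastq(reads, outdir)
  invisible(outdir)
}

## GTF is 1-based closed; internal coordinates are 0-based half-open
write_gtf <- function(ref, path) {
  lines <- character()
  g <- ref$genes
  for (i in seq_len(nrow(g))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gene_id[i], g$gene_id[i])
    lines <- c(lines, paste(g$chrom[i], "cernakit", "gene", g$start[i] + 1L,
                            g$end[i], ".", g$strand[i], ".", attrs, sep = "\t"))
    ex <- ref$exons[ref$exons$gene_id == g$gene_id[i], ]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(g$chrom[i], "cernakit", "exon", ex$start[j] + 1L,
                              ex$end[j], ".", g$strand[i], ".",
                              sprintf('%s exon_number "%d";', attrs, ex$exon_number[j]),
                              sep = "\t"))
    }
    lines <- c(lines, paste(g$chrom[i], "cernakit", "three_prime_utr",
                            g$utr3_start[i] + 1L, g$utr3_end[i], ".",
                            g$strand[i], ".", attrs, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a cernakit-style GTF
#'
#' Parses gene/exon/three_prime_utr records back into the internal 0-based
#' half-open tibbles.
#'
#' @param path GTF file path.
#' @return List with `genes` and `exons` tibbles.
#' @export
read_gtf <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "source", "feature",
                                             "start", "end", "score", "strand",
                                             "frame", "attrs"),
                         col_types = "cccddcccc", comment = "#")
  raw$gene_id <- sub('.*gene_id "([^"]+)".*', "\\1", raw$attrs)
  genes <- raw |> filter(.data$feature == "gene") |>
    transmute_gene()
  utr <- raw |> filter(.data$feature == "three_prime_utr") |>
    mutate(utr3_start = as.integer(.data$start - 1L), utr3_end = as.integer(.data$end)) |>
    select("gene_id", "utr3_start", "utr3_end")
  exons <- raw |> filter(.data$feature == "exon") |>
    mutate(exon_number = as.integer(sub('.*exon_number "([0-9]+)".*', "\\1", .data$attrs)),
           start = as.integer(.data$start - 1L), end = as.integer(.data$end)) |>
    select("gene_id", "exon_number", "start", "end") |>
    arrange(.data$gene_id, .data$exon_number)
  genes <- left_join(genes, utr, by = "gene_id") |>
    left_join(exons |> group_by(.data$gene_id) |> summarise(n_exons = dplyr::n()),
              by = "gene_id")
  list(genes = genes, exons = exons)
}

transmute_gene <- function(x) {
  x |> mutate(start = as.integer(.data$start - 1L), end = as.integer(.data$end)) |>
    select("gene_id", "chrom", "strand", "start", "end")
}

write_circ_bed <- function(circs, path) {
  if (nrow(circs) == 0) { writeLines(character(), path); return(invisible(path)) }
  lines <- paste(circs$chrom, circs$start, circs$end, circs$circ_id, 0,
                 circs$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write simulated reads as per-sample FASTQ
#'
#' @param reads A `cerna_reads` tibble.
#' @param outdir Output directory.
#' @return Paths written, invisibly.
#' @export
write_reads_fastq <- function(reads, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (s in unique(reads$sample_id)) {
    sub <- reads[reads$sample_id == s, ]
    x <- Biostrings::DNAStringSet(setNames(sub$sequence, sub$read_id))
    p <- file.path(outdir, paste0(s, ".fastq"))
    Biostrings::writeXStringSet(
      x, p, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(x))))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read per-sample FASTQ files into a reads tibble
#'
#' @param paths Named character vector of FASTQ paths; names are sample ids
#'   (defaults to file base names).
#' @return Tibble with `read_id`, `sample_id`, `sequence`.
#' @export
read_reads_fastq <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(paths))
  }
  purrr::map2_dfr(paths, names(paths), function(p, s) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    tibble(read_id = sub(" .*", "", names(x)), sample_id = s,
           sequence = unname(as.character(x)))
  })
}

#' Read a counts TSV (first column feature id, one column per sample)
#' @param path TSV path.
#' @return Tibble with `feature_id` first.
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "feature_id"
  x
}

#' Read a gene-set file in GMT format
#'
#' Wraps [fgsea::gmtPathways()] and returns the long tidy form used by
#' [ora()].
#'
#' @param path GMT file path.
#' @return Tibble with `term_id` and `gene`.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  purrr::imap_dfr(sets, function(genes, id) tibble(term_id = id, gene = genes))
}

#' Write a term map in GMT format
#'
#' @param term_map Tibble with `term_id` and `gene` (optionally `term_name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(term_map, path) {
  split_sets <- split(term_map$gene, term_map$term_id)
  lines <- vapply(names(split_sets), function(id) {
    paste(c(id, id, split_sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
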