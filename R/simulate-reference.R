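#' Simulate a toy genome, gene models, miRNAs and planted circRNAs
#'
#' Builds the reference material every downstream stage acts on: random
#' chromosomes over ACGT, non-overlapping multi-exon gene models with a 3'UTR,
#' mature miRNA sequences (stored in the DNA alphabet, U as T), and a set of
#' planted circRNAs whose back-splice junctions are placed according to a
#' requested mix of annotation-derived types (annot-exon, one-exon,
#' exon-intron, intron, intergenic, antisense).
#'
#' All coordinates are 0-based half-open internally; [write_reference()]
#' emits 1-based closed GTF.
#'
#' Each planted junction is pinned so that the base immediately upstream of
#' the acceptor differs from the last base of the circle: back-splice
#' coordinates are then unambiguous and the caller's leftmost-acceptor
#' convention recovers the planted coordinates exactly.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome (nt).
#' @param n_genes Number of genes, distributed across chromosomes.
#' @param n_mirnas Number of mature miRNAs (lengths drawn from 21-23 nt,
#'   distinct seeds).
#' @param n_circ Number of planted circRNAs.
#' @param type_mix Named numeric vector of circRNA type proportions. The
#'   default follows the type shares typically reported for muscle circRNA
#'   catalogues, where exonic circles dominate.
#' @param utr3_len 3'UTR length per gene (nt, >= 200).
#' @param min_circ_len Minimum genomic span of a planted circle.
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @return A `cerna_reference` list: `genome` (named character), `genes`,
#'   `exons`, `mirnas`, `circs` tibbles.
#' @examples
#' ref <- simulate_reference(n_genes = 6, n_mirnas = 4, n_circ = 3, seed = 1)
#' ref$circs
#' @export
simulate_reference <- function(n_chrom = 2,
                               chrom_length = 100000,
                               n_genes = 30,
                               n_mirnas = 15,
                               n_circ = 12,
                               type_mix = c("annot-exon" = 0.70,
                                            "exon-intron" = 0.12,
                                            "one-exon" = 0.06,
                                            "intron" = 0.04,
                                            "intergenic" = 0.05,
                                            "antisense" = 0.03),
                               utr3_len = 300,
                               min_circ_len = 300,
                               seed = NULL) {
  stopifnot(n_chrom >= 1, chrom_length > 0, n_genes >= 0, n_mirnas >= 0,
            n_circ >= 0, utr3_len >= 200)
  if (!is.null(seed)) set.seed(seed)

  chrom_names <- paste0("chr", seq_len(n_chrom))
  genome <- setNames(vapply(chrom_names, function(x) random_dna(chrom_length),
                            character(1)), chrom_names)

  placed <- place_genes(chrom_names, chrom_length, n_genes, utr3_len)
  genes <- placed$genes
  exons <- placed$exons

  mirnas <- simulate_mirnas(n_mirnas)

  if (n_genes == 0) n_circ <- 0L
  circs <- place_circs(genes, exons, chrom_names, chrom_length, n_circ,
                       type_mix, min_circ_len)

  ## pin junctions: the base upstream of each acceptor must differ from the
  ## last base of every circle sharing that acceptor, so leftmost-acceptor
  ## calling is exact. Iterated to a fixpoint because one pin may rewrite a
  ## base another pin compares against (overlapping circles).
  if (nrow(circs) > 0) {
    for (pass in 1:10) {
      changed <- FALSE
      acc <- unique(circs[, c("chrom", "start")])
      for (i in seq_len(nrow(acc))) {
        ch <- acc$chrom[i]; a <- acc$start[i]
        ds <- circs$end[circs$chrom == ch & circs$start == a]
        bad <- unique(vapply(ds, function(d) seq_slice(genome[[ch]], d - 1L, d),
                             character(1)))
        cur <- seq_slice(genome[[ch]], a - 1L, a)
        if (cur %in% bad) {
          free <- setdiff(DNA_BASES, bad)
          if (length(free) == 0) {
            abort("capacity: cannot pin a shared back-splice acceptor",
                  class = "cernakit_capacity_error")
          }
          genome[[ch]] <- overwrite_seq(genome[[ch]], sample(rep(free, 2), 1),
                                        a - 1L)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    if (changed) abort("junction pinning did not converge",
                       class = "cernakit_capacity_error")
  }

  structure(list(genome = genome, genes = genes, exons = exons,
                 mirnas = mirnas, circs = circs),
            class = "cerna_reference")
}

place_genes <- function(chrom_names, chrom_length, n_genes, utr3_len) {
  empty_genes <- tibble(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(), end = integer(),
                        utr3_start = integer(), utr3_end = integer(),
                        n_exons = integer())
  empty_exons <- tibble(gene_id = character(), exon_number = integer(),
                        start = integer(), end = integer())
  if (n_genes == 0) return(list(genes = empty_genes, exons = empty_exons))

  per_chrom <- table(factor(chrom_names[(seq_len(n_genes) - 1L) %% length(chrom_names) + 1L],
                            levels = chrom_names))
  genes <- list(); exons <- list(); gi <- 0L
  for (ch in chrom_names) {
    cursor <- 200L
    for (k in seq_len(per_chrom[[ch]])) {
      gi <- gi + 1L
      gap <- sample(300:800, 1)
      n_exon <- sample(2:5, 1)
      ## terminal exons long enough to hold the 3'UTR on either strand
      lens <- c(sample(350:500, 1),
                if (n_exon > 2) sample(120:250, n_exon - 2, replace = TRUE),
                sample(350:500, 1))
      introns <- sample(200:450, n_exon - 1, replace = TRUE)
      start <- cursor + gap
      starts <- start + cumsum(c(0L, head(lens, -1) + introns))
      ends <- starts + lens
      gend <- ends[n_exon]
      if (gend > chrom_length - 200L) {
        abort(sprintf("capacity: cannot place %d genes on %s of length %d",
                      per_chrom[[ch]], ch, chrom_length),
              class = "cernakit_capacity_error")
      }
      strand <- sample(c("+", "-"), 1)
      if (strand == "+") {
        u3 <- c(gend - utr3_len, gend)
      } else {
        u3 <- c(start, start + utr3_len)
      }
      id <- sprintf("gene%03d", gi)
      genes[[gi]] <- tibble(gene_id = id, chrom = ch, strand = strand,
                            start = as.integer(start), end = as.integer(gend),
                            utr3_start = as.integer(u3[1]), utr3_end = as.integer(u3[2]),
                            n_exons = as.integer(n_exon))
      exons[[gi]] <- tibble(gene_id = id, exon_number = seq_len(n_exon),
                            start = as.integer(starts), end = as.integer(ends))
      cursor <- gend
    }
  }
  list(genes = bind_rows(genes), exons = bind_rows(exons))
}

simulate_mirnas <- function(n_mirnas) {
  out <- tibble(mirna_id = character(), sequence = character(), seed = character())
  seen <- character()
  i <- 0L
  while (nrow(out) < n_mirnas) {
    i <- i + 1L
    if (i > 50L * max(n_mirnas, 1L)) abort("could not draw miRNAs with distinct seeds")
    s <- random_dna(sample(21:23, 1))
    sd <- substr(s, 2, 8)
    if (sd %in% seen) next
    seen <- c(seen, sd)
    out <- bind_rows(out, tibble(mirna_id = sprintf("mir%03d", nrow(out) + 1L),
                                 sequence = s, seed = sd))
  }
  out
}

place_circs <- function(genes, exons, chrom_names, chrom_length, n_circ,
                        type_mix, min_circ_len) {
  empty <- tibble(circ_id = character(), chrom = character(), strand = character(),
                  start = integer(), end = integer(), circ_type = character())
  if (n_circ == 0) return(empty)
  type_mix <- type_mix[type_mix > 0]
  types <- sample(names(type_mix), n_circ, replace = TRUE, prob = type_mix)
  rows <- list()
  seen_junc <- character()
  for (i in seq_len(n_circ)) {
    row <- NULL
    for (try in 1:200) {
      row <- try_place_circ(types[i], genes, exons, chrom_names, chrom_length,
                            min_circ_len)
      if (is.null(row)) next
      key <- paste(row$chrom, row$start, row$end)
      if (!key %in% seen_junc) break
      row <- NULL
    }
    if (is.null(row)) {
      abort(sprintf("capacity: could not place a '%s' circRNA after bounded retries",
                    types[i]), class = "cernakit_capacity_error")
    }
    seen_junc <- c(seen_junc, paste(row$chrom, row$start, row$end))
    row$circ_id <- sprintf("circ%03d", i)
    rows[[i]] <- row
  }
  bind_rows(rows) |> select("circ_id", "chrom", "strand", "start", "end", "circ_type")
}

try_place_circ <- function(type, genes, exons, chrom_names, chrom_length,
                           min_circ_len) {
  pick_gene <- function(min_exons = 1) {
    g <- genes[genes$n_exons >= min_exons, ]
    if (nrow(g) == 0) return(NULL)
    g[sample(nrow(g), 1), ]
  }
  if (type == "annot-exon") {
    g <- pick_gene(2); if (is.null(g)) return(NULL)
    ex <- exons[exons$gene_id == g$gene_id, ]
    i <- sample(rep(seq_len(nrow(ex) - 1L), 2), 1)
    j <- sample(rep((i + 1L):nrow(ex), 2), 1)
    a <- ex$start[i]; d <- ex$end[j]
  } else if (type == "one-exon") {
    g <- pick_gene(); ex <- exons[exons$gene_id == g$gene_id, ]
    big <- ex[ex$end - ex$start >= min_circ_len, ]
    if (nrow(big) == 0) return(NULL)
    k <- sample(nrow(big), 1)
    a <- big$start[k]; d <- big$end[k]
  } else if (type == "exon-intron") {
    g <- pick_gene(2); if (is.null(g)) return(NULL)
    ex <- exons[exons$gene_id == g$gene_id, ]
    i <- sample(seq_len(nrow(ex) - 1L), 1)
    a <- ex$start[i]
    d <- ex$start[i + 1L] + 60L   # ends inside the next exon: no boundary match
  } else if (type == "intron") {
    g <- pick_gene(2); if (is.null(g)) return(NULL)
    ex <- exons[exons$gene_id == g$gene_id, ]
    istart <- head(ex$end, -1); iend <- tail(ex$start, -1)
    ok <- which(iend - istart >= min_circ_len + 10L)
    if (length(ok) == 0) return(NULL)
    k <- sample(rep(ok, 2), 1)
    a <- istart[k] + 5L; d <- a + min_circ_len
  } else if (type == "antisense") {
    g <- pick_gene(); if (is.null(g)) return(NULL)
    span <- g$end - g$start
    if (span < min_circ_len + 40L) return(NULL)
    a <- g$start + sample(10:(span - min_circ_len - 10L), 1)
    d <- a + min_circ_len
    return(tibble(chrom = g$chrom, strand = ifelse(g$strand == "+", "-", "+"),
                  start = as.integer(a), end = as.integer(d), circ_type = type))
  } else if (type == "intergenic") {
    ch <- sample(chrom_names, 1)
    g <- genes[genes$chrom == ch, ]
    bounds <- sort(c(150L, g$start, g$end, chrom_length - 150L))
    gaps_lo <- bounds[seq(1, length(bounds), by = 2)]
    gaps_hi <- bounds[seq(2, length(bounds), by = 2)]
    ok <- which(gaps_hi - gaps_lo >= min_circ_len + 40L)
    if (length(ok) == 0) return(NULL)
    k <- sample(rep(ok, 2), 1)
    a <- gaps_lo[k] + 20L; d <- a + min_circ_len
    return(tibble(chrom = ch, strand = sample(c("+", "-"), 1),
                  start = as.integer(a), end = as.integer(d), circ_type = type))
  } else {
    abort(paste0("unknown circRNA type: ", type))
  }
  if (d - a < min_circ_len) return(NULL)
  tibble(chrom = g$chrom, strand = g$strand, start = as.integer(a),
         end = as.integer(d), circ_type = type)
}

#' Spliced 3'UTR sequences of simulated genes
#'
#' @param ref A `cerna_reference`.
#' @return Tibble with `gene_id` and the 3'UTR `sequence` read 5' to 3' on the
#'   gene strand.
#' @export
utr3_sequences <- function(ref) {
  stopifnot(inherits(ref, "cerna_reference"))
  g <- ref$genes
  if (nrow(g) == 0) return(tibble(gene_id = character(), sequence = character()))
  seqs <- vapply(seq_len(nrow(g)), function(i) {
    s <- seq_slice(ref$genome[[g$chrom[i]]], g$utr3_start[i], g$utr3_end[i])
    if (g$strand[i] == "-") revcomp(s) else s
  }, character(1))
  tibble(gene_id = g$gene_id, sequence = seqs)
}

#' Circular sequences of planted circRNAs
#'
#' The circle is the genomic span between acceptor and donor, read 5' to 3'
#' on the circle's strand. Full-length isoform splicing is deliberately not
#' modelled; exon structure is used only for type classification.
#'
#' @param ref A `cerna_reference`.
#' @return Tibble with `circ_id` and `sequence`.
#' @export
circ_sequences <- function(ref) {
  stopifnot(inherits(ref, "cerna_reference"))
  cc <- ref$circs
  if (nrow(cc) == 0) return(tibble(circ_id = character(), sequence = character()))
  seqs <- vapply(seq_len(nrow(cc)), function(i) {
    s <- seq_slice(ref$genome[[cc$chrom[i]]], cc$start[i], cc$end[i])
    if (cc$strand[i] == "-") revcomp(s) else s
  }, character(1))
  tibble(circ_id = cc$circ_id, sequence = seqs)
}

#' @export
print.cerna_reference <- function(x, ...) {
  cat("<cerna_reference>\n")
  cat(sprintf("  genome : %d chromosome(s), %s nt total\n", length(x$genome),
              format(sum(nchar(x$genome)), big.mark = ",")))
  cat(sprintf("  genes  : %d (with %d exons)\n", nrow(x$genes), nrow(x$exons)))
  cat(sprintf("  miRNAs : %d\n", nrow(x$mirnas)))
  cat(sprintf("  circRNAs: %d planted\n", nrow(x$circs)))
  invisible(x)
}
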