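test_that("anchors are the terminal 20-mers; short reads are skipped", {
  rd <- paste0(strrep("A", 20), strrep("C", 20))
  a <- extract_anchors(rd)
  expect_identical(a$left, strrep("A", 20))
  expect_identical(a$right, strrep("C", 20))
  expect_null(extract_anchors(substr(rd, 1, 39)))

  w <- handmade_world()
  reads <- tibble::tibble(read_id = "r1", sample_id = "C1",
                          sequence = substr(w$genome[["chr1"]], 1, 30))
  expect_warning(calls <- detect_circrnas(reads, w$genome), "skipped 1")
  expect_equal(attr(calls, "n_skipped_short"), 1)
  expect_equal(nrow(calls), 0)
})

test_that("anchors built from two known 20-mers map back to their loci", {
  w <- handmade_world()
  x <- substr(w$genome[["chr1"]], 101, 120)   # 0-based 100
  y <- substr(w$genome[["chr1"]], 901, 920)   # 0-based 900
  a <- extract_anchors(paste0(x, y))
  hx <- map_anchor(a$left, w$genome)
  hy <- map_anchor(a$right, w$genome)
  expect_equal(hx$position, 100)
  expect_equal(hy$position, 900)
  expect_true(hx$unique && hy$unique)
  expect_identical(hx$strand, "+")
})

test_that("anchor uniqueness counts hits across both strands", {
  g <- c(chr1 = paste0(strrep("A", 60), random_dna_str(200)))
  many <- map_anchor(strrep("A", 20), g)
  expect_gt(nrow(many), 1)
  expect_false(any(many$unique))
  ## a minus-strand-only hit is found via the reverse complement
  set.seed(1)
  probe <- random_dna_str(20)
  g2 <- c(chr1 = paste0(random_dna_str(100), oracle_revcomp(probe),
                        random_dna_str(100)))
  h <- map_anchor(probe, g2)
  expect_equal(nrow(h), 1)
  expect_identical(h$strand, "-")
  expect_true(h$unique)
  ## absent anchor: empty result, not an error
  expect_equal(nrow(map_anchor(strrep("ACGT", 5), c(chr1 = strrep("G", 100)))), 0)
})

test_that("a junction read is called at the planted coordinates", {
  w <- handmade_world()
  for (p in c(20, 37, 80)) {
    rd <- handmade_junction_read(w, p = p)
    j <- call_backsplice(rd, w$genome)
    expect_equal(j$start, w$start)
    expect_equal(j$end, w$end)
    expect_identical(j$strand, "+")
  }
  ## the reverse-complemented read yields the same junction on the minus strand
  j2 <- call_backsplice(oracle_revcomp(handmade_junction_read(w, 40)), w$genome)
  expect_equal(j2$start, w$start)
  expect_equal(j2$end, w$end)
  expect_identical(j2$strand, "-")
})

test_that("linear and cross-chromosome reads are not called", {
  w <- handmade_world()
  lin <- substr(w$genome[["chr1"]], 601, 700)
  expect_null(call_backsplice(lin, w$genome))
  expect_null(call_backsplice(oracle_revcomp(lin), w$genome))

  set.seed(2)
  g2 <- c(w$genome, chr2 = random_dna_str(1000))
  cross <- paste0(substr(g2[["chr2"]], 101, 150), substr(g2[["chr1"]], 901, 950))
  expect_null(call_backsplice(cross, g2))
})

test_that("support counts distinct read sequences per sample", {
  w <- handmade_world()
  r1 <- handmade_junction_read(w, 30)
  r2 <- handmade_junction_read(w, 55)
  mk <- function(seqs, samples) {
    tibble::tibble(read_id = sprintf("r%d", seq_along(seqs)),
                   sample_id = samples, sequence = seqs)
  }
  ## two distinct junction sequences in one sample: kept (boundary, = 2)
  kept <- detect_circrnas(mk(c(r1, r2), c("G1", "G1")), w$genome)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$max_support, 2)
  ## three copies of one sequence: support 1, dropped
  dup <- detect_circrnas(mk(rep(r1, 3), rep("G1", 3)), w$genome)
  expect_equal(nrow(dup), 0)
  ## one read in each of ten samples: dropped per-sample, kept pooled
  ten <- mk(vapply(21:30, function(p) handmade_junction_read(w, p), character(1)),
            paste0("S", 1:10))
  expect_equal(nrow(detect_circrnas(ten, w$genome)), 0)
  pooled <- detect_circrnas(ten, w$genome, per_sample = FALSE)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$pooled_support, 10)
})

test_that("classifier precedence: a single-exon-equal span is one-exon", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          start = 100L, end = 1000L, utr3_start = 700L,
                          utr3_end = 1000L, n_exons = 2L)
  exons <- tibble::tibble(gene_id = "g1", exon_number = 1:2,
                          start = c(100L, 600L), end = c(400L, 1000L))
  call1 <- tibble::tibble(chrom = "chr1", start = 100L, end = 400L, strand = "+")
  expect_identical(classify_circs(call1, genes, exons), "one-exon")
  call2 <- tibble::tibble(chrom = "chr1", start = 100L, end = 1000L, strand = "+")
  expect_identical(classify_circs(call2, genes, exons), "annot-exon")
  call3 <- tibble::tibble(chrom = "chr1", start = 100L, end = 500L, strand = "+")
  expect_identical(classify_circs(call3, genes, exons), "exon-intron")
  call4 <- tibble::tibble(chrom = "chr1", start = 420L, end = 580L, strand = "+")
  expect_identical(classify_circs(call4, genes, exons), "intron")
  call5 <- tibble::tibble(chrom = "chr1", start = 150L, end = 350L, strand = "-")
  expect_identical(classify_circs(call5, genes, exons), "antisense")
  call6 <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2400L, strand = "+")
  expect_identical(classify_circs(call6, genes, exons), "intergenic")
})

test_that("caller is complete and sound on clean synthetic reads", {
  pl <- tiny_planted(seed = 13)
  cnt <- simulate_counts(pl$truth, seed = 14)
  reads <- simulate_reads(pl$reference, cnt$samples, seed = 15)
  calls <- detect_circrnas(reads, pl$reference$genome, pl$reference$genes,
                           pl$reference$exons)
  ## completeness at exact coordinates
  matched <- match_calls_to_planted(calls, pl$reference$circs)
  expect_setequal(matched$circ_id, pl$reference$circs$circ_id)
  expect_true(all(calls$start < calls$end))
  ## soundness: linear-only reads produce zero calls
  lin <- reads[reads$label == "linear", ]
  expect_equal(nrow(detect_circrnas(lin, pl$reference$genome)), 0)
  ## support matrix is usable downstream
  sup <- circ_support_counts(calls)
  expect_identical(names(sup)[1], "feature_id")
  expect_true(all(as.matrix(sup[, -1]) >= 2 | as.matrix(sup[, -1]) == 0))
})

test_that("every supporting read is reproduced from its doubled segment", {
  pl <- tiny_planted(seed = 16)
  reads <- simulate_reads(pl$reference, sample_sheet(2), seed = 17,
                          linear_reads_per_sample = 20)
  calls <- detect_circrnas(reads, pl$reference$genome)
  for (i in seq_len(nrow(calls))) {
    seg <- substr(pl$reference$genome[[calls$chrom[i]]],
                  calls$start[i] + 1, calls$end[i])
    doubled <- paste0(seg, seg)
    jr <- reads[!is.na(reads$circ_id), ]
    jr <- jr[paste(pl$reference$circs$chrom[match(jr$circ_id,
                                                  pl$reference$circs$circ_id)]) ==
               calls$chrom[i], ]
    hits <- vapply(jr$sequence, function(s) {
      oracle_substring_count(s, doubled) +
        oracle_substring_count(oracle_revcomp(s), doubled)
    }, numeric(1))
    expect_gte(sum(hits > 0), calls$max_support[i])
  }
})
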