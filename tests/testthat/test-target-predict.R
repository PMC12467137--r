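test_that("the seed is positions 2-8 from the 5' end", {
  expect_identical(seed_of("TGAGGTAGTAGGTTGTATAGTT"), "GAGGTAG")
  expect_identical(seed_of("ACGTACGT"), "CGTACGT")
  expect_error(seed_of("ACGTACG"), "at least 8")
})

test_that("seed scan finds sites with correct 8mer/7mer-m8 labels", {
  mir <- "TGAGGTAGTAGGTTGTATAGTT"
  target <- oracle_revcomp(mir)
  hits <- seedmatch_scan(mir, target)
  expect_equal(nrow(hits), 1)
  ## the seed pairs target positions |target| - 8 .. |target| - 2
  expect_equal(hits$position, nchar(target) - 8)

  ## 8mer iff an A faces miRNA position 1
  rc7 <- oracle_revcomp(seed_of(mir))
  t8 <- paste0("CCCCC", rc7, "A", "CCCCC")
  t7 <- paste0("CCCCC", rc7, "G", "CCCCC")
  expect_identical(seedmatch_scan(mir, t8)$site_type, "8mer")
  expect_identical(seedmatch_scan(mir, t7)$site_type, "7mer-m8")

  ## a target without the 7-mer yields nothing
  expect_equal(nrow(seedmatch_scan(mir, strrep("A", 60))), 0)
})

test_that("seed scan counts equal brute-force substring search", {
  set.seed(11)
  for (i in 1:100) {
    mir <- random_dna_str(sample(18:25, 1))
    target <- random_dna_str(sample(30:120, 1))
    got <- nrow(seedmatch_scan(mir, target))
    want <- oracle_substring_count(oracle_revcomp(seed_of(mir)), target)
    expect_equal(got, want)
  }
  ## overlapping occurrences are all reported
  mir2 <- paste0("G", strrep("T", 7), "GGGGGGGGGGGGG")  # seed TTTTTTT
  hits <- seedmatch_scan(mir2, strrep("A", 10))
  expect_equal(nrow(hits), 4)
})

test_that("a perfect duplex scores 5n + 35 with a strict seed", {
  set.seed(12)
  for (n in c(18, 21, 22, 24)) {
    mir <- random_dna_str(n)
    aln <- duplex_align(mir, oracle_revcomp(mir))
    expect_equal(aln$score, 5 * n + 35)
    expect_true(aln$seed_strict)
    gc <- sum(strsplit(mir, "")[[1]] %in% c("G", "C"))
    expect_equal(aln$energy, -3 * gc - 2 * (n - gc))
  }
  ## >= 50% GC over 22 nt implies energy <= -44 (and always <= -2n)
  mir <- paste0(strrep("GC", 6), strrep("AT", 5))
  expect_lte(duplex_align(mir, oracle_revcomp(mir))$energy, -44)
})

test_that("an all-mismatch window scores zero and has no seed pairing", {
  aln <- duplex_align(strrep("A", 20), strrep("A", 30))  # A:A never pairs
  expect_equal(aln$score, 0)
  expect_false(aln$seed_strict)
})

test_that("duplex DP equals exhaustive alignment enumeration on small toys", {
  set.seed(13)
  for (i in 1:12) {
    n <- sample(2:4, 1)
    w <- sample(2:4, 1)
    mir <- random_dna_str(n)
    tgt <- random_dna_str(w)
    expect_equal(duplex_align(mir, tgt)$score, oracle_align_exhaustive(mir, tgt),
                 info = paste(mir, tgt))
  }
})

test_that("duplex DP equals an independent memoised recursion up to 10 nt", {
  set.seed(14)
  for (i in 1:40) {
    n <- sample(5:10, 1)
    w <- sample(5:10, 1)
    mir <- random_dna_str(n)
    tgt <- random_dna_str(w)
    expect_equal(duplex_align(mir, tgt)$score, oracle_align_memo(mir, tgt),
                 info = paste(mir, tgt))
  }
  ## and the memoised oracle agrees with pure enumeration where both run
  set.seed(15)
  for (i in 1:8) {
    mir <- random_dna_str(4); tgt <- random_dna_str(4)
    expect_equal(oracle_align_memo(mir, tgt), oracle_align_exhaustive(mir, tgt))
  }
})

test_that("the aligner filter applies score, energy and strict-seed rules", {
  mirnas <- tibble::tibble(mirna_id = "m1", sequence = random_dna_str(22))
  set.seed(16)
  mirnas$sequence <- "TGAGGTAGTAGGTTGTATAGTT"
  perfect <- tibble::tibble(target_id = "t1",
                            sequence = paste0("CCACC", oracle_revcomp(mirnas$sequence), "CCAGG"))
  kept <- predict_miranda(mirnas, perfect)
  expect_equal(nrow(kept), 1)           # score 145, energy well below -10
  expect_gte(kept$score, 140)

  ## one G:U in the seed: rejected regardless of score (strict seed)
  site <- oracle_revcomp(mirnas$sequence)
  ## miRNA position 5 is G; make its facing base T -> G:T wobble in the seed
  stopifnot(substr(mirnas$sequence, 5, 5) == "G")
  pos_in_site <- nchar(site) - 5 + 1
  gu_site <- paste0(substr(site, 1, pos_in_site - 1), "T",
                    substr(site, pos_in_site + 1, nchar(site)))
  gu <- tibble::tibble(target_id = "t2",
                       sequence = paste0("CCACC", gu_site, "CCAGG"))
  expect_equal(nrow(predict_miranda(mirnas, gu)), 0)

  ## score below threshold: a 20-nt miRNA's perfect site scores 135 < 140
  m20 <- tibble::tibble(mirna_id = "m2", sequence = substr(mirnas$sequence, 1, 20))
  t20 <- tibble::tibble(target_id = "t3",
                        sequence = paste0("CCACC", oracle_revcomp(m20$sequence), "CCAGG"))
  expect_equal(duplex_align(m20$sequence, oracle_revcomp(m20$sequence))$score, 135)
  expect_equal(nrow(predict_miranda(m20, t20)), 0)
  expect_equal(nrow(predict_miranda(m20, t20, score_thr = 135)), 1)
  ## energy threshold is an upper bound (more negative passes)
  expect_equal(nrow(predict_miranda(mirnas, perfect, energy_thr = -100)), 0)
})

test_that("circular targets are scanned across the junction, positions mod L", {
  mir <- "TGAGGTAGTAGGTTGTATAGTT"
  site <- oracle_revcomp(mir)
  ## split the site across the end/start of the circle
  left <- substr(site, 1, 10)
  right <- substr(site, 11, nchar(site))
  circ <- tibble::tibble(target_id = "c1",
                         sequence = paste0(right, strrep("C", 40), left))
  mirnas <- tibble::tibble(mirna_id = "m1", sequence = mir)
  hits <- predict_miranda(mirnas, circ, target_kind = "circ")
  expect_equal(nrow(hits), 1)
  expect_lt(hits$position, nchar(circ$sequence))
  ## the same site is absent when the sequence is treated as linear
  expect_equal(nrow(predict_miranda(mirnas, circ, target_kind = "utr3")), 0)
})

test_that("pair-level intersection keeps pairs found by both predictors", {
  mk <- function(mirna, target, kind, src, pos = 0) {
    tibble::tibble(mirna_id = mirna, target_id = target, target_kind = kind,
                   position = as.integer(pos), site_type = "7mer-m8",
                   score = 145, energy = -40, source = src)
  }
  mir_sites <- dplyr::bind_rows(mk("m1", "t1", "utr3", "miranda", 5),
                                mk("m2", "t2", "utr3", "miranda", 9))
  seed_sites <- dplyr::bind_rows(mk("m1", "t1", "utr3", "seedmatch", 50),
                                 mk("m3", "t3", "utr3", "seedmatch", 2))
  out <- intersect_predictions(mir_sites, seed_sites)
  expect_equal(nrow(out$pairs), 1)                 # only m1/t1 is in both
  expect_identical(out$pairs$mirna_id, "m1")
  expect_true(all(out$sites$source == "both"))
  ## disjoint site positions on the same pair still intersect at pair level
  expect_equal(out$sites$position, 5L)
})

test_that("planted target pairs are recovered and predictions are seed-sound", {
  pl <- tiny_planted(seed = 21, n_triples = 2)
  ref <- pl$reference
  tg <- predict_targets(ref$mirnas, utr3_sequences(ref), circ_sequences(ref))
  key <- function(x) paste(x$mirna_id, x$target_id, x$target_kind)
  expect_true(all(key(pl$truth$target_pairs) %in% key(tg$pairs)))
  ## intersected pairs are a subset of seed-match pairs
  sm <- dplyr::bind_rows(
    predict_seedmatch(ref$mirnas, dplyr::rename(utr3_sequences(ref), target_id = "gene_id"), "utr3"),
    predict_seedmatch(ref$mirnas, dplyr::rename(circ_sequences(ref), target_id = "circ_id"), "circ"))
  expect_true(all(key(tg$pairs) %in% key(sm)))
  ## soundness: every predicted pair has a seed reverse complement occurrence
  seqs <- c(setNames(utr3_sequences(ref)$sequence, utr3_sequences(ref)$gene_id),
            setNames(circ_sequences(ref)$sequence, circ_sequences(ref)$circ_id))
  mir <- setNames(ref$mirnas$sequence, ref$mirnas$mirna_id)
  for (i in seq_len(nrow(tg$pairs))) {
    p <- tg$pairs[i, ]
    subject <- seqs[[p$target_id]]
    if (p$target_kind == "circ") subject <- paste0(subject, subject)
    expect_gte(oracle_substring_count(oracle_revcomp(seed_of(mir[[p$mirna_id]])),
                                      subject), 1)
  }
})
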