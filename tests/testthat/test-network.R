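expr_tbl <- function(rows, samples = paste0("s", seq_len(ncol(rows)))) {
  m <- as.matrix(rows)
  colnames(m) <- samples
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(rows)),
                   tibble::as_tibble(m))
}

## five-sample toy where (c1, m1) has Spearman exactly -0.5:
## ranks x = 1..5 against y = (4, 5, 1, 2, 3): sum d^2 = 30, rho = 1 - 180/120
toy_exprs <- function(mir_vals) {
  circ <- matrix(c(10, 20, 30, 40, 50), 1, dimnames = list("c1"))
  mir <- matrix(mir_vals, 1, dimnames = list("m1"))
  mrna <- matrix(c(11, 21, 31, 41, 51), 1, dimnames = list("g1"))
  list(circ = expr_tbl(circ), mir = expr_tbl(mir), mrna = expr_tbl(mrna))
}

pairs_all <- tibble::tibble(mirna_id = c("m1", "m1"),
                            target_id = c("c1", "g1"),
                            target_kind = c("circ", "utr3"))

test_that("an SCC of exactly -0.5 is rejected (strict less-than)", {
  e <- toy_exprs(c(40, 50, 10, 20, 30))
  expect_equal(spearman_edge(c(10, 20, 30, 40, 50), c(40, 50, 10, 20, 30))$rho, -0.5)
  edges <- build_edges(pairs_all, e$circ, e$mir, e$mrna, p_scope = "pcc")
  expect_equal(nrow(edges$circ_mir), 0)
  ## strictly below -0.5 passes (with the p filter confined to the PCC leg)
  e2 <- toy_exprs(c(50, 40, 30, 20, 10))
  edges2 <- build_edges(pairs_all, e2$circ, e2$mir, e2$mrna, p_scope = "pcc")
  expect_equal(nrow(edges2$circ_mir), 1)
})

test_that("a PCC at the threshold is rejected, strictly above passes", {
  e <- toy_exprs(c(50, 40, 30, 20, 10))
  r <- pearson_edge(c(10, 20, 30, 40, 50), c(11, 21, 31, 41, 51))$r
  expect_equal(r, 1)
  edges_at <- build_edges(pairs_all, e$circ, e$mir, e$mrna, pcc_thr = r,
                          p_scope = "pcc")
  expect_equal(nrow(edges_at$circ_mrna), 0)     # coefficient == threshold
  edges_below <- build_edges(pairs_all, e$circ, e$mir, e$mrna, pcc_thr = 0.99,
                             p_scope = "pcc")
  expect_equal(nrow(edges_below$circ_mrna), 1)
})

test_that("the p filter scope covers all edges by default", {
  ## rho = -0.7: passes the SCC cut but p(n=5) ~ 0.19, so 'all' drops it
  x <- c(10, 20, 30, 40, 50)
  y <- c(30, 50, 40, 20, 10)
  rho <- spearman_edge(x, y)$rho
  expect_lt(rho, -0.5)
  expect_gt(spearman_edge(x, y)$p, 0.05)
  e <- toy_exprs(y)
  strict <- build_edges(pairs_all, e$circ, e$mir, e$mrna, p_scope = "all")
  lax <- build_edges(pairs_all, e$circ, e$mir, e$mrna, p_scope = "pcc")
  expect_equal(nrow(strict$circ_mir), 0)
  expect_equal(nrow(lax$circ_mir), 1)
})

test_that("missing expression rows are skipped, not fatal", {
  e <- toy_exprs(c(50, 40, 30, 20, 10))
  pairs2 <- dplyr::bind_rows(pairs_all,
                             tibble::tibble(mirna_id = "m9", target_id = "c1",
                                            target_kind = "circ"))
  edges <- build_edges(pairs2, e$circ, e$mir, e$mrna, p_scope = "pcc")
  expect_equal(attr(edges, "n_skipped"), 1)
})

test_that("triples require all three legs", {
  mk_edges <- function(drop = NULL) {
    e <- list(
      circ_mir = tibble::tibble(circ_id = "c1", mirna_id = "m1", method = "spearman",
                                coefficient = -0.9, p_value = 0.001, n = 10),
      mir_mrna = tibble::tibble(mirna_id = "m1", mrna_id = "g1", method = "spearman",
                                coefficient = -0.8, p_value = 0.002, n = 10),
      circ_mrna = tibble::tibble(circ_id = "c1", mrna_id = "g1", method = "pearson",
                                 coefficient = 0.9, p_value = 0.003, n = 10))
    if (!is.null(drop)) e[[drop]] <- e[[drop]][0, ]
    structure(e, class = "cerna_edges")
  }
  expect_equal(nrow(assemble_triples(mk_edges())), 1)
  expect_equal(nrow(assemble_triples(mk_edges("circ_mrna"))), 0)
  expect_equal(nrow(assemble_triples(mk_edges("circ_mir"))), 0)
})

test_that("join-based assembly equals brute-force triple enumeration", {
  set.seed(41)
  for (rep in 1:5) {
    cm <- tibble::tibble(
      circ_id = sample(paste0("c", 1:20), 60, replace = TRUE),
      mirna_id = sample(paste0("m", 1:20), 60, replace = TRUE)) |>
      dplyr::distinct() |>
      dplyr::mutate(method = "spearman", coefficient = -0.8, p_value = 0.01, n = 10)
    mg <- tibble::tibble(
      mirna_id = sample(paste0("m", 1:20), 60, replace = TRUE),
      mrna_id = sample(paste0("g", 1:20), 60, replace = TRUE)) |>
      dplyr::distinct() |>
      dplyr::mutate(method = "spearman", coefficient = -0.7, p_value = 0.01, n = 10)
    cg <- tibble::tibble(
      circ_id = sample(paste0("c", 1:20), 60, replace = TRUE),
      mrna_id = sample(paste0("g", 1:20), 60, replace = TRUE)) |>
      dplyr::distinct() |>
      dplyr::mutate(method = "pearson", coefficient = 0.9, p_value = 0.01, n = 10)
    edges <- structure(list(circ_mir = cm, mir_mrna = mg, circ_mrna = cg),
                       class = "cerna_edges")
    got <- assemble_triples(edges)
    want <- oracle_triples(cm, mg, cg)
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$circ_id, got$mirna_id, got$mrna_id),
                    paste(want$circ_id, want$mirna_id, want$mrna_id))
    ## deterministic lexicographic order
    expect_identical(got$circ_id, sort(got$circ_id))
  }
})

test_that("network export writes consistent Sankey, TSV and GraphML files", {
  triples <- structure(
    tibble::tibble(circ_id = c("c1", "c1"), mirna_id = c("m1", "m2"),
                   mrna_id = c("g1", "g1"),
                   scc_circ_mir = c(-0.9, -0.8), scc_mir_mrna = c(-0.85, -0.7),
                   pcc_circ_mrna = c(0.9, 0.9),
                   p_circ_mir = 0.01, p_mir_mrna = 0.01, p_circ_mrna = 0.01),
    class = c("cerna_triples", class(tibble::tibble())))
  out <- withr::local_tempdir()
  paths <- export_network(triples, out)
  sank <- jsonlite::read_json(paths$sankey, simplifyVector = TRUE)
  expect_equal(nrow(sank$nodes), 4)     # c1, m1, m2, g1
  expect_equal(nrow(sank$links), 4)     # 2 sponge legs per triple
  g <- igraph::read_graph(paths$graphml, format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 4)
  tsv <- readr::read_tsv(paths$triples, show_col_types = FALSE)
  expect_equal(nrow(tsv), 2)

  ## duplicates collapse; an empty network still writes valid files
  dup <- triples[c(1, 1, 2), ]
  expect_equal(nrow(readr::read_tsv(export_network(dup, out)$triples,
                                    show_col_types = FALSE)), 2)
  expect_warning(paths0 <- export_network(triples[0, ], out), "empty")
  expect_equal(nrow(readr::read_tsv(paths0$triples, show_col_types = FALSE)), 0)
})

test_that("one triple yields two Sankey links and three nodes", {
  triples <- structure(
    tibble::tibble(circ_id = "c1", mirna_id = "m1", mrna_id = "g1",
                   scc_circ_mir = -0.9, scc_mir_mrna = -0.85, pcc_circ_mrna = 0.9,
                   p_circ_mir = 0.01, p_mir_mrna = 0.01, p_circ_mrna = 0.01),
    class = c("cerna_triples", class(tibble::tibble())))
  out <- withr::local_tempdir()
  sank <- jsonlite::read_json(export_network(triples, out)$sankey,
                              simplifyVector = TRUE)
  expect_equal(nrow(sank$nodes), 3)
  expect_equal(nrow(sank$links), 2)
})
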