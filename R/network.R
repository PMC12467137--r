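#' Correlation-filtered candidate edges for a ceRNA network
#'
#' For every predicted (miRNA, circRNA) and (miRNA, mRNA) target pair the
#' Spearman correlation across all samples (both groups pooled) is computed
#' on normalized expression; sponge edges are kept iff `SCC < scc_thr`
#' (strictly) and, with `p_scope = "all"`, `p < p_thr`. circRNA-mRNA pairs
#' are formed for every (circ, mRNA) sharing at least one candidate miRNA and
#' kept iff `PCC > pcc_thr` (strictly) and `p < p_thr`.
#'
#' @param pairs Predicted target pairs tibble (`mirna_id`, `target_id`,
#'   `target_kind` in `utr3`/`circ`), e.g. from [predict_targets()].
#' @param expr_circ,expr_mir,expr_mrna Normalized expression tibbles
#'   (`feature_id` + one column per sample).
#' @param scc_thr Spearman threshold (default -0.5).
#' @param pcc_thr Pearson threshold (default 0.7).
#' @param p_thr P-value threshold (default 0.05).
#' @param p_scope Apply the p filter to all three edge types (`"all"`,
#'   default) or to the Pearson leg only (`"pcc"`).
#' @return A `cerna_edges` list of tibbles `circ_mir`, `mir_mrna`,
#'   `circ_mrna` (node ids, `method`, `coefficient`, `p_value`, `n`), with
#'   skipped-pair counts as attributes.
#' @export
build_edges <- function(pairs, expr_circ, expr_mir, expr_mrna,
                        scc_thr = -0.5, pcc_thr = 0.7, p_thr = 0.05,
                        p_scope = c("all", "pcc")) {
  p_scope <- match.arg(p_scope)
  mat <- list(circ = counts_to_matrix(expr_circ),
              mirna = counts_to_matrix(expr_mir),
              mrna = counts_to_matrix(expr_mrna))
  common <- Reduce(intersect, lapply(mat, colnames))
  mat <- lapply(mat, function(m) m[, common, drop = FALSE])
  n <- length(common)
  n_skipped <- 0L

  edge_for <- function(a_cls, a_id, b_cls, b_id, method) {
    if (!a_id %in% rownames(mat[[a_cls]]) || !b_id %in% rownames(mat[[b_cls]])) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    x <- mat[[a_cls]][a_id, ]; y <- mat[[b_cls]][b_id, ]
    res <- if (method == "spearman") spearman_edge(x, y) else pearson_edge(x, y)
    if (is.null(res)) { n_skipped <<- n_skipped + 1L; return(NULL) }
    tibble(node_a = a_id, node_b = b_id, method = method,
           coefficient = res[[1]], p_value = res$p, n = n)
  }

  sponge <- function(kind, cls) {
    cand <- pairs[pairs$target_kind == kind, , drop = FALSE]
    out <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
      e <- edge_for(cls, cand$target_id[i], "mirna", cand$mirna_id[i], "spearman")
      if (is.null(e)) return(NULL)
      e |> rename(!!paste0(cls, "_id") := "node_a", mirna_id = "node_b")
    })
    if (nrow(out) == 0) return(out)
    keep <- out$coefficient < scc_thr
    if (p_scope == "all") keep <- keep & out$p_value < p_thr
    out[keep, , drop = FALSE]
  }
  circ_mir <- sponge("circ", "circ")
  mir_mrna <- sponge("utr3", "mrna")

  cm <- inner_join(
    pairs[pairs$target_kind == "circ", c("mirna_id", "target_id")] |>
      rename(circ_id = "target_id"),
    pairs[pairs$target_kind == "utr3", c("mirna_id", "target_id")] |>
      rename(mrna_id = "target_id"),
    by = "mirna_id", relationship = "many-to-many") |>
    distinct(.data$circ_id, .data$mrna_id)
  circ_mrna <- purrr::map_dfr(seq_len(nrow(cm)), function(i) {
    e <- edge_for("circ", cm$circ_id[i], "mrna", cm$mrna_id[i], "pearson")
    if (is.null(e)) return(NULL)
    e |> rename(circ_id = "node_a", mrna_id = "node_b")
  })
  if (nrow(circ_mrna) > 0) {
    circ_mrna <- circ_mrna[circ_mrna$coefficient > pcc_thr &
                             circ_mrna$p_value < p_thr, , drop = FALSE]
  }

  structure(list(circ_mir = circ_mir, mir_mrna = mir_mrna,
                 circ_mrna = circ_mrna),
            class = "cerna_edges", n_skipped = n_skipped)
}

#' Assemble ceRNA triples from filtered edges
#'
#' A triple (circ, miR, mRNA) is emitted iff all three edges exist: the two
#' negative sponge legs sharing the miRNA and the positive circRNA-mRNA leg.
#' Output is deduplicated and ordered lexicographically by (circ, miRNA,
#' mRNA).
#'
#' @param edges A `cerna_edges` list from [build_edges()].
#' @return A `cerna_triples` tibble: ids, `scc_circ_mir`, `scc_mir_mrna`,
#'   `pcc_circ_mrna` and the three p-values.
#' @export
assemble_triples <- function(edges) {
  empty <- tibble(circ_id = character(), mirna_id = character(),
                  mrna_id = character(), scc_circ_mir = numeric(),
                  scc_mir_mrna = numeric(), pcc_circ_mrna = numeric(),
                  p_circ_mir = numeric(), p_mir_mrna = numeric(),
                  p_circ_mrna = numeric())
  if (nrow(edges$circ_mir) == 0 || nrow(edges$mir_mrna) == 0 ||
      nrow(edges$circ_mrna) == 0) {
    return(structure(empty, class = c("cerna_triples", class(empty))))
  }
  out <- edges$circ_mir |>
    select("circ_id", "mirna_id", scc_circ_mir = "coefficient",
           p_circ_mir = "p_value") |>
    inner_join(edges$mir_mrna |>
                 select("mirna_id", "mrna_id", scc_mir_mrna = "coefficient",
                        p_mir_mrna = "p_value"),
               by = "mirna_id", relationship = "many-to-many") |>
    inner_join(edges$circ_mrna |>
                 select("circ_id", "mrna_id", pcc_circ_mrna = "coefficient",
                        p_circ_mrna = "p_value"),
               by = c("circ_id", "mrna_id")) |>
    distinct(.data$circ_id, .data$mirna_id, .data$mrna_id, .keep_all = TRUE) |>
    arrange(.data$circ_id, .data$mirna_id, .data$mrna_id) |>
    select("circ_id", "mirna_id", "mrna_id", "scc_circ_mir", "scc_mir_mrna",
           "pcc_circ_mrna", "p_circ_mir", "p_mir_mrna", "p_circ_mrna")
  structure(out, class = c("cerna_triples", class(out)))
}

#' Export a ceRNA network
#'
#' Writes an edge-list TSV, a triples TSV, a GraphML graph and a Sankey-ready
#' JSON (nodes in three columns circRNA -> miRNA -> mRNA; link weight is the
#' absolute correlation).
#'
#' @param triples A `cerna_triples` tibble.
#' @param outdir Output directory.
#' @return Named list of written paths, invisibly.
#' @export
export_network <- function(triples, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  triples <- distinct(as_tibble(triples))
  if (nrow(triples) == 0) warn("empty ceRNA network: writing valid empty files")

  paths <- list(triples = file.path(outdir, "triples.tsv"),
                edges = file.path(outdir, "edges.tsv"),
                graphml = file.path(outdir, "network.graphml"),
                sankey = file.path(outdir, "sankey.json"))
  readr::write_tsv(triples, paths$triples)

  edges <- sankey_links(triples)
  readr::write_tsv(edges, paths$edges)

  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "weight", "sign")],
    directed = FALSE,
    vertices = sankey_nodes(triples))
  igraph::write_graph(g, paths$graphml, format = "graphml")

  jsonlite::write_json(list(nodes = sankey_nodes(triples), links = edges),
                       paths$sankey, digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

sankey_nodes <- function(triples) {
  bind_rows(tibble(name = unique(triples$circ_id), column = "circRNA"),
            tibble(name = unique(triples$mirna_id), column = "miRNA"),
            tibble(name = unique(triples$mrna_id), column = "mRNA"))
}

sankey_links <- function(triples) {
  bind_rows(
    triples |> distinct(.data$circ_id, .data$mirna_id, .data$scc_circ_mir) |>
      transmute(source = .data$circ_id, target = .data$mirna_id,
                weight = abs(.data$scc_circ_mir),
                sign = sign(.data$scc_circ_mir)),
    triples |> distinct(.data$mirna_id, .data$mrna_id, .data$scc_mir_mrna) |>
      transmute(source = .data$mirna_id, target = .data$mrna_id,
                weight = abs(.data$scc_mir_mrna),
                sign = sign(.data$scc_mir_mrna)))
}

#' Re-validate assembled triples against thresholds and target pairs
#'
#' Independent validator pass: recomputes both correlation legs from the
#' expression matrices and checks every threshold and the target-pair
#' membership of both sponge legs.
#'
#' @param triples A `cerna_triples` tibble.
#' @param pairs Predicted target-pair tibble.
#' @param expr_circ,expr_mir,expr_mrna Normalized expression tibbles.
#' @inheritParams build_edges
#' @return TRUE invisibly; aborts with the offending triple otherwise.
#' @export
validate_triples <- function(triples, pairs, expr_circ, expr_mir, expr_mrna,
                             scc_thr = -0.5, pcc_thr = 0.7, p_thr = 0.05) {
  mat <- list(circ = counts_to_matrix(expr_circ),
              mirna = counts_to_matrix(expr_mir),
              mrna = counts_to_matrix(expr_mrna))
  pair_key <- paste(pairs$mirna_id, pairs$target_id, pairs$target_kind)
  for (i in seq_len(nrow(triples))) {
    tr <- triples[i, ]
    ok <- paste(tr$mirna_id, tr$circ_id, "circ") %in% pair_key &&
      paste(tr$mirna_id, tr$mrna_id, "utr3") %in% pair_key
    s1 <- spearman_edge(mat$circ[tr$circ_id, ], mat$mirna[tr$mirna_id, ])
    s2 <- spearman_edge(mat$mirna[tr$mirna_id, ], mat$mrna[tr$mrna_id, ])
    p1 <- pearson_edge(mat$circ[tr$circ_id, ], mat$mrna[tr$mrna_id, ])
    ok <- ok && s1$rho < scc_thr && s1$p < p_thr &&
      s2$rho < scc_thr && s2$p < p_thr &&
      p1$r > pcc_thr && p1$p < p_thr
    if (!ok) abort(sprintf("triple %s/%s/%s fails validation",
                           tr$circ_id, tr$mirna_id, tr$mrna_id))
  }
  invisible(TRUE)
}
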