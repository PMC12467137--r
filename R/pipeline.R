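#' Run the full synthetic ceRNA pipeline
#'
#' One call that exercises every stage against planted truth: simulate a
#' reference, plant regulatory triples, simulate counts and junction reads,
#' call circRNAs from the reads, test differential expression per RNA class,
#' predict targets of the differential miRNAs, build correlation-filtered
#' edges and assemble ceRNA triples, then score the result against the
#' planted truth.
#'
#' @param seed Integer seed driving every stage.
#' @param n_genes,n_mirnas,n_circ,n_triples Reference/truth sizes.
#' @param n_per_group Replicates per group.
#' @param dispersion NB dispersion for simulated counts.
#' @param with_reads Simulate reads and run the back-splice caller (TRUE) or
#'   skip straight to counts (FALSE, faster).
#' @param lfc_thr,p_thr DE thresholds.
#' @param scc_thr,pcc_thr,corr_p_thr Network thresholds.
#' @param ... Passed to [simulate_counts()].
#' @return A `cerna_pipeline` list: `reference`, `truth`, `counts`, `calls`,
#'   `de` (per class), `targets`, `edges`, `triples`, `metrics`.
#' @examples
#' \donttest{
#' res <- run_cerna_pipeline(seed = 1, n_genes = 12, n_mirnas = 6,
#'                           n_circ = 5, n_triples = 3)
#' res$metrics
#' }
#' @export
run_cerna_pipeline <- function(seed,
                               n_genes = 30, n_mirnas = 15, n_circ = 12,
                               n_triples = 8, n_per_group = 5,
                               dispersion = 0.05, with_reads = TRUE,
                               lfc_thr = 1, p_thr = 0.05,
                               scc_thr = -0.5, pcc_thr = 0.7,
                               corr_p_thr = 0.05, ...) {
  set.seed(seed)
  ref <- simulate_reference(n_genes = n_genes, n_mirnas = n_mirnas,
                            n_circ = n_circ)
  pl <- plant_regulation(ref, n_triples = n_triples)
  ref <- pl$reference; truth <- pl$truth
  cnt <- simulate_counts(truth, n_per_group = n_per_group,
                         dispersion = dispersion, ...)

  calls <- NULL
  detected_ids <- ref$circs$circ_id
  detection_recall <- NA_real_
  if (with_reads) {
    reads <- simulate_reads(ref, cnt$samples)
    calls <- detect_circrnas(reads, ref$genome, ref$genes, ref$exons)
    matched <- match_calls_to_planted(calls, ref$circs)
    detected_ids <- matched$circ_id[!is.na(matched$circ_id)]
    detection_recall <- length(unique(detected_ids)) / max(nrow(ref$circs), 1)
  }

  ## the simulated panels are small and mostly differential, so normalization
  ## uses the recorded library sizes rather than median-of-ratios
  lib_sf <- lapply(cnt$mapped_totals, function(x) x / exp(mean(log(x))))
  de <- list(
    circ = run_de(cnt$circ |> filter(.data$feature_id %in% detected_ids),
                  cnt$samples, lfc_thr, p_thr, size_factors = lib_sf$circ),
    mirna = run_de(cnt$mirna, cnt$samples, lfc_thr, p_thr,
                   size_factors = lib_sf$mirna),
    mrna = run_de(cnt$mrna, cnt$samples, lfc_thr, p_thr,
                  size_factors = lib_sf$mrna))
  de_ids <- lapply(de, function(x) x$feature_id[x$regulated != "ns"])

  mirnas_de <- ref$mirnas |> filter(.data$mirna_id %in% de_ids$mirna)
  utrs_de <- utr3_sequences(ref) |> filter(.data$gene_id %in% de_ids$mrna)
  circs_de <- circ_sequences(ref) |> filter(.data$circ_id %in% de_ids$circ)
  targets <- predict_targets(mirnas_de, utrs_de, circs_de)

  expr <- list(circ = rpm(cnt$circ, cnt$mapped_totals$circ),
               mirna = tpm_mirna(cnt$mirna),
               mrna = rpm(cnt$mrna, cnt$mapped_totals$mrna))
  edges <- build_edges(targets$pairs, expr$circ, expr$mirna, expr$mrna,
                       scc_thr = scc_thr, pcc_thr = pcc_thr, p_thr = corr_p_thr)
  triples <- assemble_triples(edges)
  metrics <- evaluate_triples(triples, truth)
  metrics$detection_recall <- detection_recall

  structure(list(reference = ref, truth = truth, counts = cnt, calls = calls,
                 de = de, targets = targets, expr = expr, edges = edges,
                 triples = triples, metrics = metrics),
            class = "cerna_pipeline")
}

#' Match circRNA calls to planted circles by exact junction coordinates
#'
#' @param calls A `circ_calls` tibble.
#' @param planted Planted circ tibble (`circ_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @return `calls` with a `circ_id` column replaced by the planted id (NA for
#'   unmatched calls).
#' @export
match_calls_to_planted <- function(calls, planted) {
  if (is.null(calls) || nrow(calls) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), circ_id = character()))
  }
  calls |> select(-"circ_id") |>
    left_join(planted |> select("circ_id", "chrom", "start", "end", "strand"),
              by = c("chrom", "start", "end", "strand"))
}

#' Score assembled triples against planted truth
#'
#' Precision is reported as 1 when no triples are assembled (no false
#' discoveries were made).
#'
#' @param triples A `cerna_triples` tibble.
#' @param truth A `cerna_truth`.
#' @return List with `recall`, `precision`, `n_reported`, `n_planted`.
#' @export
evaluate_triples <- function(triples, truth) {
  key <- function(x) paste(x$circ_id, x$mirna_id, x$mrna_id)
  found <- key(triples); planted <- key(truth$triples)
  tp <- length(intersect(found, planted))
  list(recall = if (length(planted)) tp / length(planted) else NA_real_,
       precision = if (length(found)) tp / length(found) else 1,
       n_reported = length(found), n_planted = length(planted))
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("<cerna_pipeline>\n")
  m <- x$metrics
  cat(sprintf("  planted triples  : %d\n", m$n_planted))
  cat(sprintf("  reported triples : %d\n", m$n_reported))
  cat(sprintf("  recall %.2f / precision %.2f", m$recall, m$precision))
  if (!is.na(m$detection_recall)) {
    cat(sprintf(" / circRNA detection recall %.2f", m$detection_recall))
  }
  cat("\n")
  invisible(x)
}
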