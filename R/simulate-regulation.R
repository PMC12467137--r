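#' Plant ceRNA regulatory structure into a simulated reference
#'
#' Selects `n_triples` disjoint (circRNA, miRNA, mRNA) triples and embeds, for
#' each, the exact reverse complement of the miRNA (Watson-Crick perfect over
#' at least seed positions 2-8) into both the host gene's 3'UTR and the
#' circRNA's circular sequence, so that both target predictors can recover the
#' pair. True log2 fold changes (grazing G over control C) are assigned so
#' that circRNA and mRNA move together (up in G) and the shared miRNA moves in
#' the opposite direction; a background fraction of the remaining features is
#' made differentially expressed with random sign.
#'
#' @param ref A `cerna_reference` from [simulate_reference()].
#' @param n_triples Number of planted triples
#'   (`<= min(n_circ, n_mirnas, n_genes)`).
#' @param site_len Length of the embedded complementary site; `NULL` (default)
#'   embeds the full-length reverse complement of each miRNA.
#' @param planted_lfc Magnitude of the true log2 fold change given to planted
#'   features.
#' @param background_de_prop Fraction of non-planted features that are
#'   differentially expressed (|log2FC| drawn from `background_lfc_range`,
#'   random sign).
#' @param background_lfc_range Range of background |log2FC|.
#' @param junction_margin Planted circRNA sites are kept at least this many nt
#'   away from the back-splice junction so that junction-spanning reads never
#'   overlap an embedded (duplicated) site.
#' @param seed Integer seed.
#' @return A list with the updated `reference` (site-bearing genome) and
#'   `truth`, a `cerna_truth` list: `triples`, `target_pairs`, `features`
#'   (per-feature true log2FC and DE status).
#' @examples
#' ref <- simulate_reference(n_genes = 6, n_mirnas = 4, n_circ = 3, seed = 1)
#' pl <- plant_regulation(ref, n_triples = 2, seed = 2)
#' pl$truth$triples
#' @export
plant_regulation <- function(ref, n_triples,
                             site_len = NULL,
                             planted_lfc = 3,
                             background_de_prop = 0.25,
                             background_lfc_range = c(1.5, 3),
                             junction_margin = 100,
                             seed = NULL) {
  stopifnot(inherits(ref, "cerna_reference"), n_triples >= 0)
  if (n_triples > min(nrow(ref$circs), nrow(ref$mirnas), nrow(ref$genes))) {
    abort("n_triples exceeds min(number of circRNAs, miRNAs, genes)")
  }
  if (!is.null(seed)) set.seed(seed)

  genome <- ref$genome
  ## junction guard: embedded sites must never rewrite the bases flanking a
  ## planted back-splice (genome[a-1], genome[d-1]) or the junction pinning
  ## that makes coordinates unambiguous could be undone for an overlapping
  ## circle
  occupied <- tibble(
    chrom = rep(ref$circs$chrom, 2),
    start = c(ref$circs$start - 1L, ref$circs$end - 1L),
    end = c(ref$circs$start, ref$circs$end))

  triples <- tibble(circ_id = character(), mirna_id = character(),
                    mrna_id = character())
  pairs <- tibble(mirna_id = character(), target_id = character(),
                  target_kind = character())

  if (n_triples > 0) {
    ## planted triples are independent units: a triple gene's UTR must not lie
    ## inside any planted circle, or the embedded UTR site would also be a
    ## circle site and the planted truth would no longer be the whole truth
    utr_clear <- vapply(seq_len(nrow(ref$genes)), function(i) {
      g <- ref$genes[i, ]
      cc <- ref$circs[ref$circs$chrom == g$chrom, ]
      nrow(cc) == 0 || all(cc$end <= g$utr3_start | cc$start >= g$utr3_end)
    }, logical(1))
    eligible <- ref$genes$gene_id[utr_clear]
    if (length(eligible) < n_triples) {
      abort("too few genes with a 3'UTR clear of planted circles for n_triples")
    }
    ## symmetrically, prefer circles with junction-clear body space outside
    ## any 3'UTR for the embedded site
    utr_iv <- tibble(chrom = ref$genes$chrom, start = ref$genes$utr3_start,
                     end = ref$genes$utr3_end)
    site_w <- if (is.null(site_len)) max(nchar(ref$mirnas$sequence)) else site_len
    ## a circle-body site must not fall inside any *other* planted circle
    ## either, or that circle's sequence would also carry the site
    other_span <- function(i) {
      tibble(chrom = ref$circs$chrom[-i], start = ref$circs$start[-i],
             end = ref$circs$end[-i])
    }
    circ_clear <- vapply(seq_len(nrow(ref$circs)), function(i) {
      cc <- ref$circs[i, ]
      !is.na(place_site_try(bind_rows(utr_iv, other_span(i)), cc$chrom,
                            cc$start + junction_margin,
                            cc$end - junction_margin - site_w, site_w))
    }, logical(1))
    circ_pool <- if (sum(circ_clear) >= n_triples) {
      ref$circs$circ_id[circ_clear]
    } else {
      ref$circs$circ_id
    }
    circ_ids <- sample(circ_pool, n_triples)
    mirna_ids <- sample(ref$mirnas$mirna_id, n_triples)
    gene_ids <- sample(eligible, n_triples)
    utr_intervals <- tibble(chrom = ref$genes$chrom,
                            start = ref$genes$utr3_start,
                            end = ref$genes$utr3_end)
    for (t in seq_len(n_triples)) {
      mir <- ref$mirnas[ref$mirnas$mirna_id == mirna_ids[t], ]
      site <- revcomp(if (is.null(site_len)) mir$sequence
                      else substr(mir$sequence, 1, site_len))
      w <- nchar(site)

      ## 3'UTR of the mRNA: write so the strand-aware UTR sequence contains
      ## the site
      g <- ref$genes[ref$genes$gene_id == gene_ids[t], ]
      utr_w <- g$utr3_end - g$utr3_start
      pos_in_utr <- place_site(occupied, g$chrom, g$utr3_start + 4L,
                               g$utr3_end - w - 4L, w)
      occupied <- bind_rows(occupied, tibble(chrom = g$chrom, start = pos_in_utr,
                                             end = pos_in_utr + w))
      genomic_site <- if (g$strand == "-") revcomp(site) else site
      genome[[g$chrom]] <- overwrite_seq(genome[[g$chrom]], genomic_site, pos_in_utr)

      ## circRNA body, away from the junction
      cc <- ref$circs[ref$circs$circ_id == circ_ids[t], ]
      lo <- cc$start + junction_margin
      hi <- cc$end - junction_margin - w
      if (hi < lo) abort("circRNA too short to hold a site clear of the junction")
      ## keep circle sites out of 3'UTRs and out of every other planted
      ## circle, for the same reason; fall back to the junction-clear region
      ## when a circle has no such free space
      ci <- which(ref$circs$circ_id == cc$circ_id)
      pos_in_circ <- place_site_try(
        bind_rows(occupied, utr_intervals, other_span(ci)),
        cc$chrom, lo, hi, w)
      if (is.na(pos_in_circ)) pos_in_circ <- place_site(occupied, cc$chrom, lo, hi, w)
      occupied <- bind_rows(occupied, tibble(chrom = cc$chrom, start = pos_in_circ,
                                             end = pos_in_circ + w))
      genomic_site <- if (cc$strand == "-") revcomp(site) else site
      genome[[cc$chrom]] <- overwrite_seq(genome[[cc$chrom]], genomic_site, pos_in_circ)

      triples <- bind_rows(triples, tibble(circ_id = circ_ids[t],
                                           mirna_id = mirna_ids[t],
                                           mrna_id = gene_ids[t]))
      pairs <- bind_rows(pairs,
                         tibble(mirna_id = mirna_ids[t],
                                target_id = c(gene_ids[t], circ_ids[t]),
                                target_kind = c("utr3", "circ")))
    }
  }

  features <- bind_rows(
    tibble(feature_id = ref$circs$circ_id, class = "circ"),
    tibble(feature_id = ref$mirnas$mirna_id, class = "mirna"),
    tibble(feature_id = ref$genes$gene_id, class = "mrna")
  )
  lfc <- setNames(numeric(nrow(features)), features$feature_id)
  if (n_triples > 0) {
    lfc[triples$circ_id] <- planted_lfc
    lfc[triples$mrna_id] <- planted_lfc
    lfc[triples$mirna_id] <- -planted_lfc
  }
  free <- setdiff(features$feature_id,
                  c(triples$circ_id, triples$mirna_id, triples$mrna_id))
  n_bg <- rbinom(1, length(free), background_de_prop)
  if (n_bg > 0) {
    bg <- sample(free, n_bg)
    lfc[bg] <- sample(c(-1, 1), n_bg, replace = TRUE) *
      runif(n_bg, background_lfc_range[1], background_lfc_range[2])
  }
  features$true_log2fc <- unname(lfc[features$feature_id])
  features$is_de <- abs(features$true_log2fc) >= 1

  ref$genome <- genome
  truth <- structure(list(triples = triples, target_pairs = pairs,
                          features = features),
                     class = "cerna_truth")
  list(reference = ref, truth = truth)
}

## uniform draw of a site start from the explicitly enumerated positions in
## [lo, hi] whose [pos, pos + w) window avoids every interval in `occupied`
place_site_try <- function(occupied, chrom, lo, hi, w) {
  if (hi < lo) return(NA_integer_)
  cand <- seq.int(lo, hi)
  occ <- occupied[occupied$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(occ))) {
    cand <- cand[cand + w <= occ$start[i] | cand >= occ$end[i]]
  }
  if (length(cand) == 0) return(NA_integer_)
  as.integer(sample(rep(cand, 2), 1))
}

place_site <- function(occupied, chrom, lo, hi, w) {
  pos <- place_site_try(occupied, chrom, lo, hi, w)
  if (is.na(pos)) {
    abort("could not embed a binding site without collision")
  }
  pos
}

#' @export
print.cerna_truth <- function(x, ...) {
  cat("<cerna_truth>\n")
  cat(sprintf("  planted triples : %d\n", nrow(x$triples)))
  cat(sprintf("  target pairs    : %d\n", nrow(x$target_pairs)))
  cat(sprintf("  features        : %d (%d truly DE)\n", nrow(x$features),
              sum(x$features$is_de)))
  invisible(x)
}
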