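#' Simulate two-group negative-binomial count matrices with planted structure
#'
#' Draws feature-by-sample counts for the three RNA classes under the standard
#' RNA-seq negative-binomial convention: mean `m`, dispersion `alpha`,
#' variance `m + alpha * m^2`. Group G means are `base_mean * 2^true_log2fc`.
#' For every planted triple one latent log-normal factor per sample multiplies
#' the circRNA and mRNA means and divides the miRNA mean, so the co-expression
#' sign structure a ceRNA correlation filter looks for (circ-miR and miR-mRNA
#' negative, circ-mRNA positive) is present by construction.
#'
#' @param truth A `cerna_truth` from [plant_regulation()].
#' @param n_per_group Biological replicates per group (default 5; groups are
#'   C, control, and G, grazing).
#' @param base_mean_range Range of per-feature base means, drawn log-uniform.
#' @param dispersion NB dispersion `alpha` (> 0).
#' @param sponge_sdlog sdlog of the per-triple, per-sample latent log-normal
#'   sponge factor.
#' @param depth_sdlog sdlog of the per-sample sequencing-depth factor; depth
#'   multiplies every feature mean and sets the recorded mapped totals.
#' @param nominal_depth Nominal mapped reads per sample; the recorded
#'   mapped-read totals are `depth_factor * nominal_depth` (in a real library
#'   the analysed features are a negligible fraction of the total, so totals
#'   are depth-driven, not panel-driven).
#' @param seed Integer seed.
#' @return A `cerna_counts` list: tibbles `circ`, `mirna`, `mrna`
#'   (`feature_id` + one column per sample), a `samples` sheet and per-class
#'   `mapped_totals` (column sums, the per-million denominators).
#' @examples
#' ref <- simulate_reference(n_genes = 6, n_mirnas = 4, n_circ = 3, seed = 1)
#' pl <- plant_regulation(ref, n_triples = 2, seed = 2)
#' cnt <- simulate_counts(pl$truth, seed = 3)
#' cnt$circ
#' @export
simulate_counts <- function(truth,
                            n_per_group = 5,
                            base_mean_range = c(200, 2000),
                            dispersion = 0.05,
                            sponge_sdlog = 0.5,
                            depth_sdlog = 0.15,
                            nominal_depth = 2e7,
                            seed = NULL) {
  stopifnot(inherits(truth, "cerna_truth"), n_per_group >= 2, dispersion > 0,
            length(base_mean_range) == 2, all(base_mean_range > 0))
  if (!is.null(seed)) set.seed(seed)

  samples <- sample_sheet(n_per_group)
  n_s <- nrow(samples)
  is_g <- samples$group == "G"
  feats <- truth$features

  base_mean <- exp(runif(nrow(feats), log(base_mean_range[1]),
                         log(base_mean_range[2])))
  mu <- outer(base_mean, rep(1, n_s)) *
    2^outer(feats$true_log2fc, as.numeric(is_g))
  rownames(mu) <- feats$feature_id

  ## latent sponge factor: one log-normal draw per triple per sample
  if (nrow(truth$triples) > 0) {
    for (t in seq_len(nrow(truth$triples))) {
      f <- rlnorm(n_s, 0, sponge_sdlog)
      tr <- truth$triples[t, ]
      mu[tr$circ_id, ] <- mu[tr$circ_id, ] * f
      mu[tr$mrna_id, ] <- mu[tr$mrna_id, ] * f
      mu[tr$mirna_id, ] <- mu[tr$mirna_id, ] / f
    }
  }

  depth <- rlnorm(n_s, 0, depth_sdlog)
  mu <- sweep(mu, 2, depth, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   nrow = nrow(mu), dimnames = dimnames(mu))

  one_class <- function(cls) {
    m <- counts[feats$class == cls, , drop = FALSE]
    colnames(m) <- samples$sample_id
    matrix_to_counts(m)
  }
  out <- list(circ = one_class("circ"), mirna = one_class("mirna"),
              mrna = one_class("mrna"), samples = samples)
  totals <- setNames(round(depth * nominal_depth), samples$sample_id)
  out$mapped_totals <- list(circ = totals, mirna = totals, mrna = totals)
  structure(out, class = "cerna_counts")
}

#' @export
print.cerna_counts <- function(x, ...) {
  cat("<cerna_counts>\n")
  for (cls in c("circ", "mirna", "mrna")) {
    cat(sprintf("  %-5s : %d features x %d samples\n", cls, nrow(x[[cls]]),
                ncol(x[[cls]]) - 1L))
  }
  invisible(x)
}
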