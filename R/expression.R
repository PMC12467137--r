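#' Reads-per-million normalization
#'
#' `value = count / mapped_total * 1e6`, the normalization used for circRNA
#' junction counts.
#'
#' @param counts Tibble, `feature_id` + one column per sample.
#' @param mapped_totals Named numeric vector of per-sample mapped-read
#'   totals; defaults to the in-matrix column sums.
#' @return Normalized tibble of the same shape (attribute `method = "RPM"`).
#' @export
rpm <- function(counts, mapped_totals = NULL) {
  m <- counts_to_matrix(counts)
  if (is.null(mapped_totals)) mapped_totals <- colSums(m)
  if (!all(colnames(m) %in% names(mapped_totals))) {
    abort("mapped_totals must be named for every sample column")
  }
  mapped_totals <- mapped_totals[colnames(m)]
  if (any(mapped_totals <= 0)) {
    abort(paste0("mapped total must be > 0; offending sample(s): ",
                 paste(colnames(m)[mapped_totals <= 0], collapse = ", ")))
  }
  out <- matrix_to_counts(sweep(m, 2, mapped_totals, "/") * 1e6)
  attr(out, "method") <- "RPM"
  out
}

#' Transcripts-per-million normalization for mature miRNA counts
#'
#' Mature miRNAs are nearly constant in length, so no length term is used:
#' `value = count / column_sum * 1e6` over the counted miRNAs.
#'
#' @param counts Tibble, `feature_id` + one column per sample.
#' @return Normalized tibble (attribute `method = "TPM"`); every column sums
#'   to 1e6.
#' @export
tpm_mirna <- function(counts) {
  m <- counts_to_matrix(counts)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    abort(paste0("all-zero sample(s): ", paste(colnames(m)[cs <= 0], collapse = ", ")))
  }
  out <- matrix_to_counts(sweep(m, 2, cs, "/") * 1e6)
  attr(out, "method") <- "TPM"
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample ratios to the per-feature geometric mean, summarized by the
#' median over features expressed in every sample.
#'
#' @param m Numeric count matrix (features x samples).
#' @return Named numeric vector of size factors.
#' @export
estimate_size_factors <- function(m) {
  keep <- rowSums(m > 0) == ncol(m)
  if (!any(keep)) return(setNames(rep(1, ncol(m)), colnames(m)))
  lg <- log(m[keep, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2, function(x) exp(median(x - ref)))
}

#' Two-group negative-binomial Wald test
#'
#' A compact DE engine for two-group count matrices: median-of-ratios size
#' factors, per-feature method-of-moments NB dispersion (floored at 1e-8),
#' log2 fold change (G over C) from size-factor-normalized group means with a
#' 0.5 pseudo-count, and a two-sided Wald p-value for the difference of log
#' group means, referred to a t distribution with `n1 + n2 - 2` degrees of
#' freedom (the small-sample reference that keeps the test calibrated at
#' typical replicate numbers). A Benjamini-Hochberg adjusted p-value is
#' reported for information; calling uses the raw p-value.
#'
#' @param counts Tibble, `feature_id` + one column per sample.
#' @param samples Sample sheet tibble (`sample_id`, `group`), groups `C` and
#'   `G`, at least two samples each.
#' @param size_factors Optional named per-sample size factors (rescaled to
#'   geometric mean 1). The default, `NULL`, estimates them by median of
#'   ratios; pass library-size-derived factors when the feature panel is
#'   small and mostly differential, where median-of-ratios normalization is
#'   confounded.
#' @return Tibble: `feature_id`, `base_mean_c`, `base_mean_g`, `log2fc`,
#'   `stat`, `p_value`, `p_adj`.
#' @export
de_test <- function(counts, samples, size_factors = NULL) {
  m <- counts_to_matrix(counts)
  stopifnot(all(samples$sample_id %in% colnames(m)))
  groups <- sort(unique(samples$group))
  if (length(groups) != 2) abort("exactly two groups are required")
  idx <- lapply(groups, function(g) {
    which(colnames(m) %in% samples$sample_id[samples$group == g])
  })
  names(idx) <- groups
  if (any(lengths(idx) < 2)) abort("each group needs at least two samples")
  sf <- if (is.null(size_factors)) estimate_size_factors(m) else {
    stopifnot(all(colnames(m) %in% names(size_factors)))
    sfv <- size_factors[colnames(m)]
    sfv / exp(mean(log(sfv)))
  }
  q <- sweep(m, 2, sf, "/")
  inv_sf_mean <- vapply(idx, function(j) mean(1 / sf[j]), numeric(1))

  grp_mean <- vapply(idx, function(j) rowMeans(q[, j, drop = FALSE]), numeric(nrow(q)))
  grp_var <- vapply(idx, function(j) apply(q[, j, drop = FALSE], 1, var), numeric(nrow(q)))
  n_g <- lengths(idx)
  df <- sum(n_g) - 2L

  mC <- grp_mean[, 1]; mG <- grp_mean[, 2]
  m_bar <- (mC + mG) / 2
  s2_pooled <- ((n_g[1] - 1) * grp_var[, 1] + (n_g[2] - 1) * grp_var[, 2]) / df
  c_bar <- mean(inv_sf_mean)
  alpha <- pmax((s2_pooled - m_bar * c_bar) / m_bar^2, 1e-8)

  mC5 <- mC + 0.5; mG5 <- mG + 0.5
  var_mC <- (mC5 * inv_sf_mean[1] + alpha * mC5^2) / n_g[1]
  var_mG <- (mG5 * inv_sf_mean[2] + alpha * mG5^2) / n_g[2]
  se <- sqrt(var_mC / mC5^2 + var_mG / mG5^2)
  stat <- (log(mG5) - log(mC5)) / se
  p <- 2 * pt(-abs(stat), df = df)
  lfc <- log2(mG5 / mC5)

  zero <- mC + mG == 0
  p[zero] <- 1; lfc[zero] <- 0; stat[zero] <- 0

  tibble(feature_id = rownames(m), base_mean_c = unname(mC),
         base_mean_g = unname(mG), log2fc = unname(lfc), stat = unname(stat),
         p_value = unname(p), p_adj = p.adjust(unname(p), method = "BH"))
}

#' Label differential-expression results
#'
#' Boundary semantics follow the thresholds as stated: `|log2fc| >= lfc_thr`
#' (inclusive) and `p < p_thr` (strict).
#'
#' @param results Tibble from [de_test()].
#' @param lfc_thr Fold-change threshold on the log2 scale (default 1).
#' @param p_thr Raw p-value threshold (default 0.05).
#' @return A `cerna_de` tibble with a `regulated` column (`up`/`down`/`ns`);
#'   `glance()` reports `n_up`/`n_down`.
#' @examples
#' res <- tibble::tibble(feature_id = "f", base_mean_c = 10, base_mean_g = 40,
#'                       log2fc = 2, stat = 5, p_value = 0.001, p_adj = 0.001)
#' call_de(res)
#' @export
call_de <- function(results, lfc_thr = 1, p_thr = 0.05) {
  stopifnot(lfc_thr > 0, p_thr > 0)
  out <- results |>
    mutate(regulated = dplyr::case_when(
      .data$log2fc >= lfc_thr & .data$p_value < p_thr ~ "up",
      .data$log2fc <= -lfc_thr & .data$p_value < p_thr ~ "down",
      TRUE ~ "ns"))
  structure(out, class = c("cerna_de", class(out)),
            lfc_thr = lfc_thr, p_thr = p_thr)
}

#' Convenience wrapper: test then label
#'
#' @inheritParams de_test
#' @inheritParams call_de
#' @return A `cerna_de` tibble.
#' @export
run_de <- function(counts, samples, lfc_thr = 1, p_thr = 0.05,
                   size_factors = NULL) {
  call_de(de_test(counts, samples, size_factors = size_factors),
          lfc_thr = lfc_thr, p_thr = p_thr)
}
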