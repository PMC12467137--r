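#' Hypergeometric over-representation analysis
#'
#' For each term with members in the universe, the upper-tail hypergeometric
#' probability of observing at least the seen overlap:
#' `p = P(X >= k | N, K, n)` with `N` the universe size, `K` the term size in
#' the universe, `n` the study size and `k` the study/term overlap.
#' Benjamini-Hochberg adjustment is applied across tested terms; by default
#' significance is called on the adjusted p-value (`raw_p = TRUE` switches to
#' the raw one).
#'
#' @param study_genes Character vector, a subset of `universe`.
#' @param universe Character vector of all considered genes.
#' @param term_map Tibble with `term_id` and `gene` (long form; optionally
#'   `term_name`, `category`), e.g. from [read_gmt()] or
#'   [simulate_term_map()].
#' @param alpha Significance cutoff (default 0.05).
#' @param raw_p Call significance on the raw p-value instead of the adjusted
#'   one.
#' @return A `cerna_ora` tibble ordered by (p, term_id): `term_id`, `k`, `K`,
#'   `n`, `N`, `p_value`, `p_adjusted`, `significant`.
#' @examples
#' tm <- tibble::tibble(term_id = "t1", gene = paste0("g", 1:5))
#' ora(paste0("g", 1:5), paste0("g", 1:20), tm)
#' @export
ora <- function(study_genes, universe, term_map, alpha = 0.05, raw_p = FALSE) {
  study_genes <- unique(study_genes)
  universe <- unique(universe)
  if (length(study_genes) == 0) abort("study set is empty")
  if (!all(study_genes %in% universe)) {
    abort("study genes must be a subset of the universe")
  }
  N <- length(universe)
  n_study <- length(study_genes)
  terms <- split(term_map$gene, term_map$term_id)
  rows <- purrr::imap_dfr(terms, function(members, id) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    if (K == 0) return(NULL)             # no universe overlap: skipped
    k <- length(intersect(members, study_genes))
    tibble(term_id = id, k = k, K = K, n = n_study, N = N,
           p_value = phyper(k - 1, K, N - K, n_study, lower.tail = FALSE))
  })
  if (nrow(rows) == 0) {
    rows <- tibble(term_id = character(), k = integer(), K = integer(),
                   n = integer(), N = integer(), p_value = numeric())
  }
  rows$p_adjusted <- p.adjust(rows$p_value, method = "BH")
  rows$significant <- if (raw_p) rows$p_value < alpha else rows$p_adjusted < alpha
  if (!is.null(tm_names <- attr(term_map, "term_names"))) {
    rows$term_name <- tm_names[rows$term_id]
  }
  rows <- arrange(rows, .data$p_value, .data$term_id)
  structure(rows, class = c("cerna_ora", class(rows)), alpha = alpha)
}

#' Simulate a toy term map in tidy form
#'
#' Draws gene sets of random sizes from a universe so the enrichment stage
#' can be exercised offline; real GO/KEGG content is user-supplied via
#' [read_gmt()].
#'
#' @param universe Character vector of gene ids.
#' @param n_terms Number of terms.
#' @param size_range Term size range.
#' @param seed Integer seed.
#' @return Tibble with `term_id`, `category`, `gene`.
#' @export
simulate_term_map <- function(universe, n_terms = 20, size_range = c(10, 50),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(universe) >= size_range[2])
  purrr::map_dfr(seq_len(n_terms), function(i) {
    sz <- sample(size_range[1]:size_range[2], 1)
    tibble(term_id = sprintf("TERM%03d", i),
           category = sample(c("BP", "MF", "CC", "pathway"), 1),
           gene = sample(universe, sz))
  })
}
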