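#' Spearman rank correlation with a t-approximate p-value
#'
#' Rho is the Pearson correlation of average ranks (ties averaged); the
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' For the small sample sizes of a two-group design the exact permutation
#' reference is available as [spearman_exact_p()].
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho` and `p`; `NULL` (with a warning) when either
#'   vector is constant.
#' @export
spearman_edge <- function(x, y) {
  chk <- check_corr_input(x, y)
  if (!chk) return(NULL)
  rho <- cor(rank(x), rank(y))
  list(rho = rho, p = corr_t_p(rho, length(x)))
}

#' Pearson correlation with a t-distributed p-value
#'
#' @inheritParams spearman_edge
#' @return List with `r` and `p`; `NULL` (with a warning) for constant input.
#' @export
pearson_edge <- function(x, y) {
  chk <- check_corr_input(x, y)
  if (!chk) return(NULL)
  r <- cor(x, y)
  list(r = r, p = corr_t_p(r, length(x)))
}

check_corr_input <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (var(x) == 0 || var(y) == 0) {
    warn("correlation undefined for a constant vector; edge skipped")
    return(FALSE)
  }
  TRUE
}

corr_t_p <- function(r, n) {
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' Exact permutation p-value for the Spearman correlation
#'
#' Enumerates all `n!` rank permutations (chunked over the first rank to
#' bound memory) and reports the two-sided tail probability
#' `P(|rho_perm| >= |rho_obs|)`. Supported for `n <= 10` without ties;
#' intended as the small-sample reference for [spearman_edge()].
#'
#' @inheritParams spearman_edge
#' @return Exact two-sided p-value.
#' @export
spearman_exact_p <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3, n <= 10)
  rx <- rank(x); ry <- rank(y)
  if (anyDuplicated(rx) || anyDuplicated(ry)) {
    abort("exact permutation p requires untied data")
  }
  rho_obs <- cor(rx, ry)
  ## rho is monotone decreasing in D = sum (rx - perm)^2; enumerate D
  denom <- n * (n^2 - 1) / 6
  d_obs <- sum((rx - ry)^2)
  ## |rho| >= |rho_obs|  <=>  D <= d_lo or D >= d_hi
  d_lo <- denom * (1 - abs(rho_obs))
  d_hi <- denom * (1 + abs(rho_obs))
  count <- 0
  total <- factorial(n)
  base_perms <- perms_matrix(n - 1)
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[base_perms], nrow = nrow(base_perms)))
    d <- rowSums(sweep(block, 2, rx)^2)
    count <- count + sum(d <= d_lo + 1e-9 | d >= d_hi - 1e-9)
  }
  count / total
}

## all permutations of 1..n as a matrix (n <= 9 here)
perms_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_matrix(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1] <- k
    remapped <- sub + (sub >= k)
    out[rows, -1] <- remapped
  }
  out
}
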