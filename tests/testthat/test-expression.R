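toy_counts <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(feature_id = sprintf("f%d", seq_len(nrow(m)))),
    as.data.frame(m)))
}

test_that("RPM is count per mapped million", {
  counts <- toy_counts(matrix(c(5, 0, 10, 0), 2, dimnames = list(NULL, c("s1", "s2"))))
  out <- rpm(counts, c(s1 = 1e6, s2 = 2e6))
  expect_equal(out$s1, c(5, 0))          # 5 reads in a million
  expect_equal(out$s2, c(5, 0))          # 10 reads in two million
  expect_equal(unlist(out[2, -1], use.names = FALSE), c(0, 0))  # all-zero row
  expect_identical(attr(out, "method"), "RPM")
  ## column-sum oracle: 1e6 * in-matrix reads / mapped_total
  set.seed(1)
  m <- matrix(rpois(60, 50), 10, 6, dimnames = list(NULL, paste0("s", 1:6)))
  totals <- setNames(colSums(m) * 4, paste0("s", 1:6))
  out2 <- rpm(toy_counts(m), totals)
  expect_equal(unname(colSums(counts_to_matrix(out2))),
               unname(1e6 * colSums(m) / totals), tolerance = 1e-12)
  expect_error(rpm(counts, c(s1 = 0, s2 = 1e6)), "s1")
})

test_that("miRNA TPM columns sum to one million", {
  one <- toy_counts(matrix(c(7, 3), 1, dimnames = list(NULL, c("a", "b"))))
  out <- tpm_mirna(one)
  expect_equal(unname(unlist(out[1, -1])), c(1e6, 1e6))
  two <- toy_counts(matrix(c(1, 3), 2, 1, dimnames = list(NULL, "a")))
  out2 <- tpm_mirna(two)
  expect_equal(out2$a, c(2.5e5, 7.5e5))
  set.seed(2)
  m <- matrix(rpois(50, 20) + 1, 5, 10, dimnames = list(NULL, paste0("s", 1:10)))
  expect_equal(unname(colSums(counts_to_matrix(tpm_mirna(toy_counts(m))))),
               rep(1e6, 10), tolerance = 1e-9)
  zero <- toy_counts(matrix(c(0, 1), 1, dimnames = list(NULL, c("z", "b"))))
  expect_error(tpm_mirna(zero), "z")
})

test_that("size factors recover exact scalar column multiples", {
  set.seed(3)
  base <- rpois(50, 100) + 1
  scal <- c(1, 2, 0.5, 4)
  m <- outer(base, scal)
  colnames(m) <- paste0("s", 1:4)
  sf <- estimate_size_factors(m)
  expect_equal(unname(sf / sf[1]), scal / scal[1], tolerance = 1e-12)
})

test_that("identical groups give exactly zero fold change", {
  set.seed(4)
  half <- matrix(rpois(50, 80), 10, 5)
  m <- cbind(half, half)
  colnames(m) <- c(paste0("C", 1:5), paste0("G", 1:5))
  res <- de_test(toy_counts(m), sample_sheet(5))
  expect_true(all(res$log2fc == 0))
})

test_that("swapping group labels negates log2fc and keeps p", {
  set.seed(5)
  m <- matrix(rnbinom(200, mu = 100, size = 10), 20, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  s1 <- tibble::tibble(sample_id = paste0("s", 1:10),
                       group = rep(c("C", "G"), each = 5))
  s2 <- s1; s2$group <- rev(s2$group)
  r1 <- de_test(toy_counts(m), s1)
  r2 <- de_test(toy_counts(m), s2)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("all-zero features are reported as untestable, not significant", {
  m <- rbind(matrix(0, 1, 10), matrix(rpois(90, 50), 9, 10))
  colnames(m) <- c(paste0("C", 1:5), paste0("G", 1:5))
  res <- call_de(de_test(toy_counts(m), sample_sheet(5)))
  expect_equal(res$p_value[1], 1)
  expect_equal(res$log2fc[1], 0)
  expect_identical(res$regulated[1], "ns")
})

test_that("a strong planted effect is called", {
  set.seed(6)
  mu <- c(rep(500, 5), rep(500 * 2^3, 5))
  m <- rbind(matrix(rnbinom(50 * 10, mu = 500, size = 20), 50, 10),
             rnbinom(10, mu = mu, size = 20))
  colnames(m) <- c(paste0("C", 1:5), paste0("G", 1:5))
  res <- call_de(de_test(toy_counts(m), sample_sheet(5)))
  expect_identical(res$regulated[51], "up")
})

test_that("calling respects the stated boundary semantics", {
  res <- tibble::tibble(feature_id = c("a", "b", "c"),
                        base_mean_c = 1, base_mean_g = 1,
                        log2fc = c(1.0, 0.999, -2),
                        stat = 0, p_value = c(0.049, 1e-9, 0.05),
                        p_adj = 1)
  out <- call_de(res)
  expect_identical(out$regulated, c("up", "ns", "ns"))
  expect_equal(unname(unlist(glance(out)[, c("n_up", "n_down")])), c(1L, 0L))
})
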