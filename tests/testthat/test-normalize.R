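test_that("identical columns give unit size factors", {
  x <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(4, 9), s2 = c(4, 9))
  sf <- compute_size_factors(x)
  expect_equal(sf$size_factor, c(1, 1))
})

test_that("a doubled column splits symmetrically around the geometric mean", {
  x <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                      A = c(10, 4, 100), B = c(20, 8, 200))
  sf <- compute_size_factors(x)
  expect_equal(sf$size_factor, c(2^-0.5, 2^0.5), tolerance = 1e-12)
  expr <- apply_size_factors(x, sf)
  m <- as.matrix(expr[, -1])
  expect_equal(m[, 1], m[, 2], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("zero-containing genes drop out of the reference set", {
  with_zero <- tibble::tibble(gene_id = c("g1", "g2", "g3", "gz"),
                              A = c(10, 4, 100, 0), B = c(20, 8, 200, 50),
                              C = c(10, 4, 100, 7))
  positive_only <- dplyr::filter(with_zero, gene_id != "gz")
  expect_equal(compute_size_factors(with_zero)$size_factor,
               compute_size_factors(positive_only)$size_factor)
  all_zero_somewhere <- tibble::tibble(gene_id = c("g1", "g2"),
                                       A = c(0, 1), B = c(1, 0))
  expect_error(compute_size_factors(all_zero_somewhere), "positive in every sample")
})

test_that("size factors agree with the DESeq2 estimator on positive matrices", {
  skip_if_not_installed("DESeq2")
  cfg <- simulation_config(n_samples = 12, n_genes = 300, nb_dispersion = 0.1,
                           base_expr_range = c(50, 500), seed = 7)
  m <- as.matrix(simulate_counts(cfg)[, -1])
  m <- m[rowSums(m > 0) == ncol(m), ]
  x <- tibble::as_tibble(cbind(data.frame(gene_id = rownames(m) %||% paste0("g", seq_len(nrow(m)))), m))
  ours <- compute_size_factors(x)$size_factor
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(ours, unname(theirs), tolerance = 1e-5)
})

test_that("scale equivariance: scaling one raw column scales its factor only", {
  x <- tibble::tibble(gene_id = paste0("g", 1:50),
                      A = rpois(50, 100) + 1, B = rpois(50, 100) + 1,
                      C = rpois(50, 100) + 1)
  sf1 <- compute_size_factors(x)
  x2 <- dplyr::mutate(x, B = B * 3)
  sf2 <- compute_size_factors(x2)
  # per-gene products change the geometric mean by 3^(1/3); all factors shift
  # by that constant, and sample B additionally by 3
  shift <- 3^(1 / 3)
  expect_equal(sf2$size_factor[c(1, 3)], sf1$size_factor[c(1, 3)] / shift,
               tolerance = 1e-10)
  expect_equal(sf2$size_factor[2], sf1$size_factor[2] * 3 / shift,
               tolerance = 1e-10)
  # the scaled sample rejoins the pseudo-reference, so the whole normalized
  # matrix shifts by the constant 3^(1/3); mean rescaling removes it
  n1 <- apply_size_factors(x, sf1)
  n2 <- apply_size_factors(x2, sf2)
  expect_equal(as.matrix(n2[, -1]), as.matrix(n1[, -1]) * shift,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.matrix(rescale_sample_means(n2)[, -1]),
               as.matrix(rescale_sample_means(n1)[, -1]), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("applying unit factors is the identity and division is elementwise", {
  x <- toy_counts()
  sf <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(1, 1))
  expect_equal(as.matrix(apply_size_factors(x, sf)[, -1]),
               as.matrix(x[, -1]), ignore_attr = TRUE)
  sf2 <- tibble::tibble(sample_id = c("s1", "s2"), size_factor = c(2, 4))
  expect_equal(apply_size_factors(x, sf2)$s1[1], 5)
  expect_error(apply_size_factors(x, sf2[1, ]), "no size factor")
})

test_that("mean rescaling hits the target exactly and is idempotent", {
  set.seed(9)
  x <- tibble::tibble(gene_id = paste0("g", 1:40),
                      !!!as.data.frame(matrix(rpois(40 * 5, 50), 40,
                                              dimnames = list(NULL, paste0("s", 1:5)))))
  r1 <- rescale_sample_means(x)
  m <- as.matrix(r1[, -1])
  expect_equal(unname(colMeans(m)), rep(1000, 5), tolerance = 1e-9)
  r2 <- rescale_sample_means(r1)
  expect_equal(as.matrix(r2[, -1]), m, tolerance = 1e-12)
  expect_equal(expr_stage(r1), "mean_rescaled")

  const <- tibble::tibble(gene_id = paste0("g", 1:3), s1 = rep(500, 3))
  expect_equal(rescale_sample_means(const)$s1, rep(1000, 3))
  zero <- tibble::tibble(gene_id = paste0("g", 1:3), s1 = rep(0, 3), s2 = 1:3)
  expect_error(rescale_sample_means(zero), "s1")
})

test_that("geometric mean of size factors is near 1 on simulated data", {
  cfg <- simulation_config(n_samples = 20, n_genes = 1000, nb_dispersion = 0.1,
                           base_expr_range = c(50, 500), seed = 13)
  sf <- compute_size_factors(simulate_counts(cfg))$size_factor
  expect_lt(abs(exp(mean(log(sf))) - 1), 0.1)
})
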