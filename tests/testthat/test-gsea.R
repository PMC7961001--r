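mk_expr_mat <- function(m) {
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

test_that("phenotype labels follow the scan's ties-go-low convention", {
  m <- matrix(c(1, 5, 2, 5, 3, 7), nrow = 1,
              dimnames = list("g1", paste0("s", 1:6)))
  expr <- mk_expr_mat(m)
  lab <- phenotype_labels(expr, "g1", 0.5)
  expect_true(all(lab$label == "high"))
  lab2 <- phenotype_labels(expr, "g1", 5)
  expect_equal(lab2$label, c("low", "low", "low", "low", "low", "high"))
  expect_error(phenotype_labels(expr, "g2", 1), "g2")
})

test_that("cutoff-keyed labels reproduce the survival scan's groups", {
  cfg <- simulation_config(n_samples = 100, n_genes = 15, seed = 29)
  co <- simulate_cohort(cfg)
  expr <- normalize_counts(co$counts)
  x <- as.numeric(as.matrix(expr[expr$gene_id == "G0005", -1]))
  s <- cutoff_scan(tibble::tibble(value = x, time = co$clinical$os_time,
                                  event = co$clinical$os_event))
  lab <- phenotype_labels(expr, "G0005", s$best_cutoff)
  expect_equal(lab$label == "high", x > s$best_cutoff)
  expect_equal(sum(lab$label == "high"), s$best$n_high)
})

test_that("signal-to-noise ranking matches a hand-computed table", {
  hi <- matrix(c(10, 12, 14, 4, 4, 4, 5, 6, 7, 3, 3, 3, 2, 4, 6),
               nrow = 5, byrow = TRUE)
  lo <- matrix(c(2, 4, 6, 2, 2, 2, 9, 10, 11, 1, 2, 3, 2, 4, 6),
               nrow = 5, byrow = TRUE)
  m <- cbind(hi, lo)
  dimnames(m) <- list(paste0("g", 1:5),
                      c(paste0("h", 1:3), paste0("l", 1:3)))
  labels <- tibble::tibble(sample_id = colnames(m),
                           label = rep(c("high", "low"), each = 3))
  rk <- rank_genes(mk_expr_mat(m), labels)
  s2n_hand <- function(a, b) {
    st <- function(v) {
      mu <- mean(v); s <- stats::sd(v)
      c(mu, max(s, 0.2 * abs(mu), 1e-8))
    }
    A <- st(a); B <- st(b)
    (A[1] - B[1]) / (A[2] + B[2])
  }
  expected <- purrr::map_dbl(1:5, ~ s2n_hand(m[.x, 1:3], m[.x, 4:6]))
  names(expected) <- rownames(m)
  expected <- sort(expected, decreasing = TRUE)
  expect_equal(rk$gene_id, names(expected))
  expect_equal(rk$metric, unname(expected), tolerance = 1e-12)
  # identical distributions give metric 0; tiny shifts keep a stable sign
  expect_equal(rk$metric[rk$gene_id == "g5"], 0)
  expect_gt(rk$metric[rk$gene_id == "g2"], 0)  # sd floor engaged on constants
})

test_that("swapping class labels reverses the ranked list", {
  set.seed(31)
  m <- matrix(runif(80, 1, 100), nrow = 8,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  labels <- tibble::tibble(sample_id = colnames(m),
                           label = rep(c("high", "low"), 5))
  flipped <- dplyr::mutate(labels, label = ifelse(label == "high", "low", "high"))
  r1 <- rank_genes(mk_expr_mat(m), labels)
  r2 <- rank_genes(mk_expr_mat(m), flipped)
  expect_equal(r2$metric[match(r1$gene_id, r2$gene_id)], -r1$metric,
               tolerance = 1e-12)
})

test_that("enrichment score reproduces the worked running-sum example", {
  ranked <- tibble::tibble(gene_id = paste0("g", 1:5), metric = c(5, 4, 3, 2, 1))
  es <- enrichment_score(ranked, c("g1", "g3"))
  expect_equal(es$running$running, c(0.625, 0.625 - 1/3, 2/3, 1/3, 0),
               tolerance = 1e-12)
  expect_equal(es$es, 2/3, tolerance = 1e-12)
})

test_that("extreme placements give the forced ES signs", {
  ranked <- tibble::tibble(gene_id = paste0("g", 1:6),
                           metric = c(3, 2.5, 2, 1.5, 1, 0.5))
  top <- enrichment_score(ranked, c("g1", "g2"))
  expect_equal(top$es, 1)
  bottom <- enrichment_score(ranked, c("g5", "g6"))
  expect_lt(bottom$es, 0)
  expect_error(enrichment_score(ranked, paste0("g", 1:6)), "whole")
  expect_error(enrichment_score(ranked, "absent"), "no gene-set member")
})

test_that("ES matches brute force and fgsea on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(33)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    metric <- sort(round(rnorm(n), 3), decreasing = TRUE)
    metric <- metric + seq(0, -1e-6, length.out = n)  # break exact ties
    ids <- paste0("g", seq_len(n))
    nh <- sample(1:(n - 1), 1)
    hit_idx <- sort(sample(n, nh))
    es <- enrichment_score(tibble::tibble(gene_id = ids, metric = metric),
                           ids[hit_idx])
    orc <- gsea_oracle(metric, seq_len(n) %in% hit_idx)
    expect_equal(es$es, orc$es, tolerance = 1e-12)
    fg <- fgsea::calcGseaStat(stats::setNames(metric, ids), hit_idx, gseaParam = 1)
    expect_equal(abs(es$es), abs(fg), tolerance = 1e-10)
    if (abs(abs(es$es) - abs(min(es$running$running))) > 1e-12 ||
        abs(abs(es$es) - abs(max(es$running$running))) > 1e-12) {
      expect_equal(es$es, fg, tolerance = 1e-10)  # sign compared off ties
    }
  }
})

test_that("ES with p = 1 is invariant to positive metric rescaling", {
  set.seed(34)
  metric <- sort(rexp(12), decreasing = TRUE)
  ids <- paste0("g", 1:12)
  set_ <- ids[c(2, 5, 9)]
  e1 <- enrichment_score(tibble::tibble(gene_id = ids, metric = metric), set_)
  e2 <- enrichment_score(tibble::tibble(gene_id = ids, metric = metric * 37), set_)
  expect_equal(e1$es, e2$es, tolerance = 1e-12)
})

test_that("permutation p is deterministic under a fixed seed and floored", {
  set.seed(35)
  m <- matrix(runif(20 * 12, 1, 10), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  expr <- mk_expr_mat(m)
  labels <- tibble::tibble(sample_id = colnames(m),
                           label = rep(c("high", "low"), 6))
  r1 <- permutation_pvalue(expr, labels, paste0("g", 1:4),
                           n_permutations = 200, seed = 8)
  r2 <- permutation_pvalue(expr, labels, paste0("g", 1:4),
                           n_permutations = 200, seed = 8)
  expect_identical(r1, r2)
  expect_gte(r1$nominal_p, 1 / 201)
  expect_error(permutation_pvalue(expr, labels, "g1", n_permutations = 10), "100")
})

test_that("a label-tracking gene set is strongly significant", {
  # the four signal genes are the phenotype plus noise, hence mutually
  # correlated; phenotype permutation preserves that correlation, so the
  # permuted ES occasionally reaches the same extreme and the p-value
  # cannot be guaranteed to sit exactly at the 1/(n_perm+1) floor
  withr::with_seed(36, {
    n <- 200
    lab <- rep(c("high", "low"), each = n / 2)
    sig <- ifelse(lab == "high", 10, 2)
    m <- rbind(
      matrix(rep(sig, 4), nrow = 4, byrow = TRUE) + matrix(rnorm(4 * n, sd = 1), 4),
      matrix(runif(96 * n, 1, 10), nrow = 96)
    )
    dimnames(m) <- list(paste0("g", 1:100), paste0("s", 1:n))
    labels <- tibble::tibble(sample_id = colnames(m), label = lab)
    res <- permutation_pvalue(mk_expr_mat(m), labels, paste0("g", 1:4),
                              n_permutations = 200, seed = 9)
    expect_lte(res$nominal_p, 0.05)
    expect_gt(res$es, 0)
  })
})

test_that("run_gsea scores each testable set with BH across sets", {
  cfg <- simulation_config(n_samples = 60, n_genes = 40, seed = 37)
  co <- simulate_cohort(cfg)
  expr <- normalize_counts(co$counts)
  sets <- synthetic_hallmark_sets(n_genes = 40, genes_per_set = 5, overlap = 1,
                                  seed = 2)
  cutoff <- stats::median(as.numeric(as.matrix(expr[expr$gene_id == "G0001", -1])))
  res <- run_gsea(expr, "G0001", cutoff, sets, n_permutations = 100, seed = 3)
  expect_equal(nrow(res), 8)
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(res$q >= res$nominal_p))
})
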