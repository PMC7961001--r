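test_that("candidate cutoffs are the distinct values between the quartiles", {
  expect_equal(candidate_cutoffs(1:8), c(3, 4, 5, 6))
  expect_equal(candidate_cutoffs(rep(5, 10)), numeric(0))
  with_outlier <- c(1:9, 1e6)
  expect_false(1e6 %in% candidate_cutoffs(with_outlier))
  expect_error(candidate_cutoffs(1:7), "8")
  # min_group excludes cutoffs leaving too-small groups
  expect_true(all(purrr::map_lgl(candidate_cutoffs(1:8, min_group = 3),
                                 ~ sum(1:8 <= .x) >= 3 && sum(1:8 > .x) >= 3)))
})

test_that("symmetric groups give HR 1 and p 1", {
  d <- tibble::tibble(
    group = rep(c("low", "high"), each = 4),
    time = rep(c(1, 2, 3, 4), 2),
    event = rep(c(1, 1, 0, 1), 2)
  )
  fit <- fit_cox_binary(d)
  expect_equal(fit$hr, 1)
  expect_equal(fit$p, 1)
  expect_false(fit$degenerate)
})

test_that("the Cox fit matches the Efron Newton and log-rank oracles", {
  d <- tibble::tibble(group = c("low", "low", "high", "high"),
                      time = c(2, 4, 1, 3), event = 1)
  fit <- fit_cox_binary(d)
  orc <- efron_newton_oracle(d$time, d$event, as.numeric(d$group == "high"))
  lr <- logrank_oracle(d$time, d$event, d$group == "high")
  expect_equal(log(fit$hr), orc$beta, tolerance = 1e-8)
  expect_equal(fit$p, orc$score_p, tolerance = 1e-10)
  expect_equal(fit$p, lr$p, tolerance = 1e-10)
})

test_that("an event-free group flags the fit as degenerate", {
  d <- tibble::tibble(group = rep(c("low", "high"), each = 4),
                      time = c(1, 2, 3, 4, 5, 6, 7, 8),
                      event = c(1, 1, 0, 1, 0, 0, 0, 0))
  fit <- fit_cox_binary(d)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$ci_low))
  expect_error(fit_cox_binary(dplyr::mutate(d, event = 0)), "no events")
  expect_error(fit_cox_binary(dplyr::mutate(d, group = "low")), "non-empty")
})

test_that("scan q-values are the BH step-up of the scan p-values", {
  expect_equal(bh_stepup_oracle(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.05333333333, 0.5), tolerance = 1e-9)
  set.seed(10)
  d <- tibble::tibble(value = rnorm(60), time = rexp(60, 0.05),
                      event = rbinom(60, 1, 0.8))
  s <- cutoff_scan(d)
  expect_equal(s$scan$q, bh_stepup_oracle(s$scan$p), tolerance = 1e-12)
  expect_true(all(s$scan$q >= s$scan$p))
})

test_that("a single-candidate scan has q equal to p", {
  d <- tibble::tibble(value = rep(c(1, 2), each = 5),
                      time = c(5, 6, 7, 8, 9, 1, 2, 3, 4, 10),
                      event = 1)
  s <- cutoff_scan(d)
  expect_equal(nrow(s$scan), 1)
  expect_equal(s$scan$q, s$scan$p)
  expect_equal(s$significant, s$scan$p < 0.10)
})

test_that("scan p-values equal isolated binary fits (no state leakage)", {
  set.seed(11)
  d <- tibble::tibble(value = rnorm(40), time = rexp(40, 0.05),
                      event = rbinom(40, 1, 0.8))
  s <- cutoff_scan(d)
  for (i in seq_len(nrow(s$scan))) {
    iso <- fit_cox_binary(
      dplyr::mutate(d, group = ifelse(value > s$scan$cutoff[i], "high", "low")))
    expect_equal(s$scan$p[i], iso$p)
    expect_equal(s$scan$hr[i], iso$hr)
  }
})

test_that("monotone transforms of the feature leave the scan invariant", {
  set.seed(12)
  d <- tibble::tibble(value = runif(50, 1, 100), time = rexp(50, 0.03),
                      event = rbinom(50, 1, 0.7))
  s1 <- cutoff_scan(d)
  s2 <- cutoff_scan(dplyr::mutate(d, value = log(value)))
  expect_equal(s2$scan$p, s1$scan$p, tolerance = 1e-12)
  expect_equal(s2$best_quantile, s1$best_quantile)
  expect_equal(s2$best_cutoff, log(s1$best_cutoff), tolerance = 1e-12)
})

test_that("a planted high-expression hazard yields HR above 1", {
  cfg <- simulation_config(
    n_samples = 300, n_genes = 2, censoring_fraction = 0.2,
    planted_effects = tibble::tibble(gene_id = "G0001", cutoff_quantile = 0.5,
                                     hazard_ratio = 3),
    seed = 17
  )
  co <- simulate_cohort(cfg)
  x <- as.numeric(as.matrix(co$counts[co$counts$gene_id == "G0001", -1]))
  s <- cutoff_scan(tibble::tibble(value = x, time = co$clinical$os_time,
                                  event = co$clinical$os_event))
  expect_true(s$evaluable)
  expect_gt(s$best$hr, 1)
  expect_true(s$significant)
})

test_that("non-scannable inputs come back evaluable = FALSE, not errors", {
  tiny <- tibble::tibble(value = 1:5, time = 1:5, event = 1)
  expect_false(cutoff_scan(tiny)$evaluable)
  const <- tibble::tibble(value = 1, time = 1:20, event = 1)
  expect_false(cutoff_scan(const)$evaluable)
  no_events <- tibble::tibble(value = rnorm(20), time = 1:20, event = 0)
  expect_false(cutoff_scan(no_events)$evaluable)
})

test_that("scan_expression returns one glance row per feature and joins samples", {
  cfg <- simulation_config(n_samples = 120, n_genes = 10, seed = 19)
  co <- simulate_cohort(cfg)
  expr <- normalize_counts(co$counts)
  res <- scan_expression(expr, co$clinical)
  expect_equal(res$feature, expr$gene_id)
  expect_true(all(res$n <= 120))
  res2 <- scan_expression(expr, co$clinical, features = c("G0003", "G0001"),
                          across_features_fdr = TRUE)
  expect_equal(res2$feature, c("G0003", "G0001"))
  expect_true(all(res2$q_across >= res2$p, na.rm = TRUE))
  expect_error(scan_expression(expr, co$clinical, features = "nope"), "nope")
})

test_that("ties at the minimum p resolve to the smaller cutoff", {
  # mirror-symmetric toy: two cutoffs give identical group splits
  d <- tibble::tibble(value = c(1, 1, 1, 2, 3, 4, 4, 4),
                      time = c(1, 2, 3, 4, 5, 6, 7, 8), event = 1)
  s <- cutoff_scan(d)
  dup <- duplicated(round(s$scan$p, 12)) | duplicated(round(s$scan$p, 12), fromLast = TRUE)
  if (any(dup)) {
    tied <- s$scan$cutoff[s$scan$p == min(s$scan$p)]
    if (length(tied) > 1) expect_equal(s$best_cutoff, min(tied))
  }
  expect_true(s$best_cutoff %in% s$scan$cutoff)
})
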