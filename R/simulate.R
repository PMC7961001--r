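# Synthetic cohort generator. Emulates the statistical structure the
# analysis assumes: negative-binomial counts with sample-specific size
# factors, right-censored exponential survival with dichotomous hazard
# effects planted at chosen expression quantiles, categorical clinical
# covariates, and sparse per-sample mutation records. One global seed
# drives deterministic independent sub-streams, so a whole cohort is
# reproducible from a single integer.

#' Build a simulation configuration
#'
#' @param n_samples number of samples (>= 4).
#' @param n_genes number of genes (>= 1).
#' @param size_factor_range positive interval; per-sample sequencing-depth
#'   factors are drawn log-uniformly over it.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); `0` gives the Poisson limit.
#' @param base_expr_range positive interval; per-gene base expression means
#'   are drawn log-uniformly over it so quartile-based cutoffs are
#'   well-populated.
#' @param baseline_hazard events per month for a sample in no high-risk
#'   group.
#' @param planted_effects data frame with columns `gene_id`,
#'   `cutoff_quantile` (strictly inside (0,1)) and `hazard_ratio` (> 0);
#'   samples above the gene's expression quantile have their hazard
#'   multiplied by `hazard_ratio`.
#' @param censoring_fraction target fraction of censored samples in [0, 1).
#' @param covariates list of category probability vectors for `sex`, `race`,
#'   `stage`, `grade` plus `age_mean`/`age_sd` for a truncated-normal age.
#' @param seed integer master seed.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_samples = 300,
                              n_genes = 500,
                              size_factor_range = c(0.5, 2),
                              nb_dispersion = 0.2,
                              base_expr_range = c(5, 5000),
                              baseline_hazard = 0.02,
                              planted_effects = NULL,
                              censoring_fraction = 0.3,
                              covariates = list(
                                sex = c(F = 0.5, M = 0.5),
                                race = c(white = 0.7, asian = 0.1, black = 0.2),
                                stage = c(`1` = 0.3, `2` = 0.3, `3` = 0.25, `4` = 0.15),
                                grade = c(low = 0.5, high = 0.5),
                                age_mean = 62, age_sd = 11
                              ),
                              seed = 1L) {
  if (n_samples < 4) abort("n_samples must be >= 4")
  if (n_genes < 1) abort("n_genes must be >= 1")
  if (length(size_factor_range) != 2 || any(size_factor_range <= 0) ||
      diff(size_factor_range) < 0) {
    abort("size_factor_range must be a positive non-decreasing interval")
  }
  if (nb_dispersion < 0) abort("nb_dispersion must be >= 0")
  if (baseline_hazard <= 0) abort("baseline_hazard must be > 0")
  if (censoring_fraction < 0 || censoring_fraction >= 1) {
    abort("censoring_fraction must be in [0, 1)")
  }
  if (is.null(planted_effects)) {
    planted_effects <- tibble(gene_id = character(), cutoff_quantile = numeric(),
                              hazard_ratio = numeric())
  }
  planted_effects <- as_tibble(planted_effects)
  if (nrow(planted_effects) > 0) {
    stopifnot(all(c("gene_id", "cutoff_quantile", "hazard_ratio") %in% names(planted_effects)))
    if (any(planted_effects$cutoff_quantile <= 0 | planted_effects$cutoff_quantile >= 1)) {
      abort("cutoff_quantile must be strictly inside (0, 1)")
    }
    if (any(planted_effects$hazard_ratio <= 0)) abort("hazard_ratio must be > 0")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
      size_factor_range = size_factor_range, nb_dispersion = nb_dispersion,
      base_expr_range = base_expr_range, baseline_hazard = baseline_hazard,
      planted_effects = planted_effects,
      censoring_fraction = censoring_fraction,
      covariates = covariates, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

sim_gene_ids <- function(config) sprintf("G%04d", seq_len(config$n_genes))
sim_sample_ids <- function(config) sprintf("S%04d", seq_len(config$n_samples))

check_planted_genes <- function(config) {
  genes <- sim_gene_ids(config)
  missing <- setdiff(config$planted_effects$gene_id, genes)
  if (length(missing) > 0) {
    abort(sprintf("planted-effect gene(s) not in the simulated matrix: %s",
                  paste(missing, collapse = ", ")))
  }
}

#' Simulate a raw count matrix
#'
#' Counts are negative-binomial with mean = size_factor(sample) x
#' base_expression(gene) and the configured dispersion; dispersion 0 uses
#' the Poisson limit. Identical configuration (including seed) gives an
#' identical matrix.
#'
#' @param config a [simulation_config()].
#' @return a wide count tibble (`gene_id` + one column per sample) with the
#'   true size factors and base expressions attached as attributes
#'   `sim_size_factors` and `sim_base_expr`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  check_planted_genes(config)
  withr::with_seed(derive_seed(config$seed, 1), {
    sf <- exp(runif(config$n_samples, log(config$size_factor_range[1]),
                    log(config$size_factor_range[2])))
    base <- exp(runif(config$n_genes, log(config$base_expr_range[1]),
                      log(config$base_expr_range[2])))
    mu <- outer(base, sf)
    m <- if (config$nb_dispersion < 1e-12) {
      matrix(rpois(length(mu), mu), nrow = config$n_genes)
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
             nrow = config$n_genes)
    }
    dimnames(m) <- list(sim_gene_ids(config), sim_sample_ids(config))
    out <- matrix_to_wide(m, "gene_id")
    attr(out, "sim_size_factors") <- setNames(sf, colnames(m))
    attr(out, "sim_base_expr") <- setNames(base, rownames(m))
    out
  })
}

# Solve the exponential censoring rate c so that the expected censored
# fraction mean_i c / (c + h_i) hits the target, given per-sample hazards.
censoring_rate_for <- function(hazards, target) {
  if (target <= 0) return(0)
  f <- function(logc) mean(exp(logc) / (exp(logc) + hazards)) - target
  exp(uniroot(f, c(-40, 40), tol = 1e-10)$root)
}

#' Simulate right-censored survival with planted cutoff effects
#'
#' Event times are exponential: each sample's hazard is the baseline
#' multiplied, for every planted effect whose gene expression exceeds its
#' cutoff in that sample, by that effect's hazard ratio. Each cutoff is the configured
#' quantile of that gene's expression across samples. Censoring times are
#' independent exponentials whose rate is solved numerically to hit the
#' target censored fraction in expectation. Clinical covariates are drawn
#' from the configured categorical distributions, independent of survival.
#'
#' @param expr wide expression (or count) tibble containing every
#'   planted-effect gene.
#' @param config a [simulation_config()].
#' @return clinical tibble (`sample_id`, `os_time`, `os_event`, `rfs_time`,
#'   `rfs_event`, `sex`, `race`, `stage`, `grade`, `age`) with the true
#'   per-gene cutoff values attached as attribute `sim_true_cutoffs`.
#' @export
simulate_survival <- function(expr, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- wide_to_matrix(expr)
  missing <- setdiff(config$planted_effects$gene_id, rownames(m))
  if (length(missing) > 0) {
    abort(sprintf("planted-effect gene(s) absent from expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  samples <- colnames(m)
  n <- length(samples)
  hazards <- rep(config$baseline_hazard, n)
  true_cutoffs <- numeric(0)
  if (nrow(config$planted_effects) > 0) {
    for (k in seq_len(nrow(config$planted_effects))) {
      pe <- config$planted_effects[k, ]
      x <- m[pe$gene_id, ]
      cut <- quantile(x, pe$cutoff_quantile, names = FALSE, type = 7)
      hazards <- hazards * ifelse(x > cut, pe$hazard_ratio, 1)
      true_cutoffs[pe$gene_id] <- cut
    }
  }
  withr::with_seed(derive_seed(config$seed, 2), {
    t_event <- rexp(n, hazards)
    crate <- censoring_rate_for(hazards, config$censoring_fraction)
    t_cens <- if (crate > 0) rexp(n, crate) else rep(Inf, n)
    os_time <- pmin(t_event, t_cens)
    os_event <- as.numeric(t_event <= t_cens)
    cov <- config$covariates
    draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    age <- round(pmax(18, rnorm(n, cov$age_mean, cov$age_sd)))
    out <- tibble(
      sample_id = samples,
      os_time = round(os_time, 4), os_event = os_event,
      rfs_time = NA_real_, rfs_event = NA_real_,
      sex = draw_cat(cov$sex), race = draw_cat(cov$race),
      stage = as.integer(draw_cat(cov$stage)), grade = draw_cat(cov$grade),
      age = age
    )
    attr(out, "sim_true_cutoffs") <- true_cutoffs
    out
  })
}

#' Simulate a sparse somatic mutation table
#'
#' Each (sample, gene) pair mutates independently with its configured
#' probability; variant classes are sampled from a configurable mix that
#' includes silent classes.
#'
#' @param config a [simulation_config()].
#' @param per_gene_mutation_prob named numeric vector, gene -> probability
#'   in [0, 1].
#' @param class_mix named probability vector over MAF variant classes for
#'   mutated pairs.
#' @return mutation tibble (`sample_id`, `gene_symbol`,
#'   `variant_classification`).
#' @export
simulate_maf <- function(config, per_gene_mutation_prob,
                         class_mix = c(Missense_Mutation = 0.55,
                                       Nonsense_Mutation = 0.1,
                                       Frame_Shift_Del = 0.1,
                                       Splice_Site = 0.05,
                                       Silent = 0.2)) {
  stopifnot(inherits(config, "sim_config"))
  p <- per_gene_mutation_prob
  if (any(p < 0 | p > 1)) abort("mutation probabilities must be in [0, 1]")
  unknown <- setdiff(names(class_mix), maf_all_classes())
  if (length(unknown) > 0) {
    abort(sprintf("unknown variant class in class_mix: %s", paste(unknown, collapse = ", ")))
  }
  samples <- sim_sample_ids(config)
  withr::with_seed(derive_seed(config$seed, 3), {
    recs <- purrr::imap(p, function(prob, gene) {
      hit <- runif(length(samples)) < prob
      if (!any(hit)) return(NULL)
      tibble(sample_id = samples[hit], gene_symbol = gene,
             variant_classification = sample(names(class_mix), sum(hit),
                                             replace = TRUE, prob = class_mix))
    })
    out <- list_rbind(purrr::compact(recs))
    if (nrow(out) == 0) {
      out <- tibble(sample_id = character(), gene_symbol = character(),
                    variant_classification = character())
    }
    arrange(out, .data$sample_id, .data$gene_symbol)
  })
}

#' Simulate a complete cohort (counts, clinical, mutations, ground truth)
#'
#' @param config a [simulation_config()].
#' @param per_gene_mutation_prob optional named vector for [simulate_maf()];
#'   default mutates 20 random genes at probability 0.1.
#' @return list with elements `counts`, `clinical`, `maf`, and
#'   `ground_truth` (planted effects with realized cutoff values).
#' @export
simulate_cohort <- function(config, per_gene_mutation_prob = NULL) {
  counts <- simulate_counts(config)
  clinical <- simulate_survival(counts, config)
  if (is.null(per_gene_mutation_prob)) {
    genes <- withr::with_seed(derive_seed(config$seed, 4),
                              sample(sim_gene_ids(config), min(20, config$n_genes)))
    per_gene_mutation_prob <- setNames(rep(0.1, length(genes)), genes)
  }
  maf <- simulate_maf(config, per_gene_mutation_prob)
  truth <- config$planted_effects
  if (nrow(truth) > 0) {
    tc <- attr(clinical, "sim_true_cutoffs")
    truth$true_cutoff_value <- unname(tc[truth$gene_id])
  }
  list(counts = counts, clinical = clinical, maf = maf, ground_truth = truth)
}
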