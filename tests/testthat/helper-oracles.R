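# Independent brute-force oracles used to verify the analytical core.
# These are deliberate re-derivations from definitions, sharing no code
# path with the package implementation.

# Benjamini-Hochberg step-up by the literal definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j), mapped back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- pmin(1, m * ps / seq_len(m))
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[ord] <- q
  out
}

# Efron partial likelihood for one covariate: score, information and
# Newton-Raphson maximization from beta = 0.
efron_score_info <- function(beta, time, event, x) {
  eta <- beta * x
  w <- exp(eta)
  U <- 0; I <- 0; ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    S_R <- sum(w[R]); Sx_R <- sum(w[R] * x[R]); Sxx_R <- sum(w[R] * x[R]^2)
    S_D <- sum(w[D]); Sx_D <- sum(w[D] * x[D]); Sxx_D <- sum(w[D] * x[D]^2)
    ll <- ll + sum(eta[D])
    for (l in 0:(d - 1)) {
      S <- S_R - (l / d) * S_D
      Sx <- Sx_R - (l / d) * Sx_D
      Sxx <- Sxx_R - (l / d) * Sxx_D
      A <- Sx / S
      ll <- ll - log(S)
      I <- I + (Sxx / S - A^2)
      U <- U - A
    }
    U <- U + sum(x[D])
  }
  list(U = U, I = I, loglik = ll)
}

efron_newton_oracle <- function(time, event, x, tol = 1e-12, max_iter = 100) {
  beta <- 0
  for (i in seq_len(max_iter)) {
    si <- efron_score_info(beta, time, event, x)
    if (si$I <= 0) break
    step <- si$U / si$I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  score0 <- efron_score_info(0, time, event, x)
  list(beta = beta,
       score_stat = score0$U^2 / score0$I,
       score_p = pchisq(score0$U^2 / score0$I, df = 1, lower.tail = FALSE))
}

# Efron partial log-likelihood for a general covariate matrix, maximized
# numerically (independent of any survival-package code path).
efron_loglik_multi <- function(beta, time, event, X) {
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    S_R <- sum(w[R]); S_D <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in 0:(d - 1)) ll <- ll - log(S_R - (l / d) * S_D)
  }
  ll
}

efron_multi_oracle <- function(time, event, X) {
  opt <- optim(rep(0, ncol(X)), function(b) -efron_loglik_multi(b, time, event, X),
               method = "BFGS", control = list(reltol = 1e-14, maxit = 1000))
  opt$par
}

# Classic log-rank O-E/V with the hypergeometric variance, two groups.
logrank_oracle <- function(time, event, high) {
  O <- 0; E <- 0; V <- 0
  for (t in unique(time[event == 1])) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & high)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(stat = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Kaplan-Meier product-limit table from the definition.
km_oracle <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  out <- data.frame(time = ts, n_risk = NA_real_, n_event = NA_real_, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(event == 1 & time == ts[i])
    s <- s * (1 - d / n_risk)
    out$n_risk[i] <- n_risk; out$n_event[i] <- d; out$surv[i] <- s
  }
  out
}

# Literal GSEA running-sum statistic.
gsea_oracle <- function(metric, hit, weight_p = 1) {
  n <- length(metric)
  nh <- sum(hit)
  nr <- sum(abs(metric[hit])^weight_p)
  run <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) cur <- cur + abs(metric[i])^weight_p / nr
    else cur <- cur - 1 / (n - nh)
    run[i] <- cur
  }
  list(es = run[which.max(abs(run))], running = run)
}

# Generate a random small survival instance with a finite Cox MLE
# (regenerates until the Efron Newton solution is bounded).
random_cox_instance <- function(n_range = 8:20, max_beta = 5) {
  repeat {
    n <- sample(n_range, 1)
    time <- round(rexp(n, 0.1), 6)           # continuous, ties negligible
    event <- rbinom(n, 1, 0.7)
    x <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(x)) < 2) next
    if (sum(event[x == 1]) == 0 || sum(event[x == 0]) == 0) next
    orc <- efron_newton_oracle(time, event, x)
    if (is.finite(orc$beta) && abs(orc$beta) < max_beta) {
      return(list(time = time, event = event, x = x, oracle = orc))
    }
  }
}
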