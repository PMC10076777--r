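# Independent brute-force oracles used to pin expected values.
# These deliberately avoid the package's own code paths.

# Product-limit estimator by direct per-event-time counting.
oracle_km <- function(time, event) {
  et <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = et, survival = NA_real_)
  for (i in seq_along(et)) {
    n_risk <- sum(time >= et[i])
    d <- sum(time == et[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$survival[i] <- s
  }
  out
}

# Two-group log-rank chi-square by explicit per-event-time summation.
oracle_logrank_chisq <- function(time, event, g) {
  et <- sort(unique(time[event == 1]))
  o_e <- 0; v <- 0
  for (t in et) {
    risk <- time >= t
    n <- sum(risk); n1 <- sum(risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    o_e <- o_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) 0 else o_e^2 / v
}

# Breslow/Efron-free log partial likelihood for TIE-FREE data.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid-search maximizer of the (concave) tie-free partial likelihood.
# Coarse 1e-2 pass over [-5, 5], then a 1e-4 grid around the coarse optimum;
# by strict concavity this finds the same point as a full 1e-4 grid.
oracle_cox_beta_grid <- function(time, event, x) {
  coarse <- seq(-5, 5, by = 1e-2)
  ll <- vapply(coarse, oracle_cox_loglik, 0, time = time, event = event, x = x)
  b0 <- coarse[which.max(ll)]
  fine <- seq(max(-5, b0 - 0.02), min(5, b0 + 0.02), by = 1e-4)
  llf <- vapply(fine, oracle_cox_loglik, 0, time = time, event = event, x = x)
  fine[which.max(llf)]
}

# AUC by explicit positive-negative pair enumeration (ties = 0.5).
oracle_auc_pairs <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free inputs).
oracle_wilcox_p <- function(a, b) {
  all_v <- c(a, b)
  n1 <- length(a)
  obs <- sum(rank(all_v)[seq_len(n1)])
  combs <- utils::combn(length(all_v), n1)
  r <- rank(all_v)
  stats_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n1 * (length(all_v) + 1) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-12)
}

# Random small tie-free survival cohort.
random_cohort <- function(n, p_event = 0.6) {
  tibble::tibble(
    sample_id = paste0("S", seq_len(n)),
    time_months = round(stats::runif(n, 1, 60), 3) + stats::runif(n, 0, 1e-4),
    event = stats::rbinom(n, 1, p_event))
}

make_clinical <- function(time, event) {
  tibble::tibble(sample_id = paste0("S", seq_along(time)),
                 time_months = time, event = as.integer(event))
}

# Small deterministic expression fixture.
toy_expression <- function(genes = 5, samples = 4, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(genes * samples), genes,
                dimnames = list(sprintf("G%02d", seq_len(genes)),
                                sprintf("S%02d", seq_len(samples))))
    round(m, 6)
  })
}
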