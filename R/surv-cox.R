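# Cox proportional hazards: partial-likelihood engine.
#
# The engine works on a cohort structure precomputed once (sort order, risk
# sets, tied-event blocks) so that screening thousands of genes against the
# same follow-up data only pays the per-gene Newton cost. Ties are handled
# with the Efron correction; the no-ties case takes a fully vectorized path.

cox_prepare <- function(time, event) {
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  es <- event[ord]
  ue <- sort(unique(ts[es == 1]))
  risk_end <- vapply(ue, function(t) sum(ts >= t), 0L) # prefix length of risk set
  death_idx <- lapply(ue, function(t) which(ts == t & es == 1))
  d <- lengths(death_idx)
  list(ord = ord, ts = ts, es = es, n = length(ts),
       ue = ue, risk_end = risk_end, death_idx = death_idx, d = d,
       has_ties = any(d > 1),
       death_flat = unlist(death_idx, use.names = FALSE))
}

# Log partial likelihood, score U and information I at beta (Efron ties).
cox_quantities <- function(prep, xs, beta) {
  w <- exp(beta * xs)
  xw <- xs * w
  x2w <- xs * xw
  c0 <- cumsum(w); c1 <- cumsum(xw); c2 <- cumsum(x2w)
  if (!prep$has_ties) {
    r <- prep$risk_end
    s0 <- c0[r]; s1 <- c1[r]; s2 <- c2[r]
    xb <- xs[prep$death_flat]
    m1 <- s1 / s0
    ll <- sum(beta * xb - log(s0))
    U <- sum(xb - m1)
    I <- sum(s2 / s0 - m1^2)
    return(list(ll = ll, U = U, I = I))
  }
  ll <- 0; U <- 0; I <- 0
  for (k in seq_along(prep$ue)) {
    r <- prep$risk_end[k]
    Dk <- prep$death_idx[[k]]
    dk <- prep$d[k]
    s0 <- c0[r]; s1 <- c1[r]; s2 <- c2[r]
    d0 <- sum(w[Dk]); d1 <- sum(xw[Dk]); d2 <- sum(x2w[Dk])
    f <- (seq_len(dk) - 1) / dk
    a0 <- s0 - f * d0; a1 <- s1 - f * d1; a2 <- s2 - f * d2
    m1 <- a1 / a0
    ll <- ll + beta * sum(xs[Dk]) - sum(log(a0))
    U <- U + sum(xs[Dk]) - sum(m1)
    I <- I + sum(a2 / a0 - m1^2)
  }
  list(ll = ll, U = U, I = I)
}

# Safeguarded Newton maximizer of the partial likelihood.
cox_engine <- function(prep, x, max_iter = 30, tol = 1e-9, beta_cap = 15) {
  xs <- x[prep$ord]
  beta <- 0
  q <- cox_quantities(prep, xs, beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    if (!is.finite(q$I) || q$I <= 0) break
    step <- q$U / q$I
    if (abs(step) > 2) step <- sign(step) * 2 # trust region against overshoot
    new_beta <- beta + step
    q_new <- cox_quantities(prep, xs, new_beta)
    halvings <- 0
    while ((!is.finite(q_new$ll) || q_new$ll < q$ll - 1e-12) && halvings < 20) {
      step <- step / 2
      new_beta <- beta + step
      q_new <- cox_quantities(prep, xs, new_beta)
      halvings <- halvings + 1
    }
    beta <- new_beta
    q <- q_new
    if (abs(q$U) < tol || abs(step) < 1e-12) { converged <- TRUE; break }
    if (abs(beta) > beta_cap) break
  }
  monotone <- abs(beta) > beta_cap
  if (monotone) { # monotone partial likelihood: effect not finitely estimable
    beta <- sign(beta) * beta_cap
    q <- cox_quantities(prep, xs, beta)
    converged <- FALSE
  }
  se <- if (is.finite(q$I) && q$I > 0) 1 / sqrt(q$I) else NA_real_
  z <- if (is.finite(se)) beta / se else NA_real_
  p <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else NA_real_
  list(beta = beta, se = se, p_value = p, loglik = q$ll,
       converged = converged, iterations = iter)
}

#' Univariate Cox proportional hazards fit
#'
#' Maximizes the Cox partial likelihood for a single continuous covariate by
#' safeguarded Newton iteration, with the Efron correction for tied event
#' times. The reported p-value is the Wald test on the coefficient. A
#' monotone partial likelihood (perfectly separating covariate) is detected,
#' the coefficient capped, and `converged` set to `FALSE`.
#'
#' @param x Per-sample numeric covariate (e.g. one gene's expression), one
#'   value per row of `clinical`.
#' @param clinical Clinical tibble (`time_months`, `event`).
#' @return A `cox_fit` object: list with `beta`, `hr`, `se`, `p_value`,
#'   `converged`, `n`, `n_events`, `loglik`, `iterations`.
#' @export
fit_cox_univariate <- function(x, clinical) {
  validate_clinical(within_ids(clinical))
  if (length(x) != nrow(clinical)) {
    abort_recurisk("`x` must have one value per clinical row.", "recurisk_value_error")
  }
  if (sum(clinical$event) == 0) {
    abort_recurisk("No events in the cohort; the partial likelihood carries no information.",
                   "recurisk_data_error")
  }
  if (length(unique(x)) < 2) {
    abort_recurisk("Covariate is constant; coefficient not identifiable.",
                   "recurisk_degenerate_error")
  }
  prep <- cox_prepare(clinical$time_months, clinical$event)
  fit <- cox_engine(prep, x)
  structure(list(beta = fit$beta, hr = exp(fit$beta), se = fit$se,
                 p_value = fit$p_value, converged = fit$converged,
                 n = nrow(clinical), n_events = sum(clinical$event),
                 loglik = fit$loglik, iterations = fit$iterations),
            class = "cox_fit")
}

#' Cox proportional hazards fit on a two-group indicator
#'
#' Convenience wrapper around [fit_cox_univariate()] with `x` set to the 0/1
#' group indicator (1 = high-risk group), so `hr` is the high-vs-low hazard
#' ratio.
#'
#' @param clinical Clinical tibble.
#' @param groups Per-sample binary labels (1/TRUE = high-risk).
#' @return A `cox_fit` object.
#' @export
fit_cox_group <- function(clinical, groups) {
  g <- as_two_level(groups)
  if (!all(c(FALSE, TRUE) %in% g)) {
    abort_recurisk("Both groups must be non-empty.", "recurisk_value_error")
  }
  fit_cox_univariate(as.numeric(g), clinical)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: beta = %.4f (HR = %.3f), se = %.4f, Wald p = %.4g\n",
              x$beta, x$hr, x$se, x$p_value))
  cat(sprintf("  n = %d, events = %d, converged = %s\n", x$n, x$n_events, x$converged))
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(term = "x", estimate = x$beta, std.error = x$se,
                 statistic = x$beta / x$se, p.value = x$p_value,
                 hr = x$hr)
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, logLik = x$loglik,
                 converged = x$converged, iterations = x$iterations)
}

#' Concordance AUC of a continuous score against a binary label
#'
#' Probability that a randomly chosen positive sample outscores a randomly
#' chosen negative one; tied scores count one half. Computed via the
#' rank-sum identity, which equals exhaustive pair enumeration.
#'
#' @param score Per-sample numeric score.
#' @param label Per-sample 0/1 (or logical) outcome label.
#' @return AUC in \[0, 1\].
#' @export
concordance_auc <- function(score, label) {
  lab <- as_two_level(label)
  if (length(score) != length(lab)) {
    abort_recurisk("`score` and `label` lengths differ.", "recurisk_value_error")
  }
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) {
    abort_recurisk("Both label classes must be present.", "recurisk_value_error")
  }
  r <- rank(score) # midranks handle ties as half-wins
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
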