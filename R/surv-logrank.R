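#' Two-group log-rank test
#'
#' Classic two-sample log-rank statistic: at every distinct event time the
#' observed events in group 1 are compared with the expectation under the
#' hypergeometric null, variances summed across event times, and the squared
#' standardized difference referred to a chi-square distribution with one
#' degree of freedom.
#'
#' @param clinical Clinical tibble (`time_months`, `event`).
#' @param groups Per-sample binary labels (logical, 0/1, or a two-level
#'   factor/character vector), one per row of `clinical`.
#' @return A `logrank_test` object (list with `chi_square`, `p_value`,
#'   `observed`, `expected` per group and `n` per group).
#' @export
logrank_test <- function(clinical, groups) {
  validate_clinical(within_ids(clinical))
  g <- as_two_level(groups)
  if (length(g) != nrow(clinical)) {
    abort_recurisk("`groups` must have one label per clinical row.", "recurisk_value_error")
  }
  if (!all(c(FALSE, TRUE) %in% g)) {
    abort_recurisk("Both groups must be non-empty.", "recurisk_value_error")
  }
  time <- clinical$time_months
  event <- clinical$event

  etimes <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  var_sum <- 0
  obs1 <- 0; exp1 <- 0
  for (t in etimes) {
    at_risk <- time >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g)
    d_j <- sum(time == t & event == 1)
    d1_j <- sum(time == t & event == 1 & g)
    e1_j <- d_j * n1_j / n_j
    obs1 <- obs1 + d1_j
    exp1 <- exp1 + e1_j
    if (n_j > 1) {
      var_sum <- var_sum + d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1)
    }
    o_minus_e <- o_minus_e + (d1_j - e1_j)
  }
  total_events <- sum(event)
  chi <- if (var_sum > 0) o_minus_e^2 / var_sum else 0
  p <- if (var_sum > 0) stats::pchisq(chi, df = 1, lower.tail = FALSE) else 1

  structure(list(
    chi_square = chi, p_value = p,
    observed = c(group0 = total_events - obs1, group1 = obs1),
    expected = c(group0 = total_events - exp1, group1 = exp1),
    n = c(group0 = sum(!g), group1 = sum(g))
  ), class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Two-group log-rank test: chi-square = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  cat(sprintf("  observed events: %d vs %d; expected: %.2f vs %.2f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}

#' @export
tidy.logrank_test <- function(x, ...) {
  tibble::tibble(statistic = x$chi_square, df = 1, p.value = x$p_value,
                 observed0 = unname(x$observed[1]), observed1 = unname(x$observed[2]),
                 expected0 = unname(x$expected[1]), expected1 = unname(x$expected[2]))
}

# Coerce arbitrary two-level labels to logical (TRUE = second level / 1).
as_two_level <- function(groups) {
  if (is.logical(groups)) return(groups)
  if (is.numeric(groups)) {
    if (!all(groups %in% c(0, 1))) {
      abort_recurisk("Numeric group labels must be 0/1.", "recurisk_value_error")
    }
    return(groups == 1)
  }
  lv <- sort(unique(as.character(groups)))
  if (length(lv) > 2) {
    abort_recurisk("More than two group labels supplied.", "recurisk_value_error")
  }
  as.character(groups) == lv[length(lv)]
}

# Clinical tables produced internally may lack sample_id; add one.
within_ids <- function(clinical) {
  if (!"sample_id" %in% names(clinical)) {
    clinical$sample_id <- paste0("S", seq_len(nrow(clinical)))
  }
  clinical
}
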