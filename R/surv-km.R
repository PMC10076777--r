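#' Product-limit (Kaplan-Meier) estimate of recurrence-free survival
#'
#' Computes the product-limit estimator with Greenwood variance at every
#' event time. Tied events at a time contribute jointly; censored samples
#' leave the risk set after the event tally at their time.
#'
#' @param clinical Clinical tibble (`time_months`, `event`; `sample_id`
#'   optional for this estimator).
#' @return A `km_curve` object: tibble with columns `time`, `n_risk`,
#'   `n_event`, `survival`, `greenwood_var`, one row per distinct event time,
#'   with attributes `n` and `n_events`.
#' @export
km_estimate <- function(clinical) {
  if (!nrow(clinical)) abort_recurisk("Empty clinical table.", "recurisk_value_error")
  if (!"sample_id" %in% names(clinical)) {
    clinical$sample_id <- paste0("S", seq_len(nrow(clinical)))
  }
  validate_clinical(clinical)
  time <- clinical$time_months
  event <- clinical$event
  n <- length(time)

  etimes <- sort(unique(time[event == 1]))
  if (!length(etimes)) {
    out <- tibble::tibble(time = numeric(), n_risk = integer(), n_event = integer(),
                          survival = numeric(), greenwood_var = numeric())
  } else {
    n_risk <- vapply(etimes, function(t) sum(time >= t), 0L)
    n_event <- vapply(etimes, function(t) sum(time == t & event == 1), 0L)
    frac <- 1 - n_event / n_risk
    survival <- cumprod(frac)
    gw_terms <- n_event / (n_risk * (n_risk - n_event))
    gw_terms[!is.finite(gw_terms)] <- 0 # survival hit 0; variance term degenerate
    greenwood_var <- survival^2 * cumsum(gw_terms)
    out <- tibble::tibble(time = etimes, n_risk = n_risk, n_event = n_event,
                          survival = survival, greenwood_var = greenwood_var)
  }
  structure(out, class = c("km_curve", class(out)),
            n = n, n_events = sum(event), max_time = max(time))
}

#' Evaluate a survival curve at a time point with confidence interval
#'
#' Right-continuous step-function lookup of a [km_estimate()] curve, with a
#' pointwise confidence interval on the complementary log-log scale (which
#' keeps the interval inside \[0, 1\]).
#'
#' @param curve A `km_curve` object.
#' @param t Time in months (`t >= 0`).
#' @param ci_level Confidence level (default 0.95).
#' @return Tibble with columns `time`, `survival`, `lower`, `upper`,
#'   `extrapolated` (TRUE when `t` exceeds the last observed time).
#' @export
survival_at <- function(curve, t, ci_level = 0.95) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  purrr::map_dfr(t, function(tt) {
    idx <- findInterval(tt, curve$time)
    if (idx == 0) {
      return(tibble::tibble(time = tt, survival = 1, lower = 1, upper = 1,
                            extrapolated = FALSE))
    }
    s <- curve$survival[idx]
    v <- curve$greenwood_var[idx]
    if (s <= 0 || s >= 1 || v <= 0) {
      lower <- upper <- s # degenerate: log-log transform undefined
    } else {
      # var of log(-log S) by the delta method
      se_ll <- sqrt(v) / (s * abs(log(s)))
      lower <- s^exp(zq * se_ll)
      upper <- s^exp(-zq * se_ll)
    }
    tibble::tibble(time = tt, survival = s,
                   lower = max(0, min(1, lower)), upper = max(0, min(1, upper)),
                   extrapolated = tt > attr(curve, "max_time"))
  })
}

#' @export
tidy.km_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.km_curve <- function(x, ...) {
  tibble::tibble(n = attr(x, "n"), n_events = attr(x, "n_events"),
                 max_time = attr(x, "max_time"),
                 final_survival = if (nrow(x)) x$survival[nrow(x)] else 1)
}

#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tibble::as_tibble(object)[c("time", "survival")],
    tibble::tibble(time = attr(object, "max_time"),
                   survival = if (nrow(object)) object$survival[nrow(object)] else 1))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months from surgery", y = "Recurrence-free survival") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot stratified by risk group
#'
#' @param clinical Clinical tibble.
#' @param groups Character or factor vector, one label per row of `clinical`.
#' @return A ggplot object with one step curve per group.
#' @export
plot_km_groups <- function(clinical, groups) {
  validate_clinical(clinical)
  stopifnot(length(groups) == nrow(clinical))
  df <- purrr::map_dfr(split(seq_len(nrow(clinical)), groups), function(idx) {
    cur <- km_estimate(clinical[idx, , drop = FALSE])
    dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                     tibble::as_tibble(cur)[c("time", "survival")],
                     tibble::tibble(time = attr(cur, "max_time"),
                                    survival = if (nrow(cur)) cur$survival[nrow(cur)] else 1))
  }, .id = "group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months from surgery", y = "Recurrence-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
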