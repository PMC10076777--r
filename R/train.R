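#' Train the full two-signature risk model
#'
#' End-to-end training: cohort eligibility filters, per-gene standardization
#' (parameters frozen for later scoring), partition of recurrence tumors into
#' two branches, rank-frequency stability selection of each branch's
#' signature genes over repeated cross-validation, centroid construction
#' (branch recurrence samples vs all non-recurrence samples), and per-signature
#' cutoff optimization by training log-rank separation.
#'
#' When stability selection returns fewer than `min_signature_size` genes for
#' a branch (e.g. in cohorts with little structure), the signature falls back
#' to the top `min_signature_size` genes by hit frequency, with a warning.
#'
#' @param expr Genes x samples matrix, log2 scale.
#' @param clinical Clinical tibble covering the matrix samples.
#' @param config A [discovery_config()].
#' @param markers Epithelial markers used for canonical branch numbering.
#' @param apply_filters Apply [apply_cohort_filters()] first (default `TRUE`).
#' @param min_signature_size Fallback signature size (default 10).
#' @param min_group_frac Minimum arm fraction for [optimize_cutoff()].
#' @return A `risk_model` object: list with `sig1`, `sig2`, `config`,
#'   `standardization`, `partition`, `stability` (per-branch
#'   `stability_result`s), `prescreen` (when the config asks for it),
#'   `training` (calls + metrics tibble), `exclusions`.
#' @export
train_risk_model <- function(expr, clinical, config = discovery_config(),
                             markers = epithelial_markers(),
                             apply_filters = TRUE,
                             min_signature_size = 10,
                             min_group_frac = 0.10) {
  validate_expression(expr)
  validate_clinical(clinical)
  if (config$n_branches != 2) {
    abort_recurisk("The combined risk model requires exactly 2 branches.",
                   "recurisk_config_error")
  }
  if (apply_filters) clinical <- apply_cohort_filters(clinical)
  clinical <- clinical[clinical$sample_id %in% colnames(expr), , drop = FALSE]
  expr <- expr[, clinical$sample_id, drop = FALSE]
  if (sum(clinical$event) < 2 * config$n_branches) {
    abort_recurisk(sprintf("Too few recurrence events (%d) to train.", sum(clinical$event)),
                   "recurisk_data_error")
  }

  std <- standardize_expression(expr)
  norec <- clinical$sample_id[clinical$event == 0]

  # round 1: partition the recurrence tumors, plus the Cox gene screen
  prescreen <- prescreen_genes(expr, clinical, alpha = config$prescreen_alpha)
  partition <- partition_recurrence(expr, clinical, config, markers = markers)

  genes_universe <- rownames(expr)
  if (config$universe == "prescreen") {
    genes_universe <- as.character(prescreen)
    if (!length(genes_universe)) {
      abort_recurisk("Prescreen selected no genes; cannot form a candidate universe.",
                     "recurisk_data_error")
    }
  }

  branch_seeds <- derive_seeds(config$seed, config$n_branches + 1L)
  signatures <- list()
  stability <- list()
  for (b in seq_len(config$n_branches)) {
    branch_samples <- partition$sample_id[partition$branch == b]
    cfg_b <- config
    cfg_b$seed <- branch_seeds[b]
    st <- stability_select(expr, clinical, branch_samples, norec,
                           config = cfg_b, genes = genes_universe)
    sel <- st$gene_id[st$selected]
    if (length(sel) < min_signature_size) {
      rlang::warn(sprintf(
        "Branch %d: only %d genes reached the stability threshold; falling back to the top %d by frequency.",
        b, length(sel), min_signature_size))
      sel <- st$gene_id[seq_len(min(min_signature_size, nrow(st)))]
    }
    sig <- build_signature(std$z, high_samples = branch_samples,
                           low_samples = norec, genes = sel,
                           name = paste0("subgroup", b),
                           standardization = std$params)
    scores <- score_samples(sig, expr)
    sig$cutoff <- as.numeric(optimize_cutoff(scores[clinical$sample_id], clinical,
                                             min_group_frac = min_group_frac))
    sig$meta$config_hash <- config_hash(config)
    sig$meta$seed <- config$seed
    signatures[[b]] <- sig
    stability[[b]] <- st
  }

  calls <- classify(signatures[[1]], signatures[[2]], expr)
  metrics <- evaluate_risk(calls, clinical)

  structure(list(sig1 = signatures[[1]], sig2 = signatures[[2]],
                 config = config, standardization = std$params,
                 partition = partition, stability = stability,
                 prescreen = prescreen,
                 training = list(calls = calls, metrics = metrics),
                 exclusions = cohort_exclusions(clinical)),
            class = "risk_model")
}

#' Classify samples with a trained risk model
#'
#' @param model A `risk_model` (from [train_risk_model()]) or the list
#'   returned by [load_model()].
#' @param expr Genes x samples matrix on the raw log2 scale.
#' @return Risk-call tibble (see [classify()]).
#' @export
predict_risk <- function(model, expr) {
  classify(model$sig1, model$sig2, expr)
}

#' Evaluate risk calls against follow-up data
#'
#' Mirrors the headline read-outs of a prognostic evaluation: high-risk
#' fraction, recurrence-free survival at `t_eval` months with confidence
#' interval per risk arm, two-group log-rank test, Cox hazard ratio of
#' high vs low risk, and the concordance AUC of the continuous combined
#' score against the recorded event flag. (The event flag is used as the AUC
#' label as recorded; samples censored early are *not* excluded — a
#' documented caveat.)
#'
#' @param calls Risk-call tibble (`sample_id`, `combined_score`, `label`).
#' @param clinical Clinical tibble sharing those sample ids.
#' @param t_eval Evaluation time in months (default 36).
#' @param ci_level Confidence level (default 0.95).
#' @return One-row tibble: `n`, `n_high`, `high_fraction`, `rfs_low`,
#'   `rfs_low_lower`, `rfs_low_upper`, `rfs_high`, `rfs_high_lower`,
#'   `rfs_high_upper`, `logrank_chi_square`, `logrank_p`, `hr`, `hr_p`,
#'   `auc`.
#' @export
evaluate_risk <- function(calls, clinical, t_eval = 36, ci_level = 0.95) {
  validate_clinical(clinical)
  df <- dplyr::inner_join(calls, clinical, by = "sample_id")
  if (!nrow(df)) {
    abort_recurisk("Calls and clinical table share no sample ids.", "recurisk_key_error")
  }
  high <- df$label != "low_risk"
  rfs_arm <- function(mask) {
    if (!any(mask)) return(c(NA_real_, NA_real_, NA_real_))
    s <- survival_at(km_estimate(df[mask, , drop = FALSE]), t_eval, ci_level)
    c(s$survival, s$lower, s$upper)
  }
  arm_low <- rfs_arm(!high)
  arm_high <- rfs_arm(high)
  one_armed <- !any(high) || all(high)
  if (one_armed) {
    rlang::warn("All samples fall in one risk arm; HR and log-rank are undefined.")
    lr <- list(chi_square = NA_real_, p_value = NA_real_)
    cox <- list(hr = NA_real_, p_value = NA_real_)
  } else {
    lr <- logrank_test(df, high)
    cox <- fit_cox_group(df, high)
  }
  auc <- if (sum(df$event) == 0 || all(df$event == 1)) NA_real_ else
    concordance_auc(df$combined_score, df$event)
  tibble::tibble(
    n = nrow(df), n_high = sum(high), high_fraction = mean(high),
    rfs_low = arm_low[1], rfs_low_lower = arm_low[2], rfs_low_upper = arm_low[3],
    rfs_high = arm_high[1], rfs_high_lower = arm_high[2], rfs_high_upper = arm_high[3],
    logrank_chi_square = lr$chi_square, logrank_p = lr$p_value,
    hr = cox$hr, hr_p = cox$p_value, auc = auc)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Two-signature nearest-centroid risk model\n")
  cat(sprintf("  subgroup 1: %d genes, cutoff %.4f\n",
              length(x$sig1$genes), x$sig1$cutoff))
  cat(sprintf("  subgroup 2: %d genes, cutoff %.4f\n",
              length(x$sig2$genes), x$sig2$cutoff))
  m <- x$training$metrics
  cat(sprintf("  training: n = %d, high-risk fraction %.1f%%, HR = %.2f, log-rank p = %.3g, AUC = %.3f\n",
              m$n, 100 * m$high_fraction, m$hr, m$logrank_p, m$auc))
  invisible(x)
}

#' @export
tidy.risk_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$stability), function(b)
    dplyr::mutate(tibble::as_tibble(x$stability[[b]]), branch = b, .before = 1))
}

#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(
    n_genes_sig1 = length(x$sig1$genes), n_genes_sig2 = length(x$sig2$genes),
    cutoff1 = x$sig1$cutoff, cutoff2 = x$sig2$cutoff,
    train_hr = x$training$metrics$hr,
    train_logrank_p = x$training$metrics$logrank_p,
    train_auc = x$training$metrics$auc,
    seed = x$config$seed)
}

#' Save a trained `risk_model` to JSON
#'
#' @param model A `risk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_risk_model <- function(model, path) {
  save_model(model$sig1, model$sig2, model$config, path)
}
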