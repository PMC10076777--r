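#' Configuration for subgroup discovery and stability selection
#'
#' Defaults mirror the training recipe the pipeline was built around:
#' univariate Cox prescreen at p < 0.01, 200 rounds of 10-fold
#' cross-validation, a gene scoring a hit when it ranks in the top 150
#' p-values of a fold-fit, and selection at a hit frequency of at least 80%.
#'
#' @param prescreen_alpha Raw p-value threshold of the univariate Cox
#'   prescreen (no multiple-testing correction; the stability stage guards
#'   against false positives).
#' @param cv_rounds Rounds of repeated cross-validation.
#' @param cv_folds Folds per round (stratified on event status).
#' @param top_k Rank threshold that counts as a hit.
#' @param freq_threshold Hit frequency needed for selection.
#' @param n_branches Number of recurrence subgroups to dissect.
#' @param n_variance_genes Genes (by variance) used for partitioning.
#' @param universe Candidate universe handed to stability selection:
#'   `"all"` ranks every gene in each fold-fit; `"prescreen"` restricts to
#'   the prescreened set first.
#' @param count_unit `"fold_fit"` counts hits over all `cv_rounds * cv_folds`
#'   fits; `"per_round"` aggregates each round's fold ranks by their median
#'   before thresholding.
#' @param seed Integer seed for the fold draws.
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(prescreen_alpha = 0.01,
                             cv_rounds = 200,
                             cv_folds = 10,
                             top_k = 150,
                             freq_threshold = 0.80,
                             n_branches = 2,
                             n_variance_genes = 500,
                             universe = c("all", "prescreen"),
                             count_unit = c("fold_fit", "per_round"),
                             seed = 1L) {
  universe <- match.arg(universe)
  count_unit <- match.arg(count_unit)
  if (cv_folds < 2) abort_recurisk("cv_folds must be >= 2.", "recurisk_config_error")
  if (top_k < 1) abort_recurisk("top_k must be >= 1.", "recurisk_config_error")
  if (freq_threshold <= 0 || freq_threshold > 1) {
    abort_recurisk("freq_threshold must lie in (0, 1].", "recurisk_config_error")
  }
  structure(list(prescreen_alpha = prescreen_alpha, cv_rounds = cv_rounds,
                 cv_folds = cv_folds, top_k = top_k,
                 freq_threshold = freq_threshold, n_branches = n_branches,
                 n_variance_genes = n_variance_genes, universe = universe,
                 count_unit = count_unit, seed = as.integer(seed)),
            class = "discovery_config")
}

#' Partition recurrence tumors into candidate subgroups
#'
#' Clusters the recurrence samples into `n_branches` groups by k-medoid
#' partitioning in a low-dimensional expression-program space: the cohort
#' matrix is restricted to its `n_variance_genes` most variable genes,
#' z-scored, and projected onto its first `n_branches` principal components
#' (computed on *all* cohort samples, so the axes reflect the cohort's major
#' expression programs, not outcome); the recurrence samples are then
#' clustered on their component coordinates. Pooling evidence across genes
#' this way keeps the partition stable when per-gene effects are modest and
#' pairwise sample correlations are noise-dominated. Branches are numbered
#' canonically: when epithelial `markers` are supplied and present in the
#' matrix, branch 1 is the branch with the *lower* mean marker z-score
#' (epithelial-loss first); otherwise branches are ordered by descending
#' size.
#'
#' @param expr Genes x samples expression matrix (all cohort samples).
#' @param clinical Clinical tibble covering the matrix samples.
#' @param config A [discovery_config()].
#' @param markers Optional character vector of epithelial marker genes used
#'   for canonical branch numbering (default [epithelial_markers()]).
#' @return A tibble (`sample_id`, `branch`) covering the recurrence samples,
#'   with attribute `"cohesion"`: per-branch mean silhouette width.
#' @export
partition_recurrence <- function(expr, clinical, config = discovery_config(),
                                 markers = epithelial_markers()) {
  validate_expression(expr)
  validate_clinical(clinical)
  rec <- clinical$sample_id[clinical$event == 1]
  rec <- intersect(colnames(expr), rec)
  k <- config$n_branches
  if (length(rec) < 2 * k) {
    abort_recurisk(sprintf("Need at least %d recurrence samples for %d branches; have %d.",
                           2 * k, k, length(rec)),
                   "recurisk_data_error")
  }
  if (k == 1) {
    out <- tibble::tibble(sample_id = rec, branch = 1L)
    attr(out, "cohesion") <- tibble::tibble(branch = 1L, mean_silhouette = NA_real_)
    return(out)
  }
  vars <- apply(expr, 1, stats::var)
  top <- names(sort(vars, decreasing = TRUE))[seq_len(min(config$n_variance_genes, nrow(expr)))]
  z <- standardize_expression(expr[top, , drop = FALSE])$z
  pcs <- stats::prcomp(t(z), center = FALSE, rank. = k)
  coords <- pcs$x[rec, , drop = FALSE]
  d <- stats::dist(coords)
  pm <- cluster::pam(d, k = k, diss = TRUE)
  branch_raw <- pm$clustering

  # canonical numbering
  present <- intersect(markers %||% character(), rownames(expr))
  if (length(present)) {
    zm <- standardize_expression(expr[present, , drop = FALSE])$z[, rec, drop = FALSE]
    score <- vapply(seq_len(k), function(b) mean(zm[, branch_raw == b, drop = FALSE]), 0)
    ord <- order(score) # epithelial-low branch becomes subgroup 1
  } else {
    sizes <- tabulate(branch_raw, k)
    ord <- order(-sizes, vapply(seq_len(k), function(b) min(rec[branch_raw == b]), ""))
  }
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  branch <- relabel[branch_raw]

  sil <- cluster::silhouette(branch_raw, d)
  coh <- tibble::tibble(branch = relabel[sort(unique(branch_raw))],
                        mean_silhouette = vapply(sort(unique(branch_raw)), function(b)
                          mean(sil[sil[, "cluster"] == b, "sil_width"]), 0)) |>
    dplyr::arrange(.data$branch)

  out <- tibble::tibble(sample_id = rec, branch = as.integer(branch))
  attr(out, "cohesion") <- coh
  out
}

#' Prescreen genes by univariate Cox p-value
#'
#' Fits a univariate Cox model per gene and keeps genes with Wald p below
#' `alpha`. No multiple-testing correction is applied — the stability stage
#' downstream is the guard against false positives. Constant (zero-variance)
#' genes are skipped and reported via the `"skipped"` attribute.
#'
#' @param expr Genes x samples matrix.
#' @param clinical Clinical tibble for those samples.
#' @param alpha Raw p-value threshold.
#' @return Character vector of gene ids with `p < alpha`; attributes
#'   `"p_values"` (named numeric) and `"skipped"` (character).
#' @export
prescreen_genes <- function(expr, clinical, alpha = 0.01) {
  validate_expression(expr)
  validate_clinical(clinical)
  expr <- expr[, clinical$sample_id, drop = FALSE]
  if (sum(clinical$event) < 2) {
    abort_recurisk("Prescreen needs at least 2 events.", "recurisk_data_error")
  }
  prep <- cox_prepare(clinical$time_months, clinical$event)
  keep_fit <- function(x) {
    if (length(unique(x)) < 2) return(NA_real_)
    cox_engine(prep, x)$p_value
  }
  pvals <- apply(expr, 1, keep_fit)
  skipped <- names(pvals)[is.na(pvals)]
  selected <- names(pvals)[!is.na(pvals) & pvals < alpha]
  structure(selected, p_values = pvals, skipped = skipped)
}

#' Rank-frequency stability selection over repeated cross-validation
#'
#' Builds a working cohort from one branch's recurrence samples plus the
#' non-recurrence samples, then repeats `cv_rounds` rounds of `cv_folds`-fold
#' cross-validation (folds stratified on event status). In every fold-fit a
#' univariate Cox model is fitted for each candidate gene on the training
#' folds, genes are ranked by ascending p-value (ties by ascending |beta|,
#' then gene id), and a gene scores a hit when it ranks within `top_k`.
#' Genes whose hit frequency reaches `freq_threshold` are selected.
#'
#' @param expr Genes x samples matrix (must cover both sample subsets).
#' @param clinical Clinical tibble.
#' @param branch_samples Sample ids of the branch's recurrence tumors.
#' @param norecurrence_samples Sample ids of the non-recurrence tumors.
#' @param config A [discovery_config()]; `cv_rounds`, `cv_folds`, `top_k`,
#'   `freq_threshold`, `count_unit` and `seed` are used.
#' @param genes Candidate gene universe (default: all rows of `expr`).
#' @return A `stability_result`: tibble (`gene_id`, `frequency`, `selected`)
#'   sorted by descending frequency, with attributes `n_fold_fits` and
#'   `config`.
#' @export
stability_select <- function(expr, clinical, branch_samples, norecurrence_samples,
                             config = discovery_config(), genes = rownames(expr)) {
  validate_expression(expr)
  validate_clinical(clinical)
  if (!length(branch_samples) || !length(norecurrence_samples)) {
    abort_recurisk("Both sample subsets must be non-empty.", "recurisk_data_error")
  }
  if (length(intersect(branch_samples, norecurrence_samples))) {
    abort_recurisk("Branch and norecurrence subsets must be disjoint.", "recurisk_value_error")
  }
  ids <- c(branch_samples, norecurrence_samples)
  missing_ids <- setdiff(ids, colnames(expr))
  if (length(missing_ids)) {
    abort_recurisk(sprintf("Sample(s) absent from matrix: %s.",
                           paste(utils::head(missing_ids, 5), collapse = ", ")),
                   "recurisk_key_error")
  }
  cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  X <- expr[genes, ids, drop = FALSE]
  n <- length(ids)
  ev <- cl$event
  n_events <- sum(ev)
  folds <- config$cv_folds
  # every training fit must carry enough events to anchor the partial likelihood
  if (n_events * (folds - 1) / folds < 2) {
    abort_recurisk(sprintf(
      "Too few events (%d) for %d-fold cross-validation; reduce cv_folds.",
      n_events, folds), "recurisk_config_error")
  }

  G <- length(genes)
  hits <- numeric(G)
  names(hits) <- genes
  per_round <- config$count_unit == "per_round"
  seeds <- derive_seeds(config$seed, config$cv_rounds)

  time <- cl$time_months
  tX <- t(X) # samples x genes: column access per gene is cache-friendly

  for (r in seq_len(config$cv_rounds)) {
    fold_id <- withr::with_seed(seeds[r], {
      f <- integer(n)
      idx_e <- which(ev == 1); idx_c <- which(ev == 0)
      f[idx_e] <- sample(rep_len(seq_len(folds), length(idx_e)))
      f[idx_c] <- sample(rep_len(seq_len(folds), length(idx_c)))
      f
    })
    round_ranks <- if (per_round) matrix(NA_real_, G, folds) else NULL
    for (f in seq_len(folds)) {
      train <- fold_id != f
      prep <- cox_prepare(time[train], ev[train])
      Xt <- tX[train, , drop = FALSE]
      p <- numeric(G); b <- numeric(G)
      for (g in seq_len(G)) {
        x <- Xt[, g]
        if (x[1] == x[2] && all(x == x[1])) { p[g] <- 2; b[g] <- 0; next }
        fit <- cox_engine(prep, x)
        p[g] <- if (is.finite(fit$p_value)) fit$p_value else 2
        b[g] <- fit$beta
      }
      rk <- integer(G)
      rk[order(p, abs(b), genes)] <- seq_len(G)
      if (per_round) {
        round_ranks[, f] <- rk
      } else {
        hits <- hits + (rk <= config$top_k)
      }
    }
    if (per_round) {
      med <- apply(round_ranks, 1, stats::median)
      hits <- hits + (med <= config$top_k)
    }
  }

  denom <- if (per_round) config$cv_rounds else config$cv_rounds * folds
  freq <- hits / denom
  out <- tibble::tibble(gene_id = genes, frequency = unname(freq)) |>
    dplyr::mutate(selected = .data$frequency >= config$freq_threshold) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$gene_id)
  structure(out, class = c("stability_result", class(out)),
            n_fold_fits = denom, config = config)
}

#' @export
tidy.stability_result <- function(x, ...) tibble::as_tibble(x)

#' @export
autoplot.stability_result <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frequency, fill = .data$selected)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::geom_vline(xintercept = cfg$freq_threshold, linetype = "dashed") +
    ggplot2::labs(x = "Top-rank hit frequency across fold-fits", y = "Genes",
                  fill = "Selected") +
    ggplot2::theme_minimal()
}
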