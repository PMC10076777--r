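#' Per-gene and mean log2 fold changes between sample groups
#'
#' On a log2-scale matrix the difference of group means per gene is the log2
#' fold change; `mean_delta` is its unweighted mean over the requested genes.
#'
#' @param expr Genes x samples matrix on the log2 scale.
#' @param group_a,group_b Disjoint non-empty character vectors of sample ids
#'   (deltas are `mean(A) - mean(B)`).
#' @param genes Gene ids to report.
#' @return A `fold_change_report`: tibble (`gene_id`, `delta`) with attribute
#'   `mean_delta`.
#' @export
log2_mean_fold_change <- function(expr, group_a, group_b, genes = rownames(expr)) {
  validate_expression(expr)
  if (!length(group_a) || !length(group_b)) {
    abort_recurisk("Both groups must be non-empty.", "recurisk_value_error")
  }
  if (length(intersect(group_a, group_b))) {
    abort_recurisk("Groups must be disjoint.", "recurisk_value_error")
  }
  unknown <- setdiff(c(genes, group_a, group_b), c(rownames(expr), colnames(expr)))
  if (length(unknown)) {
    abort_recurisk(sprintf("Unknown id(s): %s.",
                           paste(utils::head(unknown, 5), collapse = ", ")),
                   "recurisk_key_error")
  }
  delta <- rowMeans(expr[genes, group_a, drop = FALSE]) -
    rowMeans(expr[genes, group_b, drop = FALSE])
  out <- tibble::tibble(gene_id = genes, delta = unname(delta))
  structure(out, class = c("fold_change_report", class(out)),
            mean_delta = mean(delta))
}

#' Single-sample gene-set scores (mean z up minus mean z down)
#'
#' For each set and sample, the score is the mean z-score of the set's up
#' genes minus the mean z-score of its down genes (0 when the down list is
#' empty). Genes absent from the matrix are dropped; a set whose coverage
#' falls below `min_coverage` is skipped with a warning.
#'
#' @param expr_z z-scored genes x samples matrix.
#' @param sets Tidy gene-set tibble (`set`, `gene`, `direction`).
#' @param min_coverage Minimum fraction of a set's genes that must be
#'   present (default 0.5).
#' @return Tibble (`sample_id`, `set`, `score`, `coverage`).
#' @export
geneset_score <- function(expr_z, sets, min_coverage = 0.5) {
  validate_expression(expr_z)
  validate_gene_sets(sets)
  purrr::map_dfr(split(sets, sets$set), function(s) {
    present <- s$gene %in% rownames(expr_z)
    coverage <- mean(present)
    if (coverage < min_coverage) {
      rlang::warn(sprintf("Gene set '%s' skipped: coverage %.0f%% below %.0f%%.",
                          s$set[1], 100 * coverage, 100 * min_coverage))
      return(tibble::tibble(sample_id = character(), set = character(),
                            score = numeric(), coverage = numeric()))
    }
    up <- s$gene[present & s$direction == "up"]
    down <- s$gene[present & s$direction == "down"]
    up_term <- if (length(up)) colMeans(expr_z[up, , drop = FALSE]) else 0
    down_term <- if (length(down)) colMeans(expr_z[down, , drop = FALSE]) else 0
    tibble::tibble(sample_id = colnames(expr_z), set = s$set[1],
                   score = unname(up_term - down_term), coverage = coverage)
  })
}

#' Wilcoxon rank-sum comparisons of grouped values
#'
#' Two-sided rank-sum test per comparison. With both group sizes at most 10
#' and no ties the exact distribution is used; otherwise the normal
#' approximation with continuity and tie correction. Significance stars
#' follow the boxplot convention: `ns` (p > 0.05), `*` (p < 0.05), `**`
#' (p < 0.01).
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param reference_mode `"one_vs_rest"` compares each group against all
#'   remaining values pooled; `"pairwise_vs_reference"` compares each group
#'   against `reference`.
#' @param reference Reference group name (first group by default) for
#'   `"pairwise_vs_reference"`.
#' @return Tibble (`group`, `comparison`, `statistic`, `p_value`, `stars`).
#' @export
compare_groups_wilcoxon <- function(values_by_group,
                                    reference_mode = c("one_vs_rest", "pairwise_vs_reference"),
                                    reference = names(values_by_group)[1]) {
  reference_mode <- match.arg(reference_mode)
  if (is.null(names(values_by_group)) || any(!nzchar(names(values_by_group)))) {
    abort_recurisk("Groups must be named.", "recurisk_value_error")
  }
  if (any(!lengths(values_by_group))) {
    abort_recurisk("Every compared group needs at least one value.", "recurisk_value_error")
  }
  run_test <- function(a, b) {
    exact <- length(a) <= 10 && length(b) <= 10 && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                              exact = exact, correct = TRUE))
    c(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  groups <- names(values_by_group)
  rows <- if (reference_mode == "one_vs_rest") {
    purrr::map(groups, function(g) {
      rest <- unlist(values_by_group[setdiff(groups, g)], use.names = FALSE)
      if (!length(rest)) return(NULL)
      c(list(group = g, comparison = "rest"), as.list(run_test(values_by_group[[g]], rest)))
    })
  } else {
    purrr::map(setdiff(groups, reference), function(g) {
      c(list(group = g, comparison = reference),
        as.list(run_test(values_by_group[[g]], values_by_group[[reference]])))
    })
  }
  out <- purrr::map_dfr(purrr::compact(rows), tibble::as_tibble)
  dplyr::mutate(out, stars = dplyr::case_when(
    p_value < 0.01 ~ "**",
    p_value < 0.05 ~ "*",
    TRUE ~ "ns"))
}

#' Bundled (incomplete) immune marker panel
#'
#' A partial tumor-infiltrating immune cell marker panel containing only
#' marker genes commonly used for neutrophils, macrophages, T cells,
#' exhausted CD8+ T cells, dendritic cells, B cells, CD8+ T cells and
#' cytotoxic cells. It is *not* the full 43-marker/14-cell-type panel the
#' complete read-out expects; supply that as a user gene-set file.
#'
#' @return Tidy gene-set tibble (`set`, `gene`, `direction`).
#' @export
default_immune_panel <- function() {
  gene_sets(
    neutrophils = "FCGR3A",
    macrophages = "CD68",
    t_cells = c("CD3D", "CD3E"),
    exhausted_cd8 = c("CD244", "LAG3"),
    dendritic_cells = "HSD11B1",
    b_cells = "CD19",
    cd8_t_cells = "CD8A",
    cytotoxic_cells = c("GZMA", "GZMB", "KLRD1", "PRF1"))
}

#' Immune / marker panel read-out across risk groups
#'
#' Scores every sample on each marker set, then compares each set's scores
#' across the risk-call labels in both conventions: each high-risk subgroup
#' against all other samples (one-vs-rest), and each group against the
#' low-risk reference.
#'
#' @param expr_z z-scored genes x samples matrix.
#' @param panel Tidy gene-set tibble (cell types as sets); default
#'   [default_immune_panel()].
#' @param calls Risk-call tibble from [classify()] (`sample_id`, `label`).
#' @param min_coverage Passed to [geneset_score()].
#' @return List with `scores` (per-sample per-set tibble, with `label`) and
#'   `comparisons` (tibble of Wilcoxon results, column `mode` naming the
#'   convention).
#' @export
marker_panel_readout <- function(expr_z, calls, panel = default_immune_panel(),
                                 min_coverage = 0.5) {
  if (!nrow(panel)) abort_recurisk("Marker panel is empty.", "recurisk_value_error")
  scores <- geneset_score(expr_z, panel, min_coverage = min_coverage)
  scores <- dplyr::inner_join(scores, calls[c("sample_id", "label")], by = "sample_id")
  comparisons <- purrr::map_dfr(split(scores, scores$set), function(sc) {
    groups <- split(sc$score, sc$label)
    present <- names(groups)[lengths(groups) > 0]
    if (length(present) < 2) {
      rlang::warn(sprintf("Set '%s': fewer than two non-empty risk groups; comparisons skipped.",
                          sc$set[1]))
      return(tibble::tibble())
    }
    ovr <- compare_groups_wilcoxon(groups[present], "one_vs_rest")
    out <- dplyr::mutate(ovr, mode = "one_vs_rest")
    if ("low_risk" %in% present) {
      ref <- compare_groups_wilcoxon(groups[c("low_risk", setdiff(present, "low_risk"))],
                                     "pairwise_vs_reference", reference = "low_risk")
      out <- dplyr::bind_rows(out, dplyr::mutate(ref, mode = "vs_low_risk"))
    }
    dplyr::mutate(out, set = sc$set[1], .before = 1)
  })
  list(scores = scores, comparisons = comparisons)
}

#' Boxplot-style view of marker read-out scores by risk group
#'
#' @param readout Output of [marker_panel_readout()].
#' @return ggplot object: per-set boxplots of scores by risk label.
#' @export
plot_marker_readout <- function(readout) {
  ggplot2::ggplot(readout$scores,
                  ggplot2::aes(x = .data$label, y = .data$score, fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~set, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Marker set score (mean z)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
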