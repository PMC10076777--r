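#' Build a two-centroid signature from labelled sample sets
#'
#' The signature stores, for each gene, the mean z-scored expression over the
#' high-risk samples (`centroid_high`) and over the low-risk samples
#' (`centroid_low`), together with the frozen standardization parameters that
#' produced the z-matrix. The decision cutoff is set later by
#' [optimize_cutoff()].
#'
#' @param expr_z z-scored genes x samples matrix (training scale).
#' @param high_samples,low_samples Disjoint character vectors of sample ids.
#' @param genes Signature gene ids (must be rows of `expr_z`).
#' @param name Signature name, conventionally `"subgroup1"` or `"subgroup2"`.
#' @param standardization Standardization tibble from
#'   [standardize_expression()] (frozen training parameters).
#' @return A `centroid_signature` object (cutoff unset, `NA`).
#' @export
build_signature <- function(expr_z, high_samples, low_samples, genes, name,
                            standardization = NULL) {
  validate_expression(expr_z)
  if (!length(high_samples) || !length(low_samples)) {
    abort_recurisk("Both sample sets must be non-empty.", "recurisk_value_error")
  }
  if (identical(sort(high_samples), sort(low_samples))) {
    rlang::warn("High and low sample sets are identical; centroids will coincide.")
  }
  unknown <- setdiff(genes, rownames(expr_z))
  if (length(unknown)) {
    abort_recurisk(sprintf("Gene(s) absent from matrix: %s.",
                           paste(utils::head(unknown, 5), collapse = ", ")),
                   "recurisk_key_error")
  }
  unknown_s <- setdiff(c(high_samples, low_samples), colnames(expr_z))
  if (length(unknown_s)) {
    abort_recurisk(sprintf("Sample(s) absent from matrix: %s.",
                           paste(utils::head(unknown_s, 5), collapse = ", ")),
                   "recurisk_key_error")
  }
  genes <- unique(genes)
  ch <- rowMeans(expr_z[genes, high_samples, drop = FALSE])
  cl <- rowMeans(expr_z[genes, low_samples, drop = FALSE])
  structure(list(name = name, genes = genes,
                 centroid_high = unname(ch), centroid_low = unname(cl),
                 cutoff = NA_real_,
                 standardization = standardization,
                 meta = list(n_high = length(high_samples),
                             n_low = length(low_samples),
                             version = package_version_string())),
            class = "centroid_signature")
}

#' Score samples against a two-centroid signature
#'
#' Each sample is z-scored with the signature's frozen training parameters
#' and scored as Pearson correlation with the high-risk centroid minus
#' Pearson correlation with the low-risk centroid, over the signature genes.
#' Samples missing up to 5% of the signature genes are scored on the shared
#' genes (pairwise drop); more missingness is an error.
#'
#' @param sig A `centroid_signature`.
#' @param expr Genes x samples matrix on the *raw* (unstandardized) scale
#'   when the signature carries standardization parameters; otherwise
#'   assumed already z-scored.
#' @param min_coverage Minimum fraction of signature genes required
#'   (default 0.95).
#' @return Named numeric vector of scores, one per sample.
#' @export
score_samples <- function(sig, expr, min_coverage = 0.95) {
  stopifnot(inherits(sig, "centroid_signature"))
  validate_expression(expr)
  available <- intersect(sig$genes, rownames(expr))
  coverage <- length(available) / length(sig$genes)
  if (coverage < min_coverage) {
    absent <- setdiff(sig$genes, rownames(expr))
    abort_recurisk(sprintf(
      "Signature '%s': only %.1f%% of signature genes present (need %.0f%%). Missing: %s.",
      sig$name, 100 * coverage, 100 * min_coverage,
      paste(utils::head(absent, 10), collapse = ", ")),
      "recurisk_coverage_error")
  }
  if (coverage < 1) {
    rlang::inform(sprintf("Signature '%s': %d/%d genes available; scoring on shared genes.",
                          sig$name, length(available), length(sig$genes)))
  }
  if (!is.null(sig$standardization)) {
    pars <- sig$standardization
    pars <- pars[pars$gene_id %in% available, , drop = FALSE]
    z <- standardize_expression(expr[available, , drop = FALSE], params = pars)$z
  } else {
    z <- expr[available, , drop = FALSE]
  }
  keep <- match(available, sig$genes)
  ch <- sig$centroid_high[keep]
  clo <- sig$centroid_low[keep]
  # degenerate (zero-variance) vectors correlate as 0 rather than NA
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  apply(z, 2, function(v) safe_cor(v, ch) - safe_cor(v, clo))
}

#' Optimize a signature's decision cutoff by training log-rank separation
#'
#' Scans the midpoints of adjacent sorted unique scores and picks the cutoff
#' whose induced split (score above vs at-or-below) maximizes the two-group
#' log-rank chi-square, subject to each arm holding at least
#' `min_group_frac` of the samples. Ties are broken toward the more balanced
#' split.
#'
#' @param scores Named or positional numeric scores, one per clinical row.
#' @param clinical Clinical tibble.
#' @param min_group_frac Minimum fraction of samples per arm (default 0.10).
#' @return The chosen cutoff (numeric scalar), with attribute `"chi_square"`.
#' @export
optimize_cutoff <- function(scores, clinical, min_group_frac = 0.10) {
  validate_clinical(within_ids(clinical))
  if (length(scores) != nrow(clinical)) {
    abort_recurisk("`scores` must have one value per clinical row.", "recurisk_value_error")
  }
  if (sum(clinical$event) < 2) {
    abort_recurisk("Cutoff optimization needs at least 2 events.", "recurisk_data_error")
  }
  u <- sort(unique(scores))
  if (length(u) < 2) {
    abort_recurisk("All scores equal; no admissible cutpoint.", "recurisk_degenerate_error")
  }
  grid <- (u[-1] + u[-length(u)]) / 2
  n <- length(scores)
  admissible <- vapply(grid, function(ct) {
    nh <- sum(scores > ct)
    nh >= min_group_frac * n && (n - nh) >= min_group_frac * n
  }, TRUE)
  if (!any(admissible)) {
    abort_recurisk("No admissible cutpoint under the minimum group-size constraint.",
                   "recurisk_degenerate_error")
  }
  grid <- grid[admissible]
  stat <- vapply(grid, function(ct) {
    logrank_test(clinical, scores > ct)$chi_square
  }, 0)
  balance <- vapply(grid, function(ct) abs(sum(scores > ct) - n / 2), 0)
  best <- which(stat == max(stat))
  best <- best[which.min(balance[best])]
  structure(grid[best], chi_square = stat[best])
}

#' Three-way risk call from two centroid signatures
#'
#' Scores every sample with both signatures; a sample is high-risk when
#' either score exceeds its signature's cutoff (OR combination). Among
#' high-risk samples the subgroup is the signature with the larger
#' cutoff-centred margin (ties go to subgroup 1). The continuous combined
#' score is the larger margin.
#'
#' @param sig1,sig2 `centroid_signature` objects with cutoffs set.
#' @param expr Genes x samples matrix.
#' @return Tibble (`sample_id`, `score1`, `score2`, `margin1`, `margin2`,
#'   `combined_score`, `label`) with `label` in
#'   `{low_risk, high_risk_1, high_risk_2}`.
#' @export
classify <- function(sig1, sig2, expr) {
  stopifnot(inherits(sig1, "centroid_signature"), inherits(sig2, "centroid_signature"))
  if (is.na(sig1$cutoff) || is.na(sig2$cutoff)) {
    abort_recurisk("Both signatures must carry cutoffs; run optimize_cutoff() first.",
                   "recurisk_value_error")
  }
  s1 <- score_samples(sig1, expr)
  s2 <- score_samples(sig2, expr)
  m1 <- s1 - sig1$cutoff
  m2 <- s2 - sig2$cutoff
  label <- dplyr::case_when(
    m1 <= 0 & m2 <= 0 ~ "low_risk",
    m1 >= m2 ~ "high_risk_1",
    TRUE ~ "high_risk_2")
  tibble::tibble(sample_id = colnames(expr),
                 score1 = unname(s1), score2 = unname(s2),
                 margin1 = unname(m1), margin2 = unname(m2),
                 combined_score = pmax(.data$margin1, .data$margin2),
                 label = label)
}

signature_to_list <- function(sig) {
  list(name = sig$name, genes = sig$genes,
       centroid_high = sig$centroid_high, centroid_low = sig$centroid_low,
       cutoff = sig$cutoff,
       standardization = if (is.null(sig$standardization)) NULL else
         as.list(sig$standardization),
       meta = sig$meta)
}

signature_from_list <- function(x) {
  std <- if (is.null(x$standardization)) NULL else {
    cols <- lapply(x$standardization, unlist, use.names = FALSE)
    tibble::tibble(gene_id = as.character(cols$gene_id),
                   mean = as.numeric(cols$mean),
                   sd = as.numeric(cols$sd),
                   zero_variance = as.logical(cols$zero_variance))
  }
  sig <- structure(list(
    name = x$name,
    genes = as.character(unlist(x$genes, use.names = FALSE)),
    centroid_high = as.numeric(unlist(x$centroid_high, use.names = FALSE)),
    centroid_low = as.numeric(unlist(x$centroid_low, use.names = FALSE)),
    cutoff = as.numeric(x$cutoff %||% NA_real_),
    standardization = std,
    meta = lapply(x$meta, function(v) if (length(v) == 1) v[[1]] else unlist(v))),
    class = "centroid_signature")
  if (length(sig$centroid_high) != length(sig$genes) ||
      length(sig$centroid_low) != length(sig$genes)) {
    abort_recurisk(sprintf(
      "Model integrity error: signature '%s' centroid length does not match its gene list.",
      sig$name), "recurisk_integrity_error")
  }
  sig
}

#' Save a fitted two-signature risk model to JSON
#'
#' The file stores both signatures (gene lists, centroids, cutoffs, frozen
#' standardization), the training configuration, its hash, and the package
#' version, at full double precision so that a load/classify round trip
#' reproduces the original calls exactly.
#'
#' @param sig1,sig2 `centroid_signature` objects.
#' @param config Training configuration list (stored verbatim).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(sig1, sig2, config, path) {
  payload <- list(
    schema = "recurisk_model/1",
    package_version = package_version_string(),
    config = unclass(config),
    config_hash = config_hash(config),
    signatures = list(signature_to_list(sig1), signature_to_list(sig2)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Load a risk model saved by [save_model()]
#'
#' @param path Model JSON path.
#' @return List with elements `sig1`, `sig2`, `config`, `package_version`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    abort_recurisk(sprintf("Model file not found: %s", path), "recurisk_io_error")
  }
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e) {
                        abort_recurisk(sprintf("Corrupted model file: %s", conditionMessage(e)),
                                       "recurisk_integrity_error")
                      })
  if (!identical(payload$schema, "recurisk_model/1")) {
    abort_recurisk("Unrecognized model schema.", "recurisk_integrity_error")
  }
  if (!identical(payload$package_version, package_version_string())) {
    rlang::warn(sprintf("Model was saved with package version %s (running %s).",
                        payload$package_version, package_version_string()))
  }
  sigs <- payload$signatures
  list(sig1 = signature_from_list(sigs[[1]]),
       sig2 = signature_from_list(sigs[[2]]),
       config = payload$config,
       package_version = payload$package_version)
}

#' @export
print.centroid_signature <- function(x, ...) {
  cat(sprintf("Centroid signature '%s': %d genes, cutoff = %s\n",
              x$name, length(x$genes),
              if (is.na(x$cutoff)) "unset" else format(x$cutoff, digits = 4)))
  invisible(x)
}

#' Documented fallback cutoffs for externally supplied models
#'
#' When a model file carries no optimized cutoffs, these constants are
#' installed as defaults for subgroup 1 and subgroup 2 respectively. They are
#' small near-zero values on the difference-of-correlations score scale.
#'
#' @return Named numeric vector `c(subgroup1 = -0.0850, subgroup2 = -0.0005)`.
#' @export
default_cutoffs <- function() c(subgroup1 = -0.0850, subgroup2 = -0.0005)
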