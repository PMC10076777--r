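#' Per-gene z-scoring with frozen training parameters
#'
#' Standardizes each gene (row) of an expression matrix to zero mean and unit
#' variance. When `params` is supplied (the output of an earlier call on a
#' training cohort), its means and standard deviations are applied unchanged —
#' the frozen-parameter contract that lets validation samples be scored on
#' the training scale. Zero-variance genes are mapped to 0 rather than
#' dropped, so downstream gene lists keep their length; they are flagged in
#' the returned parameters so a trainer can exclude them.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param params Optional standardization tibble from a previous call
#'   (columns `gene_id`, `mean`, `sd`, `zero_variance`).
#' @return List with elements `z` (the standardized matrix) and `params`
#'   (tibble `gene_id`, `mean`, `sd`, `zero_variance`).
#' @export
standardize_expression <- function(expr, params = NULL) {
  validate_expression(expr)
  gid <- rownames(expr)
  if (is.null(params)) {
    mu <- rowMeans(expr)
    # population denominator is irrelevant to the contract; sample sd used
    sdv <- apply(expr, 1, stats::sd)
    zero_var <- !is.finite(sdv) | sdv == 0
    params <- tibble::tibble(gene_id = gid, mean = unname(mu),
                             sd = unname(sdv), zero_variance = unname(zero_var))
  } else {
    missing_genes <- setdiff(gid, params$gene_id)
    if (length(missing_genes)) {
      abort_recurisk(sprintf("Gene(s) absent from standardization parameters: %s.",
                             paste(utils::head(missing_genes, 5), collapse = ", ")),
                     "recurisk_key_error")
    }
    params <- params[match(gid, params$gene_id), , drop = FALSE]
  }
  sd_safe <- ifelse(params$zero_variance | params$sd == 0, 1, params$sd)
  z <- (expr - params$mean) / sd_safe
  z[params$zero_variance, ] <- 0
  list(z = z, params = params)
}
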