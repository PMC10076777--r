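# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_recurisk <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "recurisk_error"), ...)
}

#' Derive a stream of reproducible sub-seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed. Stochastic
#' stages draw their own sub-seed from this counter scheme so that adding or
#' reordering stages does not silently shift the random streams of the others.
#'
#' @param seed Master integer seed.
#' @param n Number of sub-seeds to draw.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Validate an expression matrix: numeric genes x samples with unique dimnames.
validate_expression <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort_recurisk(sprintf("`%s` must be a numeric matrix (genes x samples).", arg),
                   "recurisk_format_error")
  }
  gid <- rownames(expr); sid <- colnames(expr)
  if (is.null(gid) || is.null(sid)) {
    abort_recurisk(sprintf("`%s` must carry gene ids as rownames and sample ids as colnames.", arg),
                   "recurisk_format_error")
  }
  if (anyDuplicated(gid)) {
    abort_recurisk(sprintf("Duplicate gene id(s): %s",
                           paste(unique(gid[duplicated(gid)]), collapse = ", ")),
                   "recurisk_format_error")
  }
  if (anyDuplicated(sid)) {
    abort_recurisk(sprintf("Duplicate sample id(s): %s",
                           paste(unique(sid[duplicated(sid)]), collapse = ", ")),
                   "recurisk_format_error")
  }
  if (any(!is.finite(expr))) {
    abort_recurisk("Expression matrix contains non-finite values; missing values are not supported.",
                   "recurisk_value_error")
  }
  invisible(expr)
}

# Validate a clinical tibble (sample_id, time_months, event [+ extras]).
validate_clinical <- function(clinical, arg = "clinical") {
  required <- c("sample_id", "time_months", "event")
  missing_cols <- setdiff(required, names(clinical))
  if (length(missing_cols)) {
    abort_recurisk(sprintf("`%s` is missing mandatory column(s): %s.",
                           arg, paste(missing_cols, collapse = ", ")),
                   "recurisk_format_error")
  }
  if (anyDuplicated(clinical$sample_id)) {
    abort_recurisk("Duplicate sample ids in clinical table.", "recurisk_format_error")
  }
  bad_event <- which(!clinical$event %in% c(0, 1))
  if (length(bad_event)) {
    abort_recurisk(sprintf("`event` must be 0 or 1; offending row(s): %s.",
                           paste(bad_event, collapse = ", ")),
                   "recurisk_value_error")
  }
  bad_time <- which(!is.finite(clinical$time_months) | clinical$time_months <= 0)
  if (length(bad_time)) {
    abort_recurisk(sprintf("`time_months` must be positive and finite; offending row(s): %s.",
                           paste(bad_time, collapse = ", ")),
                   "recurisk_value_error")
  }
  invisible(clinical)
}

# Hash used to fingerprint configs in logs and model files.
config_hash <- function(x) rlang::hash(x)

package_version_string <- function() {
  as.character(utils::packageVersion("recurisk"))
}
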