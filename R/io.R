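#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids (header
#' `gene_id`) and whose remaining columns are samples, one gene per row.
#' Values are taken to be on a log2 normalized-abundance scale; the package
#' performs no library-size normalization. Set `log2_transform = TRUE` only
#' when the file holds linear-scale abundances, in which case `log2(x + 1)`
#' is applied.
#'
#' @param path Path to a TSV file.
#' @param log2_transform Apply `log2(x + 1)` to the values (default `FALSE`).
#' @return Numeric matrix, genes x samples, with gene ids as rownames and
#'   sample ids as colnames. Row/column order follows the file.
#' @export
read_expression <- function(path, log2_transform = FALSE) {
  if (!file.exists(path)) {
    abort_recurisk(sprintf("Expression file not found: %s", path), "recurisk_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) {
    abort_recurisk("Expression TSV needs a gene id column plus at least one sample.",
                   "recurisk_format_error")
  }
  gene_ids <- df[[1]]
  body <- as.matrix(df[-1])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort_recurisk(
      sprintf("Non-numeric expression value at gene row %d ('%s'), sample column '%s'.",
              bad[1], gene_ids[bad[1]], colnames(df)[-1][bad[2]]),
      "recurisk_parse_error")
  }
  rownames(vals) <- gene_ids
  colnames(vals) <- colnames(df)[-1]
  if (log2_transform) vals <- log2(vals + 1)
  validate_expression(vals)
  vals
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: the round trip is value-identical to full
#' double precision.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  # format() at 17 significant digits round-trips IEEE doubles exactly
  df <- dplyr::mutate(df, dplyr::across(
    -"gene_id", ~ sub("^\\s+", "", format(.x, digits = 17, trim = TRUE, scientific = TRUE))))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical follow-up table from TSV
#'
#' Mandatory columns: `sample_id`, `time_months` (positive, months from
#' surgery), `event` (0/1; 1 = radiologically confirmed recurrence). An
#' optional `treatment_flag` column (`none`/`chemo`/`radio`/`unknown`) and any
#' further columns are preserved as covariates.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sample.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) {
    abort_recurisk(sprintf("Clinical file not found: %s", path), "recurisk_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  validate_clinical(df)
  df$event <- as.integer(df$event)
  df$time_months <- as.double(df$time_months)
  df$sample_id <- as.character(df$sample_id)
  tibble::as_tibble(df)
}

#' Write a clinical table to TSV
#'
#' @param clinical Clinical tibble (see [read_clinical()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  out <- dplyr::mutate(clinical, dplyr::across(
    dplyr::where(is.double),
    ~ sub("^\\s+", "", format(.x, digits = 17, trim = TRUE, scientific = TRUE))))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from GMT or two-column TSV
#'
#' Gene sets are returned in tidy form: one row per (set, gene) with a
#' `direction` column (`"up"` or `"down"`). GMT files (set name, description,
#' then genes) yield up-only sets. The two-column dialect is a TSV with
#' columns `set`, `gene` and optionally `direction`.
#'
#' @param path Path to the gene-set file.
#' @param dialect `"gmt"` or `"two_column"`.
#' @return Tibble with columns `set`, `gene`, `direction`.
#' @export
read_gene_sets <- function(path, dialect = c("gmt", "two_column")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_recurisk(sprintf("Gene-set file not found: %s", path), "recurisk_io_error")
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    rlang::warn("Gene-set file is empty; returning zero sets.")
    return(tibble::tibble(set = character(), gene = character(), direction = character()))
  }
  if (dialect == "gmt") {
    recs <- strsplit(lines, "\t", fixed = TRUE)
    sets <- purrr::map_dfr(recs, function(f) {
      if (length(f) < 3) {
        abort_recurisk(sprintf("GMT record '%s' has no genes.", f[1]), "recurisk_format_error")
      }
      tibble::tibble(set = f[1], gene = unique(f[-(1:2)]), direction = "up")
    })
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (!all(c("set", "gene") %in% names(df))) {
      abort_recurisk("two_column gene-set file needs columns `set` and `gene`.",
                     "recurisk_format_error")
    }
    if (!"direction" %in% names(df)) df$direction <- "up"
    sets <- tibble::as_tibble(df[c("set", "gene", "direction")])
  }
  validate_gene_sets(sets)
  sets
}

#' Construct a tidy gene-set table in code
#'
#' @param ... Named character vectors (up-regulated genes) or named lists with
#'   elements `up` and `down`.
#' @return Tibble with columns `set`, `gene`, `direction`.
#' @examples
#' gene_sets(cytotoxic = c("GZMA", "GZMB"), emt = list(up = "TGFBR1", down = "CDH1"))
#' @export
gene_sets <- function(...) {
  specs <- list(...)
  if (!length(specs) || is.null(names(specs)) || any(!nzchar(names(specs)))) {
    abort_recurisk("Every gene set must be named.", "recurisk_format_error")
  }
  out <- purrr::imap_dfr(specs, function(spec, nm) {
    if (is.character(spec)) spec <- list(up = spec, down = character())
    tibble::tibble(
      set = nm,
      gene = c(spec$up %||% character(), spec$down %||% character()),
      direction = rep(c("up", "down"),
                      c(length(spec$up %||% character()), length(spec$down %||% character()))))
  })
  validate_gene_sets(out)
  out
}

validate_gene_sets <- function(sets) {
  if (!all(sets$direction %in% c("up", "down"))) {
    abort_recurisk("Gene-set `direction` must be 'up' or 'down'.", "recurisk_value_error")
  }
  dup <- sets |>
    dplyr::distinct(.data$set, .data$gene, .data$direction) |>
    dplyr::count(.data$set, .data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort_recurisk(sprintf("Gene(s) listed as both up and down in set '%s': %s.",
                           dup$set[1], paste(dup$gene[dup$set == dup$set[1]], collapse = ", ")),
                   "recurisk_value_error")
  }
  if (anyDuplicated(sets[c("set", "gene")])) {
    abort_recurisk("Duplicate gene within a set.", "recurisk_value_error")
  }
  empty <- setdiff(unique(sets$set), sets$set[nzchar(sets$gene)])
  if (length(empty)) {
    abort_recurisk(sprintf("Gene set '%s' is empty.", empty[1]), "recurisk_value_error")
  }
  invisible(sets)
}

#' Write gene sets as GMT
#'
#' Only the `up` genes of each set are written (GMT is direction-less); use
#' the two-column TSV via [readr::write_tsv()] to preserve directions.
#'
#' @param sets Tidy gene-set tibble (`set`, `gene`, `direction`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path) {
  validate_gene_sets(sets)
  up <- dplyr::filter(sets, .data$direction == "up")
  lines <- vapply(split(up$gene, up$set), function(g) paste(g, collapse = "\t"), "")
  readr::write_lines(paste(names(lines), "na", lines, sep = "\t"), path)
  invisible(path)
}
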