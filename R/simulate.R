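#' Configuration for the planted-subgroup cohort simulator
#'
#' Defaults describe the cohort shape the pipeline was designed for: ~220
#' stage II tumors, two high-risk expression programs each carried by ~20% of
#' samples and marked by ~40 signature genes, a background of uninformative
#' genes, constant baseline recurrence hazard of 0.004 events/month with a
#' 4-fold hazard in each high-risk class, administrative censoring around 41
#' months and a 60-month follow-up cap.
#'
#' @param n_samples Number of samples.
#' @param frac_high1,frac_high2 Fractions of samples carrying program 1 / 2.
#' @param n_genes Total genes (programs + markers + noise).
#' @param n_sig_genes_per_program Signature genes per program.
#' @param effect_size Mean shift (in within-gene SD units) planted on a
#'   program's genes in its carrier class. Program 1 shifts are negative
#'   (loss of proliferation-like and epithelial-like expression), program 2
#'   shifts positive (gain of a TGF-beta-like program).
#' @param baseline_hazard Recurrence hazard of the low-risk class, events per
#'   month.
#' @param hr_high1,hr_high2 Hazard multipliers of the two high-risk classes.
#' @param followup_max_months Hard follow-up cap in months.
#' @param censor_admin_months Centre of the administrative censoring window.
#' @param censor_jitter_months Half-width of the uniform jitter around the
#'   administrative censoring time.
#' @param noise_sd Within-gene standard deviation of expression noise.
#' @param immune_depletion_high1 Optional positive shift subtracted from the
#'   immune marker genes in program-1 carriers (`NULL` = no depletion).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 220,
                             frac_high1 = 0.20, frac_high2 = 0.20,
                             n_genes = 2000,
                             n_sig_genes_per_program = 40,
                             effect_size = 1.0,
                             baseline_hazard = 0.004,
                             hr_high1 = 4.0, hr_high2 = 4.0,
                             followup_max_months = 60,
                             censor_admin_months = 41,
                             censor_jitter_months = 12,
                             noise_sd = 1.0,
                             immune_depletion_high1 = NULL,
                             seed = 1L) {
  cfg <- list(n_samples = n_samples, frac_high1 = frac_high1, frac_high2 = frac_high2,
              n_genes = n_genes, n_sig_genes_per_program = n_sig_genes_per_program,
              effect_size = effect_size, baseline_hazard = baseline_hazard,
              hr_high1 = hr_high1, hr_high2 = hr_high2,
              followup_max_months = followup_max_months,
              censor_admin_months = censor_admin_months,
              censor_jitter_months = censor_jitter_months,
              noise_sd = noise_sd,
              immune_depletion_high1 = immune_depletion_high1,
              seed = as.integer(seed))
  if (cfg$frac_high1 + cfg$frac_high2 >= 1) {
    abort_recurisk("Class fractions must sum to less than 1.", "recurisk_config_error")
  }
  if (cfg$baseline_hazard <= 0 || cfg$hr_high1 <= 0 || cfg$hr_high2 <= 0) {
    abort_recurisk("Hazards and hazard ratios must be positive.", "recurisk_config_error")
  }
  if (2 * cfg$n_sig_genes_per_program > cfg$n_genes) {
    abort_recurisk("Programs need 2 * n_sig_genes_per_program <= n_genes.",
                   "recurisk_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

#' Epithelial marker genes used for canonical subgroup numbering
#'
#' @return Character vector of epithelial marker symbols.
#' @export
epithelial_markers <- function() c("EPCAM", "CDH1", "EGFR", "MET")

immune_marker_symbols <- function() {
  c("FCGR3A", "CD68", "CD3D", "CD3E", "CD244", "LAG3", "HSD11B1",
    "CD19", "CD8A", "GZMA", "GZMB", "KLRD1", "PRF1")
}

#' Simulate a cohort with two planted high-risk expression programs
#'
#' Samples are assigned to classes `low`, `high1`, `high2` by the configured
#' fractions. Expression is Gaussian noise around per-gene baselines, with
#' `effect_size` shifts planted on each program's genes in its carrier class:
#' program 1 genes (which include the epithelial markers when the program is
#' large enough) are shifted *down* in `high1` carriers, program 2 genes
#' shifted *up* in `high2` carriers. Immune marker genes are carried along as
#' role `marker` and optionally depleted in `high1`. Failure times are
#' exponential with class-specific hazard; censoring is administrative with
#' uniform jitter, capped at the maximum follow-up.
#'
#' @param config A [synthetic_config()].
#' @return A `synthetic_cohort` list with elements `expr` (genes x samples
#'   matrix, log2 scale), `clinical` (tibble), `truth_samples` (tibble
#'   `sample_id`, `class`), `truth_genes` (tibble `gene_id`, `role`), and
#'   `config`.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- derive_seeds(config$seed, 4)
  n <- config$n_samples
  p <- config$n_genes
  k <- config$n_sig_genes_per_program

  # gene roles: block-assigned deterministically
  epi <- if (k >= 8) epithelial_markers() else character()
  imm <- if (p >= 2 * k + length(immune_marker_symbols()) + 1) immune_marker_symbols() else character()
  n_generic <- p - length(epi) - length(imm)
  generic <- sprintf("G%05d", seq_len(n_generic))
  prog1 <- c(epi, generic[seq_len(k - length(epi))])
  prog2 <- generic[(k - length(epi) + 1):(2 * k - length(epi))]
  n_used <- 2 * k - length(epi)
  noise_ids <- if (n_generic > n_used) generic[(n_used + 1):n_generic] else character()
  gene_ids <- c(prog1, prog2, imm, noise_ids)
  role <- rep("noise", p)
  names(role) <- gene_ids
  role[prog1] <- "program1"
  role[prog2] <- "program2"
  role[imm] <- "marker"

  sample_ids <- sprintf("S%04d", seq_len(n))

  # class draw
  cls <- withr::with_seed(seeds[1], {
    sample(c("low", "high1", "high2"), n, replace = TRUE,
           prob = c(1 - config$frac_high1 - config$frac_high2,
                    config$frac_high1, config$frac_high2))
  })

  # expression: per-gene baseline + noise + planted shifts
  expr <- withr::with_seed(seeds[2], {
    baseline <- stats::rnorm(p, mean = 6, sd = 1.5)
    m <- matrix(stats::rnorm(p * n, sd = config$noise_sd), nrow = p,
                dimnames = list(gene_ids, sample_ids))
    m + baseline
  })
  shift <- config$effect_size * config$noise_sd
  if (shift != 0) {
    expr[prog1, cls == "high1"] <- expr[prog1, cls == "high1"] - shift
    expr[prog2, cls == "high2"] <- expr[prog2, cls == "high2"] + shift
  }
  if (!is.null(config$immune_depletion_high1) && length(imm)) {
    expr[imm, cls == "high1"] <-
      expr[imm, cls == "high1"] - config$immune_depletion_high1 * config$noise_sd
  }

  # survival: exponential failure, administrative censoring with jitter
  hz <- config$baseline_hazard *
    c(low = 1, high1 = config$hr_high1, high2 = config$hr_high2)[cls]
  surv <- withr::with_seed(seeds[3], {
    t_fail <- stats::rexp(n, rate = hz)
    c_admin <- config$censor_admin_months +
      stats::runif(n, -config$censor_jitter_months, config$censor_jitter_months)
    c_time <- pmin(pmax(c_admin, 0.5), config$followup_max_months)
    tibble::tibble(time_months = pmin(t_fail, c_time),
                   event = as.integer(t_fail <= c_time))
  })

  clinical <- tibble::tibble(sample_id = sample_ids,
                             time_months = surv$time_months,
                             event = surv$event,
                             treatment_flag = "none")

  structure(list(
    expr = expr,
    clinical = clinical,
    truth_samples = tibble::tibble(sample_id = sample_ids, class = cls),
    truth_genes = tibble::tibble(gene_id = gene_ids, role = unname(role[gene_ids])),
    config = config
  ), class = "synthetic_cohort")
}

#' Summarize a simulated cohort
#'
#' @param cohort A `synthetic_cohort`.
#' @return Tibble with one row per planted class: sample counts, event counts
#'   and fractions, median follow-up among censored samples, and the realized
#'   mean planted shift of the class's program genes.
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  df <- dplyr::left_join(cohort$clinical, cohort$truth_samples, by = "sample_id")
  roles <- split(cohort$truth_genes$gene_id, cohort$truth_genes$role)
  overall_means <- rowMeans(cohort$expr)
  realized_shift <- function(class_name, genes) {
    if (!length(genes) || !any(df$class == class_name)) return(NA_real_)
    idx <- df$class == class_name
    mean(rowMeans(cohort$expr[genes, idx, drop = FALSE]) - overall_means[genes])
  }
  df |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_events = sum(.data$event),
      event_fraction = mean(.data$event),
      median_followup_censored = stats::median(.data$time_months[.data$event == 0]),
      .groups = "drop") |>
    dplyr::mutate(
      class_fraction = .data$n / sum(.data$n),
      realized_program_shift = dplyr::case_when(
        class == "high1" ~ realized_shift("high1", roles$program1),
        class == "high2" ~ realized_shift("high2", roles$program2),
        TRUE ~ NA_real_))
}

#' Write a simulated cohort to TSV files
#'
#' Writes the expression matrix, clinical table and both truth tables in the
#' same formats [read_expression()] and [read_clinical()] read.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth_samples = file.path(dir, "truth_samples.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"))
  write_expression(cohort$expr, paths["expression"])
  write_clinical(cohort$clinical, paths["clinical"])
  readr::write_tsv(cohort$truth_samples, paths["truth_samples"], progress = FALSE)
  readr::write_tsv(cohort$truth_genes, paths["truth_genes"], progress = FALSE)
  invisible(paths)
}
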