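# Discovery-stage tests run on reduced cohorts so the suite stays fast;
# full-scale behavior is exercised by the acceptance suite.

strong_cohort <- function(seed = 41, n = 120, effect = 2.5) {
  simulate_cohort(synthetic_config(
    n_samples = n, n_genes = 400, n_sig_genes_per_program = 20,
    effect_size = effect, seed = seed))
}

test_that("partition recovers planted subgroups under strong separation", {
  co <- strong_cohort()
  part <- partition_recurrence(co$expr, co$clinical,
                               discovery_config(n_variance_genes = 200))
  truth <- co$truth_samples$class[match(part$sample_id, co$truth_samples$sample_id)]
  carrier <- truth %in% c("high1", "high2")
  tab <- table(part$branch[carrier], truth[carrier])
  acc <- max(sum(diag(tab)), sum(tab[1, 2], tab[2, 1])) / sum(tab)
  expect_gte(acc, 0.90)
  # canonical numbering: branch 1 is the epithelial-low (program-1) branch
  b1 <- part$sample_id[part$branch == 1]
  expect_gt(mean(truth[part$branch == 1] == "high1"),
            mean(truth[part$branch == 2] == "high1"))
  expect_s3_class(attr(part, "cohesion"), "tbl_df")
})

test_that("single-branch configs and duplication invariance behave", {
  co <- strong_cohort(seed = 6, n = 60)
  part1 <- partition_recurrence(co$expr, co$clinical,
                                discovery_config(n_branches = 1))
  expect_true(all(part1$branch == 1L))
  expect_setequal(part1$sample_id,
                  co$clinical$sample_id[co$clinical$event == 1])

  # duplicating every sample's profile leaves original memberships unchanged
  part <- partition_recurrence(co$expr, co$clinical, discovery_config())
  expr2 <- cbind(co$expr, `colnames<-`(co$expr, paste0(colnames(co$expr), "_d")))
  cl2 <- dplyr::bind_rows(co$clinical,
                          dplyr::mutate(co$clinical, sample_id = paste0(sample_id, "_d")))
  part2 <- partition_recurrence(expr2, cl2, discovery_config())
  m <- dplyr::inner_join(part, part2, by = "sample_id")
  agree <- mean(m$branch.x == m$branch.y)
  expect_true(agree >= 0.95 || agree <= 0.05) # up to a global label swap
})

test_that("too few recurrence samples is an error", {
  cl <- make_clinical(c(10, 20, 30, 40), c(1, 0, 0, 0))
  m <- matrix(stats::rnorm(40), 10,
              dimnames = list(paste0("G", 1:10), cl$sample_id))
  expect_error(partition_recurrence(m, cl, discovery_config()),
               class = "recurisk_data_error")
})

test_that("prescreen: vacuous and empty thresholds, nesting, planted recovery", {
  co <- simulate_cohort(synthetic_config(
    n_samples = 200, n_genes = 100, n_sig_genes_per_program = 10,
    effect_size = 2, seed = 12))
  expect_identical(length(prescreen_genes(co$expr, co$clinical, alpha = 0)), 0L)
  all_sel <- prescreen_genes(co$expr, co$clinical, alpha = 1.0)
  skipped <- attr(all_sel, "skipped")
  expect_identical(length(all_sel) + length(skipped), nrow(co$expr))

  # nesting: alpha1 <= alpha2 implies subset
  s1 <- prescreen_genes(co$expr, co$clinical, alpha = 0.01)
  s2 <- prescreen_genes(co$expr, co$clinical, alpha = 0.10)
  expect_true(all(s1 %in% s2))

  # a strongly planted hazard gene is recovered
  prog <- co$truth_genes$gene_id[co$truth_genes$role == "program2"]
  expect_gt(mean(prog %in% s2), 0.5)
})

test_that("stability selection: vacuous top-k, determinism, order invariance", {
  co <- strong_cohort(seed = 19, n = 100)
  cl <- co$clinical
  branch <- cl$sample_id[cl$event == 1][1:6]
  norec <- cl$sample_id[cl$event == 0]
  genes <- rownames(co$expr)[1:30] # universe smaller than top_k
  cfg <- discovery_config(cv_rounds = 4, cv_folds = 3, seed = 55)

  st <- stability_select(co$expr, cl, branch, norec, cfg, genes = genes)
  expect_true(all(st$frequency == 1))
  expect_true(all(st$selected))
  expect_identical(attr(st, "n_fold_fits"), 12)

  st2 <- stability_select(co$expr, cl, branch, norec, cfg, genes = genes)
  expect_identical(tibble::as_tibble(st), tibble::as_tibble(st2))

  # permuting gene rows of the matrix leaves frequencies unchanged
  perm <- sample(nrow(co$expr))
  st3 <- stability_select(co$expr[perm, ], cl, branch, norec, cfg, genes = genes)
  m <- dplyr::inner_join(tibble::as_tibble(st), tibble::as_tibble(st3), by = "gene_id")
  expect_equal(m$frequency.x, m$frequency.y)
})

test_that("stability selection enriches planted genes on a reduced cohort", {
  co <- strong_cohort(seed = 23, n = 140, effect = 2.5)
  cl <- co$clinical
  truth <- setNames(co$truth_samples$class, co$truth_samples$sample_id)
  branch <- cl$sample_id[cl$event == 1 & truth[cl$sample_id] == "high2"]
  norec <- cl$sample_id[cl$event == 0]
  st <- stability_select(co$expr, cl, branch, norec,
                         discovery_config(cv_rounds = 8, cv_folds = 5,
                                          top_k = 30, seed = 9))
  sel <- st$gene_id[st$selected]
  roles <- setNames(co$truth_genes$role, co$truth_genes$gene_id)
  expect_gt(mean(roles[sel] == "program2"), 0.5)
  expect_gt(length(sel), 5)
})

test_that("hit frequencies stabilize as rounds accumulate", {
  co <- strong_cohort(seed = 47, n = 100)
  cl <- co$clinical
  branch <- cl$sample_id[cl$event == 1]
  norec <- cl$sample_id[cl$event == 0]
  genes <- rownames(co$expr)[1:60]
  run_freq <- function(rounds, seed) {
    stability_select(co$expr, cl, branch, norec,
                     discovery_config(cv_rounds = rounds, cv_folds = 4,
                                      top_k = 10, seed = seed),
                     genes = genes) |>
      dplyr::arrange(gene_id) |>
      dplyr::pull(frequency)
  }
  # run-to-run frequency scatter shrinks when rounds increase 5 -> 25
  spread <- function(rounds) {
    mean(abs(run_freq(rounds, 1) - run_freq(rounds, 2)))
  }
  expect_lt(spread(25), spread(5))
})

test_that("stability selection guards its preconditions", {
  co <- strong_cohort(seed = 29, n = 60)
  cl <- co$clinical
  rec <- cl$sample_id[cl$event == 1]
  norec <- cl$sample_id[cl$event == 0]
  expect_error(stability_select(co$expr, cl, rec[1:2], norec,
                                discovery_config(cv_folds = 10)),
               "cv_folds", class = "recurisk_config_error")
  expect_error(stability_select(co$expr, cl, rec, c(norec, rec[1]),
                                discovery_config()),
               class = "recurisk_value_error")
  expect_error(stability_select(co$expr, cl, character(), norec,
                                discovery_config()),
               class = "recurisk_data_error")
})

test_that("config validation rejects bad values", {
  expect_error(discovery_config(cv_folds = 1), class = "recurisk_config_error")
  expect_error(discovery_config(freq_threshold = 0), class = "recurisk_config_error")
  expect_error(discovery_config(top_k = 0), class = "recurisk_config_error")
})
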