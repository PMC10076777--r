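# End-to-end trainer tests use small cohorts with strong planted effects so
# each run stays in the seconds range.

small_train_setup <- function(seed = 101) {
  co <- simulate_cohort(synthetic_config(
    n_samples = 140, n_genes = 300, n_sig_genes_per_program = 15,
    effect_size = 2.5, seed = seed))
  cfg <- discovery_config(cv_rounds = 5, cv_folds = 4, top_k = 40, seed = seed + 1)
  list(co = co, cfg = cfg)
}

test_that("trainer produces a two-signature model with plausible content", {
  s <- small_train_setup()
  model <- suppressWarnings(train_risk_model(s$co$expr, s$co$clinical, s$cfg))
  expect_s3_class(model, "risk_model")
  expect_gte(length(model$sig1$genes), 5)
  expect_gte(length(model$sig2$genes), 5)
  expect_false(is.na(model$sig1$cutoff))
  expect_false(is.na(model$sig2$cutoff))

  # signatures are enriched for the planted programs (numbering canonical:
  # subgroup 1 = epithelial-loss = planted program 1)
  roles <- setNames(s$co$truth_genes$role, s$co$truth_genes$gene_id)
  expect_gt(mean(roles[model$sig1$genes] == "program1"), 0.3)
  expect_gt(mean(roles[model$sig2$genes] == "program2"), 0.3)

  # training-time metrics are populated and the model prints/tidies
  expect_true(is.finite(model$training$metrics$hr))
  expect_s3_class(tidy(model), "tbl_df")
  expect_identical(nrow(glance(model)), 1L)
  expect_output(print(model), "risk model")
})

test_that("training is reproducible: identical seeds give identical model files", {
  s <- small_train_setup(seed = 55)
  m1 <- suppressWarnings(train_risk_model(s$co$expr, s$co$clinical, s$cfg))
  m2 <- suppressWarnings(train_risk_model(s$co$expr, s$co$clinical, s$cfg))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_risk_model(m1, p1)
  save_risk_model(m2, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("predictions on training samples reproduce training-time calls", {
  s <- small_train_setup(seed = 77)
  model <- suppressWarnings(train_risk_model(s$co$expr, s$co$clinical, s$cfg))
  calls <- predict_risk(model, s$co$expr)
  train_calls <- model$training$calls
  m <- dplyr::inner_join(calls, train_calls, by = "sample_id")
  expect_identical(m$label.x, m$label.y)
  expect_equal(m$combined_score.x, m$combined_score.y)
})

test_that("held-out classification beats chance on a strong-effect cohort", {
  s <- small_train_setup(seed = 31)
  ids <- colnames(s$co$expr)
  train_ids <- withr::with_seed(1, sort(sample(ids, 70)))
  test_ids <- setdiff(ids, train_ids)
  cl_train <- s$co$clinical[s$co$clinical$sample_id %in% train_ids, ]
  model <- suppressWarnings(
    train_risk_model(s$co$expr[, train_ids], cl_train, s$cfg))
  calls <- predict_risk(model, s$co$expr[, test_ids])
  truth <- s$co$truth_samples$class[match(test_ids, s$co$truth_samples$sample_id)]
  high_truth <- truth %in% c("high1", "high2")
  high_pred <- calls$label != "low_risk"
  expect_gt(mean(high_truth == high_pred), 0.6)
})

test_that("trainer rejects cohorts without enough events", {
  co <- simulate_cohort(synthetic_config(
    n_samples = 40, n_genes = 50, n_sig_genes_per_program = 5,
    baseline_hazard = 1e-6, hr_high1 = 1, hr_high2 = 1, seed = 2))
  expect_error(train_risk_model(co$expr, co$clinical, discovery_config()),
               class = "recurisk_data_error")
})

test_that("evaluation handles a single risk arm with NA and a warning", {
  cl <- make_clinical(c(10, 20, 30, 40), c(1, 0, 1, 0))
  calls <- tibble::tibble(sample_id = cl$sample_id,
                          combined_score = c(0.5, 0.1, 0.4, 0.2),
                          label = "high_risk_1")
  expect_warning(ev <- evaluate_risk(calls, cl), "one risk arm")
  expect_true(is.na(ev$hr))
  expect_true(is.na(ev$logrank_p))
  expect_equal(ev$high_fraction, 1)
  expect_equal(ev$auc, concordance_auc(calls$combined_score, cl$event))
})

test_that("evaluation of perfectly separating calls yields AUC 1", {
  cl <- make_clinical(c(5, 8, 50, 55), c(1, 1, 0, 0))
  calls <- tibble::tibble(sample_id = cl$sample_id,
                          combined_score = c(2, 1.5, -1, -2),
                          label = c("high_risk_1", "high_risk_2", "low_risk", "low_risk"))
  ev <- evaluate_risk(calls, cl)
  expect_equal(ev$auc, 1)
  expect_equal(ev$high_fraction, 0.5)
})

test_that("evaluation reports populated confidence bounds per arm", {
  withr::with_seed(12, {
    cl <- random_cohort(60, p_event = 0.4)
    calls <- tibble::tibble(sample_id = cl$sample_id,
                            combined_score = stats::rnorm(60),
                            label = rep(c("low_risk", "high_risk_1"), 30))
    ev <- evaluate_risk(calls, cl, t_eval = 30)
    expect_true(all(is.finite(c(ev$rfs_low_lower, ev$rfs_low_upper,
                                ev$rfs_high_lower, ev$rfs_high_upper))))
    expect_true(ev$rfs_low_lower <= ev$rfs_low &&
                  ev$rfs_low <= ev$rfs_low_upper)
  })
})
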