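zmat <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

test_that("centroids are group means; single-sample and degenerate sets", {
  z <- zmat(c(1, 0, -1, -1, 0, 1, 2, 2, 2), paste0("G", 1:3), paste0("S", 1:3))
  sig <- build_signature(z, "S1", c("S2", "S3"), paste0("G", 1:3), "subgroup1")
  expect_equal(sig$centroid_high, unname(z[, "S1"]))
  expect_equal(sig$centroid_low, unname(rowMeans(z[, c("S2", "S3")])))
  expect_warning(build_signature(z, "S1", "S1", "G1", "s"), "identical")
  expect_error(build_signature(z, character(), "S1", "G1", "s"),
               class = "recurisk_value_error")
  expect_error(build_signature(z, "S1", "S2", "GX", "s"),
               class = "recurisk_key_error")
})

test_that("correlation-difference scoring: perfect match, symmetry, affine invariance", {
  genes <- paste0("G", 1:3)
  z <- zmat(c(1, 0, -1), genes, "S1")
  sig <- build_signature(
    zmat(c(1, 0, -1, -1, 0, 1), genes, c("H", "L")), "H", "L", genes, "s")
  expect_equal(unname(score_samples(sig, z)), 2)

  # a sample equally correlated with both centroids scores 0
  z0 <- zmat(c(0, 1, 0), genes, "S1")
  expect_equal(unname(score_samples(sig, z0)), 0, tolerance = 1e-12)

  # positive affine transforms of the sample vector leave the score unchanged
  z2 <- 3 * z + 5
  expect_equal(score_samples(sig, z2), score_samples(sig, z))
})

test_that("missing-gene policy: pairwise drop below 5%, error above", {
  genes <- sprintf("G%03d", 1:100)
  withr::with_seed(8, {
    zh <- zmat(stats::rnorm(200), genes, c("H", "L"))
    sig <- build_signature(zh, "H", "L", genes, "s")
    full <- zmat(stats::rnorm(100), genes, "S1")
    partial <- full[1:97, , drop = FALSE] # 3% missing
    expect_message(s_part <- score_samples(sig, partial), "available")
    expect_true(is.finite(s_part))
    tiny <- full[1:80, , drop = FALSE] # 20% missing
    expect_error(score_samples(sig, tiny), class = "recurisk_coverage_error")
  })
})

test_that("cutoff optimization: perfect separation, constraints, degenerate input", {
  cl <- make_clinical(c(50, 55, 60, 5, 8, 12), c(0, 0, 0, 1, 1, 1))
  scores <- c(-1, -1, -1, 1, 1, 1)
  ct <- optimize_cutoff(scores, cl, min_group_frac = 0.1)
  expect_gt(ct, -1)
  expect_lt(ct, 1)
  expect_identical(sum(scores > ct), 3L)

  expect_error(optimize_cutoff(rep(0.3, 6), cl), class = "recurisk_degenerate_error")
  # constraint can exclude all cutpoints
  expect_error(optimize_cutoff(c(-1, rep(1, 5)), cl, min_group_frac = 0.4),
               class = "recurisk_degenerate_error")
})

test_that("three-way calls follow the OR rule, margins and tie-breaks", {
  genes <- paste0("G", 1:4)
  zh <- zmat(c(1, 1, -1, -1, -1, -1, 1, 1), genes, c("H", "L"))
  sig1 <- build_signature(zh, "H", "L", genes, "subgroup1")
  sig2 <- build_signature(zh, "H", "L", genes, "subgroup2")
  sig1$cutoff <- -0.0850
  sig2$cutoff <- -0.0005

  # sample aligned with the high centroid: both margins positive, tie rule
  z <- zmat(c(1, 1, -1, -1), genes, "S1")
  calls <- classify(sig1, sig2, z)
  expect_identical(calls$label, "high_risk_1")
  expect_equal(calls$combined_score, max(calls$margin1, calls$margin2))

  # sample aligned with the low centroid: both margins negative
  zl <- zmat(c(-1, -1, 1, 1), genes, "S1")
  expect_identical(classify(sig1, sig2, zl)$label, "low_risk")

  # score above cutoff1 only, second signature below its cutoff
  sig2b <- sig2
  sig2b$centroid_high <- c(-1, -1, 1, 1); sig2b$centroid_low <- c(1, 1, -1, -1)
  sig2b$cutoff <- 0.5
  zm <- zmat(c(1, 1, -1, -1), genes, "S1")
  c2 <- classify(sig1, sig2b, zm)
  expect_true(c2$margin1 > 0 && c2$margin2 < 0)
  expect_identical(c2$label, "high_risk_1")

  # low-risk iff both margins non-positive (invariant over random samples)
  withr::with_seed(14, {
    zr <- zmat(stats::rnorm(40), genes, paste0("R", 1:10))
    cr <- classify(sig1, sig2, zr)
    expect_identical(cr$label == "low_risk", cr$margin1 <= 0 & cr$margin2 <= 0)
  })

  sig1$cutoff <- NA_real_
  expect_error(classify(sig1, sig2, z), class = "recurisk_value_error")
})

test_that("classify is invariant to sample order", {
  withr::with_seed(3, {
    genes <- paste0("G", 1:6)
    zh <- zmat(stats::rnorm(12), genes, c("H", "L"))
    sig1 <- build_signature(zh, "H", "L", genes, "s1"); sig1$cutoff <- 0
    sig2 <- build_signature(zh[, c(2, 1)], "L", "H", genes, "s2"); sig2$cutoff <- 0.2
    z <- zmat(stats::rnorm(60), genes, paste0("S", 1:10))
    a <- classify(sig1, sig2, z)
    b <- classify(sig1, sig2, z[, 10:1])
    expect_equal(dplyr::arrange(a, sample_id), dplyr::arrange(b, sample_id))
  })
})

test_that("model JSON round trip preserves classify output exactly", {
  withr::with_seed(9, {
    genes <- sprintf("G%02d", 1:20)
    expr <- matrix(stats::rnorm(200, 6), 20, dimnames = list(genes, paste0("S", 1:10)))
    std <- standardize_expression(expr)
    sig1 <- build_signature(std$z, paste0("S", 1:3), paste0("S", 4:10), genes[1:8],
                            "subgroup1", standardization = std$params)
    sig2 <- build_signature(std$z, paste0("S", 4:5), paste0("S", 6:10), genes[9:16],
                            "subgroup2", standardization = std$params)
    sig1$cutoff <- -0.0850; sig2$cutoff <- -0.0005
    before <- classify(sig1, sig2, expr)

    path <- withr::local_tempfile(fileext = ".json")
    save_model(sig1, sig2, list(seed = 1), path)
    m <- load_model(path)
    after <- classify(m$sig1, m$sig2, expr)
    expect_equal(after, before, tolerance = 0)

    # tampered gene list breaks integrity
    payload <- jsonlite::read_json(path)
    payload$signatures[[1]]$genes <- payload$signatures[[1]]$genes[-1]
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
    expect_error(load_model(path), class = "recurisk_integrity_error")

    # version mismatch warns but loads
    payload$signatures[[1]]$genes <- as.list(genes[1:8])
    payload$package_version <- "0.0.1"
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
    expect_warning(load_model(path), "version")

    # corrupted file errors
    writeLines("{not json", path)
    expect_error(load_model(path), class = "recurisk_integrity_error")
  })
})

test_that("documented default cutoffs are exposed", {
  expect_equal(unname(default_cutoffs()), c(-0.0850, -0.0005))
})
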