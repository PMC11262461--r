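test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_adjust(0.07), 0.07)
  # hand-computed step-up: min over tails of p * m / rank, capped at 1
  p <- c(0.005, 0.9, 0.04, 0.03, 0.6)
  m <- length(p)
  r <- rank(p)
  hand <- vapply(seq_len(m), function(i) {
    min(1, min((p * m / r)[r >= r[i]]))
  }, numeric(1))
  expect_equal(bh_adjust(p), hand)
  # order invariance and NA passthrough
  o <- sample(m)
  expect_equal(bh_adjust(p[o]), hand[o])
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("decay-rate selection returns the AIC minimizer with a full table", {
  sim <- simulate_ccc(n_units = 100, n_types = 2,
                      beta = matrix(c(0, 0, 1.2, 0), 2, 2), rho = 0.5,
                      dmax = 2, seed = 61)
  sc <- sim$truth$scores
  cfg <- ccc_config(refine_smoothing = FALSE,
                    lambda_grid = 10^seq(-2, 2, length.out = 3))
  one <- select_rho(sim$dataset, sc$score, sc[, 1:3], candidates = 0.7,
                    partition = sim$truth$partition, config = cfg)
  expect_equal(one$rho, 0.7)
  expect_equal(nrow(one$aic_table), 1)
  multi <- select_rho(sim$dataset, sc$score, sc[, 1:3],
                      candidates = c(0, 0.5, 2),
                      partition = sim$truth$partition, config = cfg)
  expect_equal(nrow(multi$aic_table), 3)
  expect_equal(multi$rho,
               multi$aic_table$rho[which.min(multi$aic_table$aic)])
  expect_error(select_rho(sim$dataset, sc$score, sc[, 1:3], numeric(0),
                          sim$truth$partition, cfg), "at least one")
})

test_that("per-pair inference emits G^2 rows per measurable pair, deterministically", {
  sim <- simulate_ccc(n_units = 120, n_types = 2,
                      beta = matrix(c(0, 0, 1.5, 0), 2, 2), rho = 0.5,
                      dmax = 1.6, n_noise_genes = 4, n_null_pairs = 1,
                      seed = 62)
  cfg <- ccc_config(rho_candidates = 0.5, refine_smoothing = FALSE,
                    lambda_grid = 10^seq(-2, 2, length.out = 3))
  res <- suppressMessages(infer_ccc(sim$dataset, sim$lr_db, dmax = 1.6,
                                    config = cfg))
  expect_s3_class(res, "ccc_result")
  expect_equal(nrow(res), 2 * 4)          # 2 measurable pairs x G^2
  expect_true(all(res$p_adjusted >= res$p_value - 1e-12, na.rm = TRUE))
  expect_true(all(res$p_adjusted <= 1, na.rm = TRUE))
  expect_true(all(res$rho_selected == 0.5))
  res2 <- suppressMessages(infer_ccc(sim$dataset, sim$lr_db, dmax = 1.6,
                                     config = cfg))
  expect_identical(res, res2)             # determinism
  # G = 1 single-cell data: exactly one test row per pair
  sim1 <- simulate_ccc(n_units = 80, n_types = 1, beta = matrix(1, 1, 1),
                       rho = 0.5, dmax = 2, seed = 63)
  res1 <- suppressMessages(infer_ccc(sim1$dataset, sim1$lr_db[1, ], dmax = 2,
                                     config = cfg))
  expect_equal(nrow(res1), 1)
  # unmeasurable pairs are reported in the failure message
  db_bad <- lr_database("ABSENT1", "ABSENT2")
  expect_error(suppressWarnings(
    infer_ccc(sim1$dataset, db_bad, dmax = 2, config = cfg)
  ), "ABSENT1")
})

test_that("relabeling cell types permutes result rows equivariantly", {
  sim <- simulate_ccc(n_units = 100, n_types = 2,
                      beta = matrix(c(0, 0, 1.5, 0), 2, 2), rho = 0.5,
                      dmax = 1.8, seed = 64)
  cfg <- ccc_config(rho_candidates = 0.5, refine_smoothing = FALSE,
                    lambda_grid = 10^seq(-2, 2, length.out = 3))
  res <- suppressMessages(infer_ccc(sim$dataset, sim$lr_db, dmax = 1.8,
                                    config = cfg))
  ds2 <- sim$dataset
  relabel <- c(T1 = "zeta", T2 = "alpha")
  colnames(ds2$composition) <- relabel[colnames(ds2$composition)]
  ds2$type_names <- colnames(ds2$composition)
  # column order follows the stored composition, so re-sort as a user would
  ord <- order(ds2$type_names)
  ds2$composition <- ds2$composition[, ord]
  ds2$type_names <- ds2$type_names[ord]
  res2 <- suppressMessages(infer_ccc(ds2, sim$lr_db, dmax = 1.8, config = cfg))
  key <- function(r, map) {
    paste(map[r$sender_type], map[r$receiver_type])
  }
  idx <- match(key(res, relabel),
               paste(res2$sender_type, res2$receiver_type))
  expect_false(anyNA(idx))
  expect_equal(res$estimate, res2$estimate[idx], tolerance = 1e-6)
  expect_equal(res$p_value, res2$p_value[idx], tolerance = 1e-5)
})

test_that("pathway aggregation sums member responses on the shared pair set", {
  sim <- simulate_ccc(n_units = 60, n_types = 2, dmax = 3,
                      n_noise_genes = 10, n_null_pairs = 3, seed = 65)
  pairs <- build_pair_set(sim$dataset$coords, 3)
  # brute-force oracle: column sums of the per-pair response matrix
  members <- sim$lr_db[sim$lr_db$pathway == "NULLPW", ]
  per_pair <- sapply(seq_len(nrow(members)), function(k) {
    sc <- communication_scores(sim$dataset$expr, members[k, ])
    sc$L[pairs$sender] * sc$R[pairs$receiver]
  })
  pooled <- aggregate_pathway(sim$dataset, sim$lr_db, "NULLPW", pairs)
  expect_equal(pooled, rowSums(per_pair), tolerance = 1e-12)
  # a single-pair pathway is identical to that pair's own response
  one <- aggregate_pathway(sim$dataset, sim$lr_db, "SIM", pairs)
  sc1 <- communication_scores(sim$dataset$expr, sim$lr_db[1, ])
  expect_equal(one, sc1$L[pairs$sender] * sc1$R[pairs$receiver])
  # elementary addition example
  expect_equal(c(1, 0, 2) + c(0, 0, 3), c(1, 0, 5))
  expect_error(aggregate_pathway(sim$dataset, sim$lr_db, "NOPE", pairs),
               "unknown pathway")
})

test_that("pathway-level inference labels rows and reuses the fit path", {
  sim <- simulate_ccc(n_units = 100, n_types = 2,
                      beta = matrix(c(0, 0, 1.5, 0), 2, 2), rho = 0.5,
                      dmax = 1.8, n_noise_genes = 4, n_null_pairs = 1,
                      seed = 66)
  cfg <- ccc_config(rho_candidates = 0.5, refine_smoothing = FALSE,
                    lambda_grid = 10^seq(-2, 2, length.out = 3))
  res <- suppressMessages(
    infer_ccc_pathway(sim$dataset, sim$lr_db, dmax = 1.8, config = cfg)
  )
  expect_true(all(startsWith(res$ligand, "pathway:")))
  expect_setequal(unique(res$pathway), c("SIM", "NULLPW"))
  expect_equal(nrow(res), 2 * 4)
})
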