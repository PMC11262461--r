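test_that("the log-link score equation collapses to the mean for intercept-only fits", {
  # one cell type at rho = 0 aliases the single interaction column with the
  # intercept (it is dropped), and huge penalties force the random effects
  # to zero: the fit is effectively intercept-only, so mu-hat = mean(y)
  set.seed(12)
  des <- make_score_design(seed = 31, g = 1, beta12 = 0.4, rho = 0)
  y <- des$pairs$response
  fit <- pirls_fit(des, p = 1.5, lambda_L = 1e10, lambda_R = 1e10)
  expect_equal(length(fit$dropped), 1)
  expect_lt(diff(range(fit$fitted)) / mean(y), 1e-6)
  expect_equal(fit$beta0, log(mean(y)), tolerance = 1e-6)
  # constant positive response: exact fit with zero deviance
  des2 <- des
  des2$pairs$response <- rep(2.5, nrow(des$pairs))
  fit2 <- pirls_fit(des2, p = 1.5, lambda_L = 1e10, lambda_R = 1e10)
  expect_equal(fit2$deviance, 0, tolerance = 1e-10)
  expect_equal(fit2$beta0, log(2.5), tolerance = 1e-8)
})

test_that("PIRLS coefficients match a generic optimizer of the penalized objective", {
  for (seed in 1:3) {
    des <- make_score_design(seed = seed, g = 2, n_rows = 80)
    fit <- pirls_fit(des, p = 1.5, lambda_L = 1, lambda_R = 1)
    oracle <- oracle_optimize(des, 1.5, 1, 1)
    ours <- c(fit$beta0, unname(fit$beta), fit$nu_L, fit$nu_R)
    expect_lt(max(abs(ours - oracle)), 1e-4)
    expect_true(fit$converged)
  }
})

test_that("fit invariants hold: edf range, AIC identity, covariance psd, shrinkage", {
  des <- make_score_design(seed = 44, g = 2, n_units = 60, beta12 = 1)
  fit <- fit_tweedie_gam(des)
  k_total <- 1 + 4 + 2 * des$ngrid
  expect_gte(fit$edf, 1)
  expect_lte(fit$edf, k_total)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$edf, tolerance = 1e-8)
  expect_equal(fit$aic, model_aic(fit))
  ev <- eigen(fit$cov_beta, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(fit$cov_beta, t(fit$cov_beta), tolerance = 1e-12)
  # ||nu_L|| non-increasing in lambda_L at fixed lambda_R
  norms <- vapply(c(0.01, 0.1, 1, 10, 100), function(l) {
    sqrt(sum(pirls_fit(des, 1.5, l, 1)$nu_L^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("GCV at huge smoothing matches a fixed-effects-only fit", {
  des <- make_score_design(seed = 45, g = 2, n_units = 60, beta12 = 1)
  y <- des$pairs$response
  p <- 1.5
  big <- pirls_fit(des, p, 1e9, 1e9)
  expect_lt(max(abs(c(big$nu_L, big$nu_R))), 1e-6)
  # independent fixed-effects-only IRLS (no random-effect columns)
  X <- des$X
  mu <- y + mean(y) / 10; eta <- log(mu)
  for (it in 1:200) {
    w <- mu^(2 - p); z <- eta + (y - mu) / mu
    beta <- solve(crossprod(X * sqrt(w)), crossprod(X, w * z))
    eta_new <- drop(X %*% beta)
    if (max(abs(eta_new - eta)) < 1e-10) { eta <- eta_new; break }
    eta <- eta_new; mu <- exp(eta)
  }
  mu <- exp(eta)
  dev_fx <- sum(tweedie_unit_deviance(y, mu, p))
  edf_fx <- ncol(X)
  gcv_fx <- length(y) * dev_fx / (length(y) - edf_fx)^2
  expect_equal(gcv_score(des, p, 1e9, 1e9, fit = big), gcv_fx, tolerance = 1e-4)
})

test_that("GCV smoothing selection shrinks null heterogeneity and frees real effects", {
  # no sender/receiver heterogeneity: selected smoothing at/near the grid top
  b <- matrix(0, 2, 2)
  sim0 <- simulate_ccc(n_units = 150, n_types = 2, beta = b, rho = 0.5,
                       sender_sd = 0, receiver_sd = 0, dmax = 1.6, seed = 71)
  sc0 <- sim0$truth$scores
  des0 <- build_design(sim0$dataset, pairs = sc0[, 1:3], rho = 0.5,
                       partition = sim0$truth$partition, response = sc0$score)
  sel0 <- select_smoothing(des0, 1.5, refine = FALSE)
  # strong sender heterogeneity: lambda_L materially smaller than under null
  sim1 <- simulate_ccc(n_units = 150, n_types = 2, beta = b, rho = 0.5,
                       sender_sd = 1.5, receiver_sd = 0, dmax = 1.6, seed = 71)
  sc1 <- sim1$truth$scores
  des1 <- build_design(sim1$dataset, pairs = sc1[, 1:3], rho = 0.5,
                       partition = sim1$truth$partition, response = sc1$score)
  sel1 <- select_smoothing(des1, 1.5, refine = FALSE)
  expect_gte(sel0$lambda_L, 100)
  expect_lt(sel1$lambda_L, sel0$lambda_L)
  # permutation invariance: reordering rows leaves the selection unchanged
  set.seed(13)
  perm <- sample(nrow(des1$pairs))
  des_p <- des1
  des_p$pairs <- des1$pairs[perm, ]
  des_p$X <- des1$X[perm, , drop = FALSE]
  sel_p <- select_smoothing(des_p, 1.5, refine = FALSE)
  expect_equal(c(sel_p$lambda_L, sel_p$lambda_R),
               c(sel1$lambda_L, sel1$lambda_R))
})

test_that("the power profile recovers the emission power and breaks ties at 1.5", {
  hits <- vapply(1:10, function(r) {
    b <- matrix(0, 3, 3); b[1, 2] <- 1.5
    sim <- simulate_ccc(n_units = 200, beta = b, rho = 0.5, power_p = 1.3,
                        seed = 600 + r)
    sc <- sim$truth$scores
    des <- build_design(sim$dataset, pairs = sc[, 1:3], rho = 0.5,
                        partition = sim$truth$partition, response = sc$score)
    sm <- select_smoothing(des, 1.5)
    estimate_power(des, sm$lambda_L, sm$lambda_R)$p
  }, numeric(1))
  expect_gte(mean(hits %in% c(1.2, 1.3, 1.4)), 0.9)
  # degenerate flat profile returns 1.5, and selection is the argmax
  des <- make_score_design(seed = 46, g = 2, n_units = 50)
  des$pairs$response <- rep(3, nrow(des$pairs))
  pw_flat <- estimate_power(des, 1, 1)
  expect_equal(pw_flat$p, 1.5)
  des2 <- make_score_design(seed = 47, g = 2, n_units = 50)
  pw <- estimate_power(des2, 1, 1)
  ll <- pw$table$loglik
  expect_equal(pw$p, pw$table$p[which.max(ll)])
})

test_that("AIC comparisons are invariant to rescaling distances and decay rates", {
  sim <- simulate_ccc(n_units = 80, n_types = 2,
                      beta = matrix(c(0, 0, 1, 0), 2, 2), rho = 0.5,
                      dmax = 2, seed = 48)
  sc <- sim$truth$scores
  cfg <- ccc_config(refine_smoothing = FALSE,
                    lambda_grid = 10^seq(-2, 2, length.out = 3))
  aic_at <- function(scale) {
    ds <- sim$dataset
    ds$coords <- ds$coords * scale
    pairs <- sc[, 1:3]
    pairs$distance <- pairs$distance * scale
    vapply(c(0.5, 2) / scale, function(rho) {
      des <- build_design(ds, pairs = pairs, rho = rho,
                          partition = grid_partition(ds$coords, 2, 2),
                          response = sc$score)
      fit_tweedie_gam(des, cfg)$aic
    }, numeric(1))
  }
  a1 <- aic_at(1)
  a3 <- aic_at(3)
  expect_equal(a1, a3, tolerance = 1e-6)
})

test_that("tidy and glance expose the fit in broom style", {
  des <- make_score_design(seed = 49, g = 2, n_units = 60, beta12 = 1.2)
  fit <- fit_tweedie_gam(des)
  td <- tidy(fit)
  expect_equal(nrow(td), 5) # intercept + 4 interaction terms
  expect_named(td, c("term", "sender_type", "receiver_type", "estimate",
                     "std.error", "statistic", "p.value"))
  expect_equal(td$term[-1], c("T1->T1", "T1->T2", "T2->T1", "T2->T2"))
  td_sw <- tidy(fit, cov_type = "sandwich")
  expect_false(isTRUE(all.equal(td$std.error, td_sw$std.error)))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(des$pairs))
  expect_true(gl$converged)
})
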