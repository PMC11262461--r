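# Heavy simulation batches shared between acceptance checks. Results are
# cached for the session so several test blocks can reuse one batch.
.run_cache <- new.env(parent = emptyenv())

# 30 replicates of the reference recovery study: N = 300 single-cell units,
# G = 3, planted beta[T1 -> T2] = 1.5, true rho = 0.5 among candidates
# {0, 0.5, 2}; random effects generated at grid or unit level.
recovery_runs <- function(level = c("grid", "unit"), n_reps = 30) {
  level <- match.arg(level)
  key <- paste0("recovery_", level)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  seed_base <- if (level == "grid") 100L else 500L
  rows <- lapply(seq_len(n_reps), function(r) {
    b <- matrix(0, 3, 3); b[1, 2] <- 1.5
    sim <- simulate_ccc(n_units = 300, n_types = 3, beta = b, rho = 0.5,
                        dmax = 1.3, random_effect_level = level,
                        seed = seed_base + r)
    sc <- sim$truth$scores
    sr <- select_rho(sim$dataset, sc$score,
                     sc[, c("sender", "receiver", "distance")],
                     candidates = c(0, 0.5, 2),
                     partition = sim$truth$partition, config = ccc_config())
    td <- tidy(sr$fit)
    row <- td[!is.na(td$sender_type) &
                td$sender_type == "T1" & td$receiver_type == "T2", ]
    tibble::tibble(rep = r, estimate = row$estimate, p_value = row$p.value,
                   rho_selected = sr$rho, converged = sr$fit$converged)
  })
  .run_cache[[key]] <- dplyr::bind_rows(rows)
  .run_cache[[key]]
}

# Null calibration batch: one designated type-pair Wald test per simulated
# dataset so the pooled tests are independent across replicates.
null_runs <- function(n_reps = 220) {
  if (!is.null(.run_cache$null)) return(.run_cache$null)
  p_vals <- vapply(seq_len(n_reps), function(r) {
    sim <- simulate_ccc(n_units = 200, n_types = 3, beta = matrix(0, 3, 3),
                        rho = 0.5, dmax = 1.3, seed = 1000L + r)
    sc <- sim$truth$scores
    des <- build_design(sim$dataset,
                        pairs = sc[, c("sender", "receiver", "distance")],
                        rho = 0.5, partition = sim$truth$partition,
                        response = sc$score)
    fit <- fit_tweedie_gam(des)
    td <- tidy(fit)
    td$p.value[!is.na(td$sender_type) &
                 td$sender_type == "T1" & td$receiver_type == "T2"]
  }, numeric(1))
  .run_cache$null <- p_vals
  p_vals
}
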