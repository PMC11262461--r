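#' Simulate a spatial dataset with planted communication structure
#'
#' Generates a synthetic spatially resolved transcriptomics dataset whose
#' pairwise ligand-receptor communication scores follow the model exactly:
#' for every ordered unit pair (i, j) within `dmax`, the log mean is
#' `beta0 + exp(-rho * D_ij) * sum_{g1,g2} beta[g1,g2] M[i,g1] M[j,g2]
#'  + nuL_i + nuR_j`, and the score is drawn from a Tweedie
#' (compound Poisson-Gamma) distribution with dispersion `phi` and power
#' `power_p`. Random effects are normal, drawn at grid level by default
#' (matching the fitted model) or per unit to stress the grid approximation.
#'
#' Per-unit ligand and receptor gene expression is constructed from the
#' square-root-scaled marginal means of the planted score field with
#' multiplicative Gamma noise, so that `L_i * R_j` reproduces the planted
#' structure in expectation up to the separability approximation; the drawn
#' pairwise scores themselves are returned in the ground truth for tests
#' that need the exact generative response.
#'
#' @param n_units Number of spots/cells.
#' @param n_types Number of cell types G.
#' @param layout `"uniform_square"` (uniform on a `side x side` square) or
#'   `"grid_lattice"` (regular lattice).
#' @param side Side length of the tissue field (coordinate units).
#' @param resolution `"single_cell"` (one-hot composition) or `"spot"`
#'   (Dirichlet proportions).
#' @param composition_concentration Dirichlet concentration for spot mixing.
#' @param beta G x G matrix of planted interaction coefficients
#'   (sender rows, receiver columns); default all zero.
#' @param beta0 Planted intercept (log baseline score).
#' @param rho Planted distance-decay rate.
#' @param power_p,phi Tweedie power and dispersion of the score emission.
#' @param sender_sd,receiver_sd Random-effect standard deviations.
#' @param random_effect_level `"grid"` or `"unit"`.
#' @param dmax Communication radius used to enumerate pairs.
#' @param n_noise_genes Pure-noise genes appended to the expression matrix.
#' @param n_null_pairs Extra null ligand-receptor pairs built from noise
#'   genes (useful for pathway and FDR tests).
#' @param expr_noise_cv Coefficient of variation of the multiplicative noise
#'   on the constructed ligand/receptor expression.
#' @param n_x,n_y Grid dimensions for grid-level random effects (defaults as
#'   in [grid_partition()]).
#' @param seed Integer seed; fully determines the output.
#' @return A list with `dataset` (a [spatial_dataset()]), `lr_db` (an
#'   [lr_database()]), and `truth`: the planted parameters, realized random
#'   effects, the pair table, and the drawn pairwise `scores` tibble
#'   (sender, receiver, distance, mu, score).
#' @export
simulate_ccc <- function(n_units = 300, n_types = 3,
                         layout = c("uniform_square", "grid_lattice"),
                         side = 10,
                         resolution = c("single_cell", "spot"),
                         composition_concentration = 0.8,
                         beta = matrix(0, n_types, n_types), beta0 = 0,
                         rho = 0.5, power_p = 1.5, phi = 0.5,
                         sender_sd = 0.3, receiver_sd = 0.3,
                         random_effect_level = c("grid", "unit"),
                         dmax = 1.3, n_noise_genes = 10, n_null_pairs = 0,
                         expr_noise_cv = 0.3, n_x = NULL, n_y = NULL,
                         seed = 1) {
  layout <- match.arg(layout)
  resolution <- match.arg(resolution)
  random_effect_level <- match.arg(random_effect_level)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == n_types)) abort("`beta` must be G x G.")
  set.seed(seed)

  coords <- switch(layout,
    uniform_square = cbind(x = runif(n_units, 0, side),
                           y = runif(n_units, 0, side)),
    grid_lattice = {
      k <- ceiling(sqrt(n_units))
      g <- expand.grid(x = seq(0, side, length.out = k),
                       y = seq(0, side, length.out = k))
      as.matrix(g[seq_len(n_units), ])
    }
  )

  type_names <- paste0("T", seq_len(n_types))
  if (resolution == "single_cell") {
    labels <- sample(type_names, n_units, replace = TRUE)
    M <- cell_type_matrix(labels)
  } else {
    gdraw <- matrix(rgamma(n_units * n_types,
                           shape = composition_concentration), n_units)
    M <- gdraw / rowSums(gdraw)
    colnames(M) <- type_names
  }

  partition <- grid_partition(coords, n_x, n_y)
  gid <- assign_grid(coords, partition)
  if (random_effect_level == "grid") {
    nuL_lev <- rnorm(partition$ngrid, 0, sender_sd)
    nuR_lev <- rnorm(partition$ngrid, 0, receiver_sd)
    nuL <- nuL_lev[gid]; nuR <- nuR_lev[gid]
  } else {
    nuL_lev <- nuL <- rnorm(n_units, 0, sender_sd)
    nuR_lev <- nuR <- rnorm(n_units, 0, receiver_sd)
  }

  pairs <- build_pair_set(coords, dmax)
  w <- decay_weight(rho, pairs$distance)
  inter <- rowSums((M[pairs$sender, , drop = FALSE] %*% beta) *
                     M[pairs$receiver, , drop = FALSE])
  mu <- exp(beta0 + w * inter + nuL[pairs$sender] + nuR[pairs$receiver])
  score <- sample_tweedie(nrow(pairs), mu, phi, power_p)

  # expression construction: square-root-scaled marginal factors of the
  # planted mean field, times mean-one Gamma noise
  mbar <- mean(mu)
  m_send <- tapply(mu, pairs$sender, mean)
  m_recv <- tapply(mu, pairs$receiver, mean)
  Lmarg <- Rmarg <- rep(sqrt(mbar), n_units)
  Lmarg[as.integer(names(m_send))] <- m_send / sqrt(mbar)
  Rmarg[as.integer(names(m_recv))] <- m_recv / sqrt(mbar)
  shp <- 1 / expr_noise_cv^2
  L_expr <- Lmarg * rgamma(n_units, shape = shp, scale = 1 / shp)
  R_expr <- Rmarg * rgamma(n_units, shape = shp, scale = 1 / shp)

  noise <- matrix(sample_tweedie(n_noise_genes * n_units, mu = 1,
                                 phi = 1, p = 1.5),
                  nrow = n_noise_genes)
  expr <- rbind(matrix(L_expr, 1), matrix(R_expr, 1), noise)
  rownames(expr) <- c("LIG1", "REC1",
                      if (n_noise_genes > 0) paste0("NOISE", seq_len(n_noise_genes)))
  colnames(expr) <- paste0("unit", seq_len(n_units))

  lig <- "LIG1"; rec <- "REC1"; pw <- "SIM"
  if (n_null_pairs > 0) {
    if (2 * n_null_pairs > n_noise_genes) {
      abort("need at least 2 noise genes per null LR pair.")
    }
    lig <- c(lig, paste0("NOISE", seq(1, 2 * n_null_pairs, by = 2)))
    rec <- c(rec, paste0("NOISE", seq(2, 2 * n_null_pairs, by = 2)))
    pw <- c(pw, rep("NULLPW", n_null_pairs))
  }
  db <- lr_database(lig, rec, pw)

  dataset <- spatial_dataset(expr, coords, M, resolution = resolution)
  list(
    dataset = dataset,
    lr_db = db,
    truth = list(
      beta = beta, beta0 = beta0, rho = rho, power_p = power_p, phi = phi,
      sender_sd = sender_sd, receiver_sd = receiver_sd,
      random_effect_level = random_effect_level,
      nu_L_levels = nuL_lev, nu_R_levels = nuR_lev,
      partition = partition, grid_id = gid, type_names = type_names,
      dmax = dmax, seed = seed,
      scores = dplyr::mutate(pairs, mu = mu, score = score)
    )
  )
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' Emits exactly the files the command-line `run` step consumes: a
#' MatrixMarket expression triplet with gene/barcode sidecars, a coordinate
#' CSV, a proportion CSV, the ligand-receptor database CSV, and a
#' ground-truth TSV of the planted coefficients.
#'
#' @param sim Output of [simulate_ccc()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  Matrix::writeMM(Matrix::Matrix(ds$expr, sparse = TRUE),
                  file.path(dir, "expression.mtx"))
  writeLines(ds$gene_ids, file.path(dir, "genes.txt"))
  writeLines(ds$unit_ids, file.path(dir, "barcodes.txt"))
  readr::write_csv(
    tibble::tibble(unit_id = ds$unit_ids, x = ds$coords[, 1], y = ds$coords[, 2]),
    file.path(dir, "coordinates.csv")
  )
  comp <- tibble::as_tibble(ds$composition)
  comp <- dplyr::bind_cols(tibble::tibble(unit_id = ds$unit_ids), comp)
  readr::write_csv(comp, file.path(dir, "proportions.csv"))
  readr::write_csv(
    dplyr::select(sim$lr_db, "ligand", "receptor", "pathway"),
    file.path(dir, "lr_database.csv")
  )
  g <- length(sim$truth$type_names)
  truth <- tibble::tibble(
    sender_type = rep(sim$truth$type_names, each = g),
    receiver_type = rep(sim$truth$type_names, times = g),
    true_beta = as.vector(t(sim$truth$beta)),
    true_beta0 = sim$truth$beta0, true_rho = sim$truth$rho,
    power_p = sim$truth$power_p, phi = sim$truth$phi, seed = sim$truth$seed
  )
  readr::write_tsv(truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
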