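#' Analysis configuration
#'
#' Collects every tunable of the communication inference pipeline in one
#' list, so runs are reproducible from a single object. It can be written
#' to / read from JSON for the command line interface.
#'
#' @param dmax Maximum communication distance (same units as coordinates).
#' @param rho_candidates Candidate distance-decay rates; `NULL` uses the
#'   scale-adaptive default `{0} U {-log(q)/d_med : q in 0.75, 0.5, 0.25,
#'   0.1}` with `d_med` the median pairwise distance within `dmax`.
#' @param n_x,n_y Grid dimensions for the random-effect partition; `NULL`
#'   targets ~25 units per rectangle.
#' @param complex_rule Subunit combination rule for ligand/receptor
#'   complexes: `"min"` or `"geometric_mean"`.
#' @param include_self Include autocrine (distance 0) self pairs?
#' @param p_grid Candidate Tweedie powers for profile selection.
#' @param p_reference Power used during GCV smoothing selection.
#' @param lambda_grid Per-axis GCV grid for the smoothing parameters.
#' @param refine_smoothing Nelder-Mead refinement after the GCV grid?
#' @param bh_scope `"global"` adjusts p-values across the whole emitted
#'   table (all pairs x all type pairs, the default family);
#'   `"within_pair"` adjusts within each ligand-receptor pair.
#' @param cov_type Wald covariance: `"penalized"` (default) or `"sandwich"`.
#' @param threshold Adjusted-p significance threshold used by plots.
#' @param tol,max_iter PIRLS convergence controls.
#' @return A list of class `ccc_config`.
#' @export
ccc_config <- function(dmax = NULL, rho_candidates = NULL,
                       n_x = NULL, n_y = NULL,
                       complex_rule = "min", include_self = TRUE,
                       p_grid = seq(1.1, 1.9, by = 0.1), p_reference = 1.5,
                       lambda_grid = 10^seq(-3, 3, length.out = 7),
                       refine_smoothing = TRUE,
                       bh_scope = c("global", "within_pair"),
                       cov_type = c("penalized", "sandwich"),
                       threshold = 0.1, tol = 1e-8, max_iter = 200) {
  structure(
    list(dmax = dmax, rho_candidates = rho_candidates, n_x = n_x, n_y = n_y,
         complex_rule = complex_rule, include_self = include_self,
         p_grid = p_grid, p_reference = p_reference,
         lambda_grid = lambda_grid, refine_smoothing = refine_smoothing,
         bh_scope = match.arg(bh_scope), cov_type = match.arg(cov_type),
         threshold = threshold, tol = tol, max_iter = max_iter),
    class = "ccc_config"
  )
}

#' Read an analysis configuration from JSON
#'
#' Reads a flat JSON object whose keys are [ccc_config()] arguments (e.g.
#' `{"dmax": 1.3, "rho_candidates": [0, 0.5, 2], "threshold": 0.1}`);
#' unknown keys are rejected. The command line accepts such a file via
#' `--config`, with explicit flags taking precedence.
#'
#' @param path JSON file path.
#' @return A [ccc_config()] list.
#' @export
read_ccc_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("reading JSON configs requires the jsonlite package.")
  }
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(ccc_config)))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(ccc_config, vals)
}

default_rho_candidates <- function(distances) {
  d_med <- median(distances[distances > 0])
  if (!is.finite(d_med) || d_med <= 0) return(0)
  c(0, -log(c(0.75, 0.5, 0.25, 0.1)) / d_med)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed for
#'   non-converged tests and left `NA`).
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- p.adjust(p_values[ok], method = "BH")
  out
}

#' Select the distance-decay rate by AIC
#'
#' For each candidate decay rate, rebuilds the design and runs the full
#' fitting path (GCV smoothing selection, power profile, final fit), then
#' returns the candidate with the smallest AIC (ties go to the smallest
#' rate).
#'
#' @param dataset A [spatial_dataset()].
#' @param response Pairwise response vector aligned with `pairs`.
#' @param pairs Pair table from [build_pair_set()].
#' @param candidates Non-negative candidate decay rates.
#' @param partition A [grid_partition()].
#' @param config A [ccc_config()].
#' @return List with `rho`, the selected `fit`, and the per-candidate
#'   `aic_table` (tibble: rho, aic, converged).
#' @export
select_rho <- function(dataset, response, pairs, candidates, partition,
                       config = ccc_config()) {
  if (length(candidates) < 1 || any(candidates < 0)) {
    abort("need at least one non-negative candidate decay rate.")
  }
  fits <- vector("list", length(candidates))
  aics <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    des <- build_design(dataset, pairs = pairs, rho = candidates[i],
                        partition = partition, response = response)
    fits[[i]] <- tryCatch(fit_tweedie_gam(des, config),
                          error = function(e) NULL)
    if (!is.null(fits[[i]])) aics[i] <- fits[[i]]$aic
  }
  if (all(is.na(aics))) {
    abort("model fitting failed for every candidate decay rate.")
  }
  best <- which(aics <= min(aics, na.rm = TRUE) + 1e-9)
  sel <- best[which.min(candidates[best])] # ties -> smallest rho
  list(rho = candidates[sel], fit = fits[[sel]],
       aic_table = tibble::tibble(
         rho = candidates, aic = aics,
         converged = purrr::map_lgl(fits, ~ !is.null(.x) && .x$converged)
       ))
}

fit_one_response <- function(dataset, response, pairs, partition, config,
                             rho_candidates) {
  sr <- select_rho(dataset, response, pairs, rho_candidates, partition, config)
  fit <- sr$fit
  td <- tidy(fit, cov_type = config$cov_type)
  td <- dplyr::filter(td, .data$term != "(Intercept)")
  dplyr::mutate(td, rho_selected = sr$rho, power_p = fit$power_p,
                aic = fit$aic, converged = fit$converged)
}

finalize_result <- function(rows, config) {
  out <- dplyr::rename(rows, std_error = "std.error", z_value = "statistic",
                       p_value = "p.value")
  if (config$bh_scope == "global") {
    out <- dplyr::mutate(out, p_adjusted = bh_adjust(.data$p_value))
  } else {
    out <- dplyr::mutate(dplyr::group_by(out, .data$ligand, .data$receptor),
                         p_adjusted = bh_adjust(.data$p_value))
    out <- dplyr::ungroup(out)
  }
  out <- dplyr::select(out, "ligand", "receptor", "pathway", "sender_type",
                       "receiver_type", "estimate", "std_error", "z_value",
                       "p_value", "p_adjusted", "rho_selected", "power_p",
                       "aic", "converged")
  class(out) <- c("ccc_result", class(out))
  out
}

#' Infer cell-cell communication for every ligand-receptor pair
#'
#' The core pipeline: for each measurable ligand-receptor pair, compute
#' per-unit ligand/receptor scores, build the pairwise design over all unit
#' pairs within `dmax`, select the distance-decay rate by AIC, fit the
#' penalized Tweedie model, and test each of the G^2 directed cell-type
#' interaction coefficients by a two-sided Wald test. Benjamini-Hochberg
#' adjustment is applied across the whole emitted table by default.
#'
#' @param dataset A [spatial_dataset()].
#' @param lr_db An [lr_database()].
#' @param dmax Maximum communication distance; overrides `config$dmax`.
#' @param config A [ccc_config()].
#' @return A `ccc_result` tibble with one row per (ligand, receptor,
#'   sender type, receiver type): estimate, std_error, z_value, p_value,
#'   p_adjusted, rho_selected, power_p, aic, converged.
#' @export
infer_ccc <- function(dataset, lr_db, dmax = config$dmax,
                      config = ccc_config()) {
  if (is.null(dmax)) abort("`dmax` must be supplied (here or in the config).")
  pairs <- build_pair_set(dataset$coords, dmax,
                          include_self = config$include_self)
  partition <- grid_partition(dataset$coords, config$n_x, config$n_y)
  rho_candidates <- config$rho_candidates %||%
    default_rho_candidates(pairs$distance)

  unmatched <- character(0)
  rows <- purrr::map(seq_len(nrow(lr_db)), function(k) {
    pair <- lr_db[k, ]
    sc <- communication_scores(dataset$expr, pair, dataset$gene_ids,
                               complex_rule = config$complex_rule)
    if (is.null(sc)) {
      unmatched <<- c(unmatched, pair$pair_id)
      return(NULL)
    }
    response <- sc$L[pairs$sender] * sc$R[pairs$receiver]
    if (all(response == 0)) {
      inform(sprintf("pair %s skipped: all pairwise scores are zero.", pair$pair_id))
      return(NULL)
    }
    td <- tryCatch(
      fit_one_response(dataset, response, pairs, partition, config,
                       rho_candidates),
      error = function(e) {
        inform(sprintf("pair %s failed to fit: %s", pair$pair_id,
                       conditionMessage(e)))
        NULL
      }
    )
    if (is.null(td)) return(NULL)
    dplyr::mutate(td, ligand = pair$ligand, receptor = pair$receptor,
                  pathway = pair$pathway, .before = 1)
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0) {
    abort(paste0("no measurable ligand-receptor pair. Unmatched: ",
                 paste(unmatched, collapse = ", ")))
  }
  finalize_result(rows, config)
}

#' Aggregate pairwise communication scores within a pathway
#'
#' Elementwise sum of the per-pair responses of every measurable
#' ligand-receptor pair carrying the given pathway label, on the identical
#' spatial pair set.
#'
#' @inheritParams infer_ccc
#' @param pathway_label Pathway to aggregate.
#' @param pairs Pair table from [build_pair_set()].
#' @return Numeric response vector of length `nrow(pairs)`.
#' @export
aggregate_pathway <- function(dataset, lr_db, pathway_label, pairs,
                              config = ccc_config()) {
  members <- dplyr::filter(lr_db, .data$pathway == pathway_label)
  if (nrow(members) == 0) abort(sprintf("unknown pathway '%s'.", pathway_label))
  total <- numeric(nrow(pairs))
  used <- 0L
  for (k in seq_len(nrow(members))) {
    sc <- communication_scores(dataset$expr, members[k, ], dataset$gene_ids,
                               complex_rule = config$complex_rule)
    if (is.null(sc)) next
    total <- total + sc$L[pairs$sender] * sc$R[pairs$receiver]
    used <- used + 1L
  }
  if (used == 0L) {
    warn(sprintf("pathway '%s' has no measurable ligand-receptor pair; skipped.",
                 pathway_label))
    return(NULL)
  }
  total
}

#' Infer pathway-level cell-cell communication
#'
#' Pools the communication scores of all ligand-receptor pairs in each
#' pathway (`C_ij = sum_k C_ijk`) and fits the pooled response through the
#' same decay-selection and Tweedie-GAM path as a single pseudo-pair.
#' Result rows carry `ligand = receptor = "pathway:<label>"`.
#'
#' @inheritParams infer_ccc
#' @param pathways Pathway labels to analyse; default all in `lr_db`.
#' @return A `ccc_result` tibble, one block of G^2 rows per pathway.
#' @export
infer_ccc_pathway <- function(dataset, lr_db, dmax = config$dmax,
                              pathways = NULL, config = ccc_config()) {
  if (is.null(dmax)) abort("`dmax` must be supplied (here or in the config).")
  pairs <- build_pair_set(dataset$coords, dmax,
                          include_self = config$include_self)
  partition <- grid_partition(dataset$coords, config$n_x, config$n_y)
  rho_candidates <- config$rho_candidates %||%
    default_rho_candidates(pairs$distance)
  pathways <- pathways %||% unique(lr_db$pathway)

  rows <- purrr::map(pathways, function(pw) {
    response <- aggregate_pathway(dataset, lr_db, pw, pairs, config)
    if (is.null(response) || all(response == 0)) return(NULL)
    td <- tryCatch(
      fit_one_response(dataset, response, pairs, partition, config,
                       rho_candidates),
      error = function(e) {
        inform(sprintf("pathway %s failed to fit: %s", pw, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(td)) return(NULL)
    dplyr::mutate(td, ligand = paste0("pathway:", pw),
                  receptor = paste0("pathway:", pw), pathway = pw, .before = 1)
  })
  rows <- dplyr::bind_rows(rows)
  if (nrow(rows) == 0) abort("no pathway could be analysed.")
  finalize_result(rows, config)
}
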