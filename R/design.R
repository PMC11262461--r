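#' Ligand and receptor scores per unit
#'
#' Combines the expression of the genes making up a ligand (or receptor)
#' complex into one non-negative score per spot/cell. Single-subunit entries
#' return their expression unchanged; multi-subunit complexes are combined by
#' the elementwise minimum over subunits (conservative: a complex is only as
#' available as its scarcest subunit) or by the geometric mean.
#'
#' @param expr Numeric matrix, genes x units, non-negative normalized
#'   expression with rownames.
#' @param gene_ids Character vector of gene symbols (defaults to
#'   `rownames(expr)`).
#' @param pair One row of an LR database as returned by [read_lr_database()],
#'   or a list with elements `ligand_genes` and `receptor_genes`.
#' @param complex_rule `"min"` (default) or `"geometric_mean"`.
#' @return A list with numeric vectors `L` and `R` of length `ncol(expr)`,
#'   or `NULL` (with a warning) when neither side has any measured gene.
#' @export
communication_scores <- function(expr, pair, gene_ids = rownames(expr),
                                 complex_rule = c("min", "geometric_mean")) {
  complex_rule <- match.arg(complex_rule)
  lig <- intersect(pair$ligand_genes[[1]], gene_ids)
  rec <- intersect(pair$receptor_genes[[1]], gene_ids)
  if (length(lig) == 0 || length(rec) == 0) {
    warn(sprintf("pair %s not measurable: no %s gene found in expression matrix",
                 pair$pair_id %||% "<unnamed>",
                 if (length(lig) == 0) "ligand" else "receptor"))
    return(NULL)
  }
  combine <- function(genes) {
    sub <- expr[match(genes, gene_ids), , drop = FALSE]
    if (length(genes) == 1L) return(as.numeric(sub))
    switch(complex_rule,
      min = apply(sub, 2, min),
      geometric_mean = exp(colMeans(log(sub + 1e-300))) *
        (apply(sub, 2, min) > 0) # zero subunit => zero complex
    )
  }
  list(L = combine(lig), R = combine(rec))
}

#' Enumerate spatial pairs within a communication radius
#'
#' All ordered (sender, receiver) pairs of units whose Euclidean distance is
#' at most `dmax` (boundary inclusive). Self pairs (distance 0, autocrine
#' signaling) are included by default. Candidate pairs are pre-filtered with a
#' spatial bin grid of cell width `dmax` so cost is near-linear in the number
#' of returned pairs.
#'
#' @param coords Numeric matrix or data frame, units x 2 (x, y).
#' @param dmax Positive communication radius, same length unit as `coords`.
#' @param include_self Keep (i, i) pairs? Default `TRUE`.
#' @return Tibble with integer columns `sender`, `receiver` and numeric
#'   `distance`, ordered by (sender, receiver).
#' @export
build_pair_set <- function(coords, dmax, include_self = TRUE) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  if (!is.numeric(dmax) || length(dmax) != 1L || dmax <= 0) {
    abort("`dmax` must be a single positive number.")
  }
  if (anyNA(coords)) abort("`coords` must not contain missing values.")
  n <- nrow(coords)
  bx <- pmin(floor((coords[, 1] - min(coords[, 1])) / dmax), 1e9)
  by <- pmin(floor((coords[, 2] - min(coords[, 2])) / dmax), 1e9)
  key <- bx * (max(by) + 2) + by
  cells <- split(seq_len(n), key)
  cell_xy <- do.call(rbind, lapply(cells, function(ix) c(bx[ix[1]], by[ix[1]])))
  keys <- as.numeric(names(cells))

  senders <- integer(0); receivers <- integer(0)
  for (ci in seq_along(cells)) {
    # neighbours: all cells within one bin step in each axis
    nb <- which(abs(cell_xy[, 1] - cell_xy[ci, 1]) <= 1 &
                  abs(cell_xy[, 2] - cell_xy[ci, 2]) <= 1)
    i_idx <- cells[[ci]]
    j_idx <- unlist(cells[nb], use.names = FALSE)
    senders <- c(senders, rep(i_idx, each = length(j_idx)))
    receivers <- c(receivers, rep(j_idx, times = length(i_idx)))
  }
  dx <- coords[senders, 1] - coords[receivers, 1]
  dy <- coords[senders, 2] - coords[receivers, 2]
  d <- sqrt(dx * dx + dy * dy)
  keep <- d <= dmax & (include_self | senders != receivers)
  out <- tibble::tibble(sender = senders[keep], receiver = receivers[keep],
                        distance = d[keep])
  out <- dplyr::arrange(out, .data$sender, .data$receiver)
  if (nrow(out) == 0) {
    abort("`dmax` too small: no unit pair lies within the communication radius.")
  }
  out
}

#' Exponential distance-decay weights
#'
#' `exp(-rho * distance)`: 1 at distance zero, strictly decreasing for
#' `rho > 0`, identically 1 when `rho = 0`.
#'
#' @param rho Non-negative decay rate (inverse distance units).
#' @param distance Non-negative distances.
#' @return Numeric vector of weights in (0, 1].
#' @export
decay_weight <- function(rho, distance) {
  if (rho < 0) abort("`rho` must be non-negative.")
  if (any(distance < 0)) abort("distances must be non-negative.")
  exp(-rho * distance)
}

#' Rectangular grid partition of a tissue field
#'
#' Equal-width partition of the coordinate bounding box into `n_x` x `n_y`
#' rectangles, used to bucket sender/receiver random effects so their level
#' count is `2 * Ngrid` instead of `2 * N`. The default targets roughly 25
#' units per rectangle.
#'
#' @param coords Units x 2 coordinate matrix.
#' @param n_x,n_y Number of bins along x and y; defaults to
#'   `max(2, round(sqrt(N / 25)))` each.
#' @return An object of class `grid_partition` with fields `n_x`, `n_y`,
#'   `ngrid` and the bounding box.
#' @export
grid_partition <- function(coords, n_x = NULL, n_y = NULL) {
  coords <- as.matrix(coords)
  default_bins <- max(2L, as.integer(round(sqrt(nrow(coords) / 25))))
  n_x <- as.integer(n_x %||% default_bins)
  n_y <- as.integer(n_y %||% default_bins)
  if (n_x < 1L || n_y < 1L) abort("grid dimensions must be positive integers.")
  xr <- range(coords[, 1]); yr <- range(coords[, 2])
  if (xr[1] == xr[2] && n_x > 1L) {
    warn("all x coordinates equal; collapsing x axis to one bin")
    n_x <- 1L
  }
  if (yr[1] == yr[2] && n_y > 1L) {
    warn("all y coordinates equal; collapsing y axis to one bin")
    n_y <- 1L
  }
  structure(
    list(n_x = n_x, n_y = n_y, ngrid = n_x * n_y,
         xmin = xr[1], xmax = xr[2], ymin = yr[1], ymax = yr[2]),
    class = "grid_partition"
  )
}

#' Assign units to grid rectangles
#'
#' Equal-width binning of x and y; rectangle id is
#' `(row - 1) * n_x + col`, ids in `1..Ngrid`. Points on the maximal edge of
#' an axis fall in the last bin.
#'
#' @param coords Units x 2 coordinate matrix.
#' @param partition A [grid_partition()].
#' @return Integer vector of grid ids, one per unit.
#' @export
assign_grid <- function(coords, partition) {
  coords <- as.matrix(coords)
  bin <- function(v, lo, hi, k) {
    if (k == 1L || hi == lo) return(rep(1L, length(v)))
    b <- floor((v - lo) / (hi - lo) * k) + 1L
    pmin(pmax(as.integer(b), 1L), k)
  }
  col <- bin(coords[, 1], partition$xmin, partition$xmax, partition$n_x)
  row <- bin(coords[, 2], partition$ymin, partition$ymax, partition$n_y)
  (row - 1L) * partition$n_x + col
}

interaction_col_names <- function(type_names) {
  g <- length(type_names)
  paste0(rep(type_names, each = g), "->", rep(type_names, times = g))
}

#' Build the pairwise regression design for one ligand-receptor pair
#'
#' Assembles the dataset on which one communication model is fitted: for
#' every (sender i, receiver j) pair within `dmax`, the response
#' `C_ij = L_i * R_j`, the distance, the decayed cell-type interaction
#' covariates `exp(-rho * D_ij) * M[i, g1] * M[j, g2]`, and the sender and
#' receiver grid random-effect indices. Column order is intercept first,
#' then (g1, g2) sender-major, so the coefficient for (g1 -> g2) is distinct
#' from (g2 -> g1).
#'
#' @param dataset A [spatial_dataset()].
#' @param L,R Per-unit ligand and receptor scores (from
#'   [communication_scores()]), or `NULL` when `response` is supplied.
#' @param pairs Pair table from [build_pair_set()].
#' @param rho Non-negative distance-decay rate.
#' @param partition A [grid_partition()]; default computed from the
#'   coordinates.
#' @param response Optional explicit response vector (length `nrow(pairs)`),
#'   overriding `L[sender] * R[receiver]` — used for pathway-aggregated scores
#'   and simulated scores.
#' @return An object of class `pair_design`: list with `pairs` (tibble with
#'   sender, receiver, distance, response, sender_grid, receiver_grid), the
#'   model matrix `X` (P x (1 + G^2)), `rho`, `dmax`, `ngrid`, `type_names`.
#' @export
build_design <- function(dataset, L = NULL, R = NULL, pairs, rho,
                         partition = NULL, response = NULL) {
  if (rho < 0) abort("`rho` must be non-negative.")
  partition <- partition %||% grid_partition(dataset$coords)
  M <- dataset$composition
  g <- ncol(M)
  s <- pairs$sender; r <- pairs$receiver
  if (is.null(response)) {
    if (is.null(L) || is.null(R)) abort("supply either `L` and `R`, or `response`.")
    response <- L[s] * R[r]
  }
  if (all(response == 0)) {
    abort("no signal for this pair: all pairwise communication scores are zero.")
  }
  w <- decay_weight(rho, pairs$distance)
  # X[, 1 + (g1-1)*G + g2] = w * M[s, g1] * M[r, g2]  (sender-major)
  X <- matrix(0, nrow = nrow(pairs), ncol = 1L + g * g)
  X[, 1] <- 1
  Ms <- M[s, , drop = FALSE]; Mr <- M[r, , drop = FALSE]
  for (g1 in seq_len(g)) {
    block <- (Ms[, g1] * w) * Mr
    X[, 1L + (g1 - 1L) * g + seq_len(g)] <- block
  }
  colnames(X) <- c("(Intercept)", interaction_col_names(dataset$type_names))
  gid <- assign_grid(dataset$coords, partition)
  structure(
    list(
      pairs = dplyr::mutate(pairs, response = response,
                            sender_grid = gid[s], receiver_grid = gid[r]),
      X = X, rho = rho, dmax = max(pairs$distance), ngrid = partition$ngrid,
      partition = partition, type_names = dataset$type_names
    ),
    class = "pair_design"
  )
}

#' @export
print.pair_design <- function(x, ...) {
  cat(sprintf(
    "<pair_design> %d pairs, %d cell types (%d interaction terms), rho = %g, Ngrid = %d\n",
    nrow(x$pairs), length(x$type_names), ncol(x$X) - 1L, x$rho, x$ngrid
  ))
  invisible(x)
}
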