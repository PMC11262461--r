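#' Assemble and validate a spatial dataset
#'
#' Bundles the four inputs of a communication analysis — normalized
#' expression, coordinates, and per-unit cell-type composition — into one
#' validated object. For single-cell resolution data the composition matrix
#' must be one-hot (build it with [cell_type_matrix()]); for spot-based data
#' it holds deconvolved proportions whose rows sum to 1.
#'
#' @param expr Genes x units numeric matrix, non-negative, with rownames
#'   (gene symbols) and colnames (unit barcodes).
#' @param coords Units x 2 numeric matrix of x/y positions.
#' @param composition Units x G matrix of cell-type proportions in `[0, 1]`,
#'   rows summing to 1, with type names as colnames.
#' @param resolution `"single_cell"` or `"spot"`.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(expr, coords, composition,
                            resolution = c("single_cell", "spot")) {
  resolution <- match.arg(resolution)
  expr <- as.matrix(expr)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  composition <- as.matrix(composition)
  n <- ncol(expr)
  if (nrow(coords) != n || nrow(composition) != n) {
    abort(sprintf(
      "dimension mismatch: expr has %d units but coords has %d rows and composition %d rows.",
      n, nrow(coords), nrow(composition)
    ))
  }
  if (anyNA(coords)) abort("coordinates must not contain missing values.")
  if (any(expr < 0)) abort("expression matrix must be non-negative.")
  rs <- rowSums(composition)
  if (any(abs(rs - 1) > 1e-6)) {
    abort(sprintf("composition rows must sum to 1 (first offender: row %d, sum %.8f).",
                  which(abs(rs - 1) > 1e-6)[1], rs[which(abs(rs - 1) > 1e-6)[1]]))
  }
  if (any(composition < 0) || any(composition > 1)) {
    abort("composition entries must lie in [0, 1].")
  }
  if (resolution == "single_cell" &&
      !all(composition %in% c(0, 1))) {
    abort("single-cell resolution requires a one-hot composition matrix; see cell_type_matrix().")
  }
  if (is.null(colnames(composition))) {
    colnames(composition) <- paste0("type", seq_len(ncol(composition)))
  }
  structure(
    list(expr = expr,
         gene_ids = rownames(expr) %||% paste0("gene", seq_len(nrow(expr))),
         unit_ids = colnames(expr) %||% paste0("unit", seq_len(n)),
         coords = coords, composition = composition,
         type_names = colnames(composition), resolution = resolution),
    class = "spatial_dataset"
  )
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d genes x %d units (%s resolution), %d cell types\n",
              nrow(x$expr), ncol(x$expr), x$resolution, length(x$type_names)))
  invisible(x)
}

#' Read a normalized expression matrix
#'
#' Reads genes x units expression from either a dense CSV/TSV (first column =
#' gene symbol, remaining columns = units) or a MatrixMarket sparse triplet
#' file with plain-text gene and barcode sidecar lists (one id per line).
#' Duplicate gene symbols are collapsed by summation with a warning.
#'
#' @param path File path (`.csv`/`.tsv` or `.mtx`).
#' @param format `"csv"` or `"mtx"`; guessed from the extension by default.
#' @param genes_path,barcodes_path Sidecar paths for the MTX variant;
#'   default `<dir>/genes.txt` and `<dir>/barcodes.txt`.
#' @return Dense numeric matrix with gene rownames and unit colnames.
#' @export
read_expression <- function(path, format = NULL,
                            genes_path = NULL, barcodes_path = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  format <- format %||% if (grepl("\\.mtx$", path)) "mtx" else "csv"
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    genes_path <- genes_path %||% file.path(dirname(path), "genes.txt")
    barcodes_path <- barcodes_path %||% file.path(dirname(path), "barcodes.txt")
    genes <- readLines(genes_path)
    barcodes <- readLines(barcodes_path)
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
      abort(sprintf(
        "MTX dimensions (%d x %d) do not match sidecars (%d genes, %d barcodes).",
        nrow(m), ncol(m), length(genes), length(barcodes)
      ))
    }
    mat <- as.matrix(m)
    dimnames(mat) <- list(genes, barcodes)
  } else {
    df <- readr::read_delim(path, delim = if (grepl("\\.tsv$", path)) "\t" else ",",
                            show_col_types = FALSE, progress = FALSE)
    genes <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- genes
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf("negative expression at gene '%s', unit '%s'.",
                  rownames(mat)[neg[1, 1]] %||% neg[1, 1],
                  colnames(mat)[neg[1, 2]] %||% neg[1, 2]))
  }
  if (anyDuplicated(rownames(mat))) {
    warn("duplicate gene symbols collapsed by summation.")
    mat <- rowsum(mat, group = rownames(mat), reorder = FALSE)
  }
  mat
}

#' Read unit coordinates
#'
#' CSV/TSV with header columns `unit_id`, `x`, `y`.
#'
#' @param path File path.
#' @return Units x 2 matrix with unit ids as rownames.
#' @export
read_coordinates <- function(path) {
  df <- readr::read_delim(path, delim = if (grepl("\\.tsv$", path)) "\t" else ",",
                          show_col_types = FALSE, progress = FALSE)
  need <- c("unit_id", "x", "y")
  if (!all(need %in% names(df))) {
    abort(sprintf("coordinate file must have columns %s.", paste(need, collapse = ", ")))
  }
  m <- as.matrix(df[, c("x", "y")])
  rownames(m) <- as.character(df$unit_id)
  if (anyNA(m)) abort("coordinates contain missing values.")
  m
}

#' Read a cell-type proportion matrix
#'
#' CSV/TSV with header: `unit_id` plus one column per cell type; rows must
#' sum to 1 within 1e-6.
#'
#' @param path File path.
#' @return Units x G matrix with unit rownames and type colnames.
#' @export
read_composition <- function(path) {
  df <- readr::read_delim(path, delim = if (grepl("\\.tsv$", path)) "\t" else ",",
                          show_col_types = FALSE, progress = FALSE)
  if (!"unit_id" %in% names(df)) abort("proportion file must have a unit_id column.")
  m <- as.matrix(df[, setdiff(names(df), "unit_id"), drop = FALSE])
  rownames(m) <- as.character(df$unit_id)
  m
}

#' Read a ligand-receptor database
#'
#' CSV with columns `ligand`, `receptor` and optionally `pathway`.
#' Multi-subunit complexes are encoded as subunits joined by `complex_sep`
#' (CellChatDB-style `"_"` by default), e.g. `Itga6_Itgb1`. Rows with an
#' empty ligand or receptor are dropped with a warning; empty pathway labels
#' become `"unassigned"`.
#'
#' @param path CSV file path.
#' @param complex_sep Separator splitting complex subunits.
#' @return A tibble of class `lr_database` with list-columns `ligand_genes`
#'   and `receptor_genes` plus `ligand`, `receptor`, `pathway`, `pair_id`.
#' @export
read_lr_database <- function(path, complex_sep = "_") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df))) {
    abort("LR database must have `ligand` and `receptor` columns.")
  }
  if (!"pathway" %in% names(df)) df$pathway <- NA_character_
  lr_database(df$ligand, df$receptor, df$pathway, complex_sep = complex_sep)
}

#' Construct a ligand-receptor database from vectors
#'
#' @param ligand,receptor Character vectors of (possibly complex) gene
#'   symbols; subunits joined by `complex_sep`.
#' @param pathway Optional character vector of pathway labels.
#' @param complex_sep Separator splitting complex subunits.
#' @return A tibble of class `lr_database`.
#' @export
lr_database <- function(ligand, receptor, pathway = NULL, complex_sep = "_") {
  pathway <- pathway %||% rep(NA_character_, length(ligand))
  pathway <- dplyr::if_else(is.na(pathway) | pathway == "", "unassigned", pathway)
  keep <- !is.na(ligand) & ligand != "" & !is.na(receptor) & receptor != ""
  if (any(!keep)) {
    warn(sprintf("dropping %d row(s) with empty ligand or receptor.", sum(!keep)))
  }
  out <- tibble::tibble(
    ligand = ligand[keep], receptor = receptor[keep], pathway = pathway[keep],
    ligand_genes = strsplit(ligand[keep], complex_sep, fixed = TRUE),
    receptor_genes = strsplit(receptor[keep], complex_sep, fixed = TRUE),
    pair_id = paste0(ligand[keep], "->", receptor[keep])
  )
  if (anyDuplicated(out$pair_id)) {
    abort(sprintf("duplicate pair_id in LR database: %s",
                  out$pair_id[duplicated(out$pair_id)][1]))
  }
  class(out) <- c("lr_database", class(out))
  out
}

#' One-hot cell-type indicator matrix from labels
#'
#' Transforms per-cell type labels into the N x G indicator matrix used as
#' the composition of single-cell resolution data. Columns are the sorted
#' unique labels; each row sums to exactly 1.
#'
#' @param labels Character vector of cell-type labels, no missing values.
#' @return N x G numeric 0/1 matrix with type names as colnames.
#' @export
#' @examples
#' cell_type_matrix(c("A", "A", "B"))
cell_type_matrix <- function(labels) {
  if (length(labels) < 1L) abort("need at least one label.")
  if (anyNA(labels) || any(labels == "")) {
    abort(sprintf("missing cell-type label at index %d.",
                  which(is.na(labels) | labels == "")[1]))
  }
  labels <- as.character(labels)
  types <- sort(unique(labels))
  m <- matrix(0, nrow = length(labels), ncol = length(types),
              dimnames = list(NULL, types))
  m[cbind(seq_along(labels), match(labels, types))] <- 1
  m
}

#' Quality-control filter for expression matrices
#'
#' Two-pass filter: first keep cells (units) with at least
#' `min_genes_per_cell` expressed genes, then keep genes expressed in at
#' least a fraction `min_frac_cells_per_gene` of the surviving cells.
#' "Expressed" means a strictly positive entry. Defaults match retaining
#' cells with >= 100 expressed genes and genes expressed in >= 2.5% of cells.
#'
#' @param expr Genes x cells matrix.
#' @param min_genes_per_cell Minimum expressed-gene count per cell.
#' @param min_frac_cells_per_gene Minimum fraction of (surviving) cells in
#'   which a gene must be expressed.
#' @return List with the filtered matrix `expr` and integer index vectors
#'   `kept_genes`, `kept_cells` into the input.
#' @export
qc_filter <- function(expr, min_genes_per_cell = 100,
                      min_frac_cells_per_gene = 0.025) {
  if (min_genes_per_cell < 0 || min_frac_cells_per_gene < 0) {
    abort("filter thresholds must be non-negative.")
  }
  pos <- expr > 0
  kept_cells <- which(colSums(pos) >= min_genes_per_cell)
  if (length(kept_cells) == 0) {
    abort(sprintf("no cell has >= %d expressed genes (max observed: %d).",
                  min_genes_per_cell, max(colSums(pos))))
  }
  frac <- rowSums(pos[, kept_cells, drop = FALSE]) / length(kept_cells)
  kept_genes <- which(frac >= min_frac_cells_per_gene)
  if (length(kept_genes) == 0) {
    abort("no gene passes the expression-fraction filter.")
  }
  list(expr = expr[kept_genes, kept_cells, drop = FALSE],
       kept_genes = kept_genes, kept_cells = kept_cells)
}

#' Library-size normalization helper
#'
#' Optional convenience: scales each unit to the median library size and
#' applies `log1p`. Upstream pipelines that already provide normalized
#' expression should skip this.
#'
#' @param counts Genes x units non-negative matrix of counts.
#' @return Matrix of the same shape.
#' @export
normalize_log1p <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) abort("unit with zero total counts; filter first.")
  log1p(sweep(counts, 2, median(lib) / lib, `*`))
}

results_columns <- c("ligand", "receptor", "pathway", "sender_type",
                     "receiver_type", "estimate", "std_error", "p_value",
                     "p_adjusted", "rho_selected", "converged")

#' Write a communication result table to TSV
#'
#' Writes the columns ligand, receptor, pathway, sender_type, receiver_type,
#' estimate, std_error, p_value, p_adjusted, rho_selected, converged; missing
#' estimates (non-converged fits) are written as literal `NA`. Values
#' round-trip through [read_ccc_results()] to full double precision.
#'
#' @param result A `ccc_result` tibble from [infer_ccc()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ccc_results <- function(result, path) {
  if (nrow(result) == 0) abort("result table is empty.")
  out <- dplyr::select(result, dplyr::all_of(results_columns))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a communication result table written by [write_ccc_results()]
#'
#' @param path TSV path.
#' @return Tibble with the standard result columns.
#' @export
read_ccc_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    ligand = "c", receptor = "c", pathway = "c",
                    sender_type = "c", receiver_type = "c",
                    estimate = "d", std_error = "d", p_value = "d",
                    p_adjusted = "d", rho_selected = "d", converged = "l"
                  ))
}
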