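#' Construct a validated cell-level experiment
#'
#' Wraps a genes x cells count matrix plus per-cell pseudotime and
#' branching-path labels into a [SingleCellExperiment::SingleCellExperiment]
#' with colData columns `pseudotime` and `path`. This is the input container
#' for the binning and modelling steps; pseudotime and path labels are
#' expected to come from an upstream trajectory-inference tool.
#'
#' @param counts genes x cells matrix of non-negative integer counts (dense
#'   or sparse; stored as a sparse `dgCMatrix`).
#' @param pseudotime numeric vector, one finite non-negative value per cell.
#' @param path character/factor vector, one branching-path label per cell.
#' @param gene_ids,cell_ids optional unique identifiers; default to the
#'   dimnames of `counts`, or `gene1..`/`cell1..` when absent.
#' @return A `SingleCellExperiment` with a `counts` assay and colData
#'   columns `pseudotime` and `path`.
#' @export
cell_experiment <- function(counts, pseudotime, path,
                            gene_ids = NULL, cell_ids = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "dMatrix")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(counts)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(counts)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  ce <- SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(pseudotime = as.numeric(pseudotime),
                        path = as.character(path),
                        row.names = cell_ids)
  )
  validate_cell_experiment(ce)
  ce
}

#' Validate a cell-level experiment
#'
#' Checks the container invariants: matching dimensions, unique identifiers,
#' non-negative integer counts, finite non-negative pseudotime and exactly
#' one path label per cell.
#'
#' @param ce a `SingleCellExperiment` as built by [cell_experiment()].
#' @param require_paths minimum number of distinct paths (1 for single-path
#'   analyses, 2 for branch comparisons).
#' @return `ce`, invisibly, or an error.
#' @export
validate_cell_experiment <- function(ce, require_paths = 1) {
  stopifnot(is(ce, "SingleCellExperiment"))
  if (!"counts" %in% assayNames(ce))
    stop("experiment must carry a 'counts' assay")
  cd <- colData(ce)
  for (col in c("pseudotime", "path"))
    if (!col %in% colnames(cd))
      stop("colData is missing required column '", col, "'")
  m <- assay(ce, "counts")
  if (nrow(m) != length(rownames(ce)) || ncol(m) != nrow(cd))
    stop("count matrix dimensions do not match identifier lists")
  if (anyDuplicated(rownames(ce)))
    stop("duplicated gene identifiers are not allowed")
  if (anyDuplicated(colnames(ce)))
    stop("duplicated cell identifiers are not allowed")
  x <- if (is(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && (any(!is.finite(x)) || any(x < 0)))
    stop("counts must be finite and >= 0")
  if (length(x) && any(abs(x - round(x)) > 1e-8))
    stop("counts must be integers")
  pt <- cd$pseudotime
  if (any(!is.finite(pt)) || any(pt < 0))
    stop("every cell needs a finite, non-negative pseudotime")
  if (any(is.na(cd$path) | cd$path == ""))
    stop("every cell needs a path label")
  if (length(unique(cd$path)) < require_paths)
    stop("at least ", require_paths, " distinct paths are required")
  invisible(ce)
}

#' Load counts and cell metadata from disk
#'
#' Reads a MatrixMarket `.mtx` file (with sidecar gene/barcode text files in
#' the 10x directory layout) or a dense delimited table, joins it with a
#' cell metadata table, and returns a validated experiment. Cells with
#' missing pseudotime or path are rejected (with a message reporting how
#' many); gene and cell order is never changed relative to the source.
#'
#' @param matrix_source path to an `.mtx` file or a delimited genes x cells
#'   table with gene ids in the first column and cell ids as header.
#' @param cell_metadata_source path to a delimited per-cell table.
#' @param pseudotime_column,path_column column names in the metadata table.
#' @param genes_source,cells_source sidecar id files for MTX input; default
#'   to `features.tsv`/`genes.tsv` and `barcodes.tsv` next to the matrix.
#' @param transpose set `TRUE` for cells x genes matrices (10x-style MTX is
#'   genes x cells already).
#' @param sep metadata field separator (default tab; `","` for CSV).
#' @return A validated `SingleCellExperiment`.
#' @export
load_cell_experiment <- function(matrix_source, cell_metadata_source,
                                 pseudotime_column = "pseudotime",
                                 path_column = "path",
                                 genes_source = NULL, cells_source = NULL,
                                 transpose = FALSE, sep = "\t") {
  if (!file.exists(matrix_source))
    stop("matrix source not found: ", matrix_source)
  if (grepl("\\.mtx$", matrix_source, ignore.case = TRUE)) {
    m <- as(readMM(matrix_source), "CsparseMatrix")
    dir <- dirname(matrix_source)
    if (is.null(genes_source)) {
      for (cand in c("features.tsv", "genes.tsv")) {
        p <- file.path(dir, cand)
        if (file.exists(p)) { genes_source <- p; break }
      }
    }
    if (is.null(cells_source)) {
      p <- file.path(dir, "barcodes.tsv")
      if (file.exists(p)) cells_source <- p
    }
    if (transpose) m <- Matrix::t(m)
    gene_ids <- if (!is.null(genes_source))
      data.table::fread(genes_source, header = FALSE)[[1]] else NULL
    cell_ids <- if (!is.null(cells_source))
      data.table::fread(cells_source, header = FALSE)[[1]] else NULL
  } else {
    dt <- data.table::fread(matrix_source, sep = sep, header = TRUE)
    gene_ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    cell_ids <- colnames(m)
    if (transpose) { m <- t(m); tmp <- gene_ids; gene_ids <- cell_ids; cell_ids <- tmp }
    m <- as(m, "CsparseMatrix")
  }
  meta <- as.data.frame(data.table::fread(cell_metadata_source, sep = sep,
                                          header = TRUE))
  for (col in c(pseudotime_column, path_column))
    if (!col %in% colnames(meta))
      stop("cell metadata lacks column '", col, "'")
  if (nrow(meta) != ncol(m))
    stop("metadata rows (", nrow(meta), ") do not match matrix cells (",
         ncol(m), ")")
  if (is.null(cell_ids)) {
    cell_ids <- if ("cell_id" %in% colnames(meta)) as.character(meta$cell_id)
                else paste0("cell", seq_len(ncol(m)))
  }
  pt <- suppressWarnings(as.numeric(meta[[pseudotime_column]]))
  pa <- as.character(meta[[path_column]])
  keep <- is.finite(pt) & !is.na(pa) & pa != ""
  if (any(!keep))
    message("rejected ", sum(!keep), " cell(s) with missing pseudotime/path")
  cell_experiment(m[, keep, drop = FALSE], pt[keep], pa[keep],
                  gene_ids = gene_ids, cell_ids = cell_ids[keep])
}

# canonical column order of a result table on disk
.result_columns <- c("gene", "p_value", "adjusted_p", "screened", "theta",
                     "selected_terms", "term_pvalues", "coefficients",
                     "r_squared", "converged", "classification")

#' Write a per-gene result table to a tab-delimited file
#'
#' Columns are emitted in a fixed, documented order so that identical runs
#' produce byte-identical files. [read_results()] reproduces the table
#' exactly for non-float columns and to better than 1e-12 for floats.
#'
#' @param table a result table from [t_fit()] / [run_trajectory_de()].
#' @param dest output file path.
#' @export
write_results <- function(table, dest) {
  if (dir.exists(dest)) stop("destination is a directory: ", dest)
  stopifnot(is.data.frame(table))
  cols <- intersect(.result_columns, colnames(table))
  cols <- c(cols, setdiff(colnames(table), cols))
  data.table::fwrite(as.data.frame(table)[, cols, drop = FALSE], dest,
                     sep = "\t", quote = FALSE, na = "NA")
  invisible(dest)
}

#' Read a result table written by [write_results()]
#' @param src path to the tab-delimited file.
#' @return a data.frame, one row per gene.
#' @export
read_results <- function(src) {
  dt <- data.table::fread(src, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = intersect(
                            c("gene", "selected_terms", "term_pvalues",
                              "coefficients", "classification"),
                            names(data.table::fread(src, nrows = 0)))))
  as.data.frame(dt)
}
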