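#' Construct a cells-by-genes count matrix
#'
#' Container for raw scRNA-seq counts.  Rows are cells, columns are genes,
#' entries are non-negative integers (UMI or read counts).  Library sizes
#' (per-cell row sums) are computed and stored on construction.
#'
#' @param counts numeric matrix of non-negative integers, cells in rows.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   existing rownames or `cell1..cellC`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   existing colnames or `gene1..geneG`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix with dimnames), `cell_ids`, `gene_ids` and
#'   `library_sizes`.
#' @examples
#' m <- count_matrix(matrix(rpois(20, 3), 4, 5))
#' m$library_sizes
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is_count_vector(as.vector(counts))) {
    bad <- which(!(is.finite(counts) & counts >= 0 & counts == floor(counts)),
                 arr.ind = TRUE)
    stop(sprintf(
      "counts must be non-negative integers; first offending entry at cell %s, gene %s (value %s)",
      bad[1, 1], bad[1, 2], counts[bad[1, 1], bad[1, 2]]))
  }
  storage.mode(counts) <- "double"  # keeps lgamma() fast, values stay integral
  cell_ids <- cell_ids %||% rownames(counts) %||% paste0("cell", seq_len(nrow(counts)))
  gene_ids <- gene_ids %||% colnames(counts) %||% paste0("gene", seq_len(ncol(counts)))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length(cell_ids) != nrow(counts)) stop("cell_ids length does not match rows")
  if (length(gene_ids) != ncol(counts)) stop("gene_ids length does not match columns")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts,
                 cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids),
                 library_sizes = rowSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes\n", nrow(x$counts), ncol(x$counts)))
  cat(sprintf("library sizes: median %.0f, range [%.0f, %.0f]\n",
              stats::median(x$library_sizes), min(x$library_sizes), max(x$library_sizes)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# coerce a plain matrix transparently where a count_matrix is expected
as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) x else count_matrix(x)
}

#' Per-cell library-size scalers
#'
#' Computes the cell-level scaler \eqn{s_c = \mathrm{library\ size}_c /
#' \mathrm{target}}, the same normalization used by common scRNA-seq
#' pipelines (library size normalized to 10,000 by default).  The scaler
#' multiplies the Poisson intensity of every negative binomial component for
#' that cell.
#'
#' @param counts a `count_matrix` (or coercible matrix).
#' @param target_size positive scalar; library size that maps to \eqn{s = 1}.
#' @return numeric vector of positive scalers, one per cell.
#' @export
compute_cell_scalers <- function(counts, target_size = 1e4) {
  counts <- as_count_matrix(counts)
  ls <- counts$library_sizes
  if (any(ls == 0)) {
    stop(sprintf("cell '%s' has zero library size; filter empty cells first",
                 counts$cell_ids[which(ls == 0)[1]]))
  }
  if (!is.numeric(target_size) || target_size <= 0) stop("target_size must be positive")
  ls / target_size
}

# expand a scaler argument to one value per cell; NULL means unit scalers
expand_scalers <- function(scalers, n_cells) {
  if (is.null(scalers)) scalers <- 1
  if (length(scalers) == 1) scalers <- rep(scalers, n_cells)
  if (length(scalers) != n_cells) stop("scalers length does not match number of cells")
  if (any(!is.finite(scalers) | scalers <= 0)) stop("scalers must be positive and finite")
  scalers
}
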