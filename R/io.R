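#' Read a count matrix
#'
#' Dense CSV/TSV (header row = gene ids, first column = cell ids) or
#' MatrixMarket coordinate format with companion gene/cell label files
#' (1-based indices on disk, the standard convention).  All inputs are
#' normalized to the internal cells-by-genes orientation and validated as
#' non-negative integers.
#'
#' @param path input file.
#' @param format `"csv_dense"`, `"tsv_dense"` or `"mtx_triplet"`; default
#'   guessed from the file extension.
#' @param orientation `"cells_by_genes"` (default) or `"genes_by_cells"`
#'   (input is transposed on read).
#' @param gene_file,cell_file companion label files (one id per line),
#'   required for `mtx_triplet`.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path,
                        format = c("auto", "csv_dense", "tsv_dense", "mtx_triplet"),
                        orientation = c("cells_by_genes", "genes_by_cells"),
                        gene_file = NULL, cell_file = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv_dense", tsv = "tsv_dense", txt = "tsv_dense",
                     mtx = "mtx_triplet",
                     stop("cannot guess format from extension; pass format="))
  }
  if (format == "mtx_triplet") {
    if (is.null(gene_file) || is.null(cell_file)) {
      stop("mtx_triplet requires gene_file and cell_file")
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (orientation == "genes_by_cells") m <- t(m)
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop("label files do not match matrix dimensions")
    }
    return(count_matrix(m, cell_ids = cells, gene_ids = genes))
  }
  sep <- if (format == "csv_dense") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in count table")
  if (orientation == "genes_by_cells") m <- t(m)
  frac <- which(m != floor(m), arr.ind = TRUE)
  if (length(frac) > 0) {
    stop(sprintf("fractional entry %s at row '%s', column '%s'",
                 m[frac[1, 1], frac[1, 2]], rownames(m)[frac[1, 1]],
                 colnames(m)[frac[1, 2]]))
  }
  count_matrix(m)
}

#' Write a count matrix
#'
#' @param counts a [count_matrix()].
#' @param path output file.
#' @param format `"csv_dense"`, `"tsv_dense"` or `"mtx_triplet"`.  For MTX,
#'   `<path>.genes.tsv` and `<path>.cells.tsv` companions are written.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path,
                         format = c("csv_dense", "tsv_dense", "mtx_triplet")) {
  format <- match.arg(format)
  counts <- as_count_matrix(counts)
  if (format == "mtx_triplet") {
    Matrix::writeMM(Matrix::Matrix(counts$counts, sparse = TRUE), path)
    writeLines(counts$gene_ids, paste0(path, ".genes.tsv"))
    writeLines(counts$cell_ids, paste0(path, ".cells.tsv"))
    return(invisible(path))
  }
  sep <- if (format == "csv_dense") "," else "\t"
  df <- data.frame(cell_id = counts$cell_ids,
                   counts$counts, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter cells by library size
#'
#' Either trims a fraction from each tail of the library-size ranking
#' (`trim_percent`, ties broken by cell order) or keeps cells with library
#' size strictly greater than `min_library`.
#'
#' @param counts a [count_matrix()].
#' @param trim_percent fraction in `[0, 0.5)` removed from each tail.
#' @param min_library minimum library size (exclusive).
#' @return list with `counts` (filtered) and `report`.
#' @export
filter_cells <- function(counts, trim_percent = NULL, min_library = NULL) {
  counts <- as_count_matrix(counts)
  C <- nrow(counts$counts)
  keep <- rep(TRUE, C)
  rule <- list()
  if (!is.null(trim_percent)) {
    if (trim_percent < 0 || trim_percent >= 0.5) stop("trim_percent must be in [0, 0.5)")
    n_trim <- floor(trim_percent * C)
    if (n_trim > 0) {
      ord <- order(counts$library_sizes, seq_len(C))
      keep[ord[seq_len(n_trim)]] <- FALSE
      keep[ord[C - seq_len(n_trim) + 1]] <- FALSE
    }
    rule$trim_percent <- trim_percent
  }
  if (!is.null(min_library)) {
    if (min_library < 0) stop("min_library must be >= 0")
    keep <- keep & counts$library_sizes > min_library
    rule$min_library <- min_library
  }
  if (!any(keep)) stop("no cells left after filtering")
  out <- count_matrix(counts$counts[keep, , drop = FALSE],
                      counts$cell_ids[keep], counts$gene_ids)
  list(counts = out,
       report = list(cells_in = C, cells_out = sum(keep),
                     genes_in = ncol(counts$counts),
                     genes_out = ncol(counts$counts), rule = rule))
}

#' Filter genes by non-zero fraction
#'
#' Keeps genes whose fraction of cells with non-zero counts lies within
#' `[min_nonzero_frac, max_nonzero_frac]` (both bounds inclusive).
#'
#' @param counts a [count_matrix()].
#' @param min_nonzero_frac,max_nonzero_frac bounds in `[0, 1]`.
#' @return list with `counts` (filtered) and `report`.
#' @export
filter_genes <- function(counts, min_nonzero_frac = 0, max_nonzero_frac = 1) {
  counts <- as_count_matrix(counts)
  if (min_nonzero_frac < 0 || max_nonzero_frac > 1 ||
      min_nonzero_frac > max_nonzero_frac) stop("invalid bounds")
  f <- colMeans(counts$counts > 0)
  keep <- f >= min_nonzero_frac & f <= max_nonzero_frac
  if (!any(keep)) stop("no genes left after filtering")
  out <- count_matrix(counts$counts[, keep, drop = FALSE],
                      counts$cell_ids, counts$gene_ids[keep])
  list(counts = out,
       report = list(cells_in = nrow(counts$counts),
                     cells_out = nrow(counts$counts),
                     genes_in = ncol(counts$counts), genes_out = sum(keep),
                     rule = list(min_nonzero_frac = min_nonzero_frac,
                                 max_nonzero_frac = max_nonzero_frac)))
}

#' Write a DEG table as TSV
#'
#' @param deg_table data.frame from [deg_between_clusters()].
#' @param path output file.
#' @export
write_deg_table <- function(deg_table, path) {
  utils::write.table(deg_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
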