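#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' cells in columns, carrying unique gene and cell identifiers as dimnames.
#' Values are expected to be raw (untransformed) counts or count-like
#' nonnegative numbers; the mixture model downstream is fitted on these
#' values as-is, without any log transform.
#'
#' @param values numeric matrix, genes x cells, nonnegative and finite.
#' @param gene_names character vector of unique gene identifiers
#'   (default: `rownames(values)`).
#' @param cell_names character vector of unique cell identifiers
#'   (default: `colnames(values)`).
#' @return the validated matrix with dimnames set.
#' @export
as_expression_matrix <- function(values,
                                 gene_names = rownames(values),
                                 cell_names = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (genes x cells)")
  }
  if (nrow(values) < 1L) stop("expression matrix must have at least one gene (g >= 1)")
  if (ncol(values) < 1L) stop("expression matrix must have at least one cell")
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(nrow(values)))
  if (is.null(cell_names)) cell_names <- paste0("cell", seq_len(ncol(values)))
  rownames(values) <- as.character(gene_names)
  colnames(values) <- as.character(cell_names)
  validate_expression_matrix(values)
  values
}

#' Validate an expression matrix
#'
#' Checks nonnegativity, finiteness, unique labels, and dimension/label
#' agreement. Emits a warning (not an error) when more than 1% of nonzero
#' entries are non-integer, because the Binomial mixture component assumes
#' count-like data.
#'
#' @param m matrix as returned by [as_expression_matrix()].
#' @param warn_nonint warn on substantially non-integer data (default TRUE).
#' @return `m`, invisibly.
#' @export
validate_expression_matrix <- function(m, warn_nonint = TRUE) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be numeric")
  if (nrow(m) < 1L) stop("expression matrix must have at least one gene (g >= 1)")
  if (ncol(m) < 1L) stop("expression matrix must have at least one cell")
  if (anyNA(m) || any(!is.finite(m))) stop("non-finite expression value")
  if (any(m < 0)) stop("negative expression value")
  gn <- rownames(m); cn <- colnames(m)
  if (is.null(gn) || is.null(cn)) stop("gene and cell names are required")
  if (anyDuplicated(gn)) stop("duplicate gene names")
  if (anyDuplicated(cn)) stop("duplicate cell names")
  if (length(gn) != nrow(m) || length(cn) != ncol(m)) {
    stop("label length does not match matrix dimensions")
  }
  if (warn_nonint) {
    nz <- m[m != 0]
    if (length(nz) > 0) {
      frac_nonint <- mean(abs(nz - round(nz)) > 1e-8)
      if (frac_nonint > 0.01) {
        warning(sprintf(
          "%.1f%% of nonzero entries are non-integer; the Binomial component assumes count-like data",
          100 * frac_nonint))
      }
    }
  }
  invisible(m)
}

.infer_format <- function(path, format = "auto") {
  format <- match.arg(format, c("auto", "tsv", "csv", "mtx"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = "tsv", txt = "tsv", tab = "tsv",
         csv = "csv",
         mtx = "mtx",
         stop("cannot infer format from extension '", ext,
              "'; pass format explicitly"))
}

.mtx_companions <- function(path, gene_file, cell_file) {
  base <- sub("\\.mtx$", "", path, ignore.case = TRUE)
  dir <- dirname(path)
  if (is.null(gene_file)) {
    cand <- c(paste0(base, "_genes.txt"), file.path(dir, "genes.txt"))
    gene_file <- cand[file.exists(cand)][1]
    if (is.na(gene_file)) stop("no gene-name file found next to ", path)
  }
  if (is.null(cell_file)) {
    cand <- c(paste0(base, "_cells.txt"), file.path(dir, "barcodes.txt"),
              file.path(dir, "cells.txt"))
    cell_file <- cand[file.exists(cand)][1]
    if (is.na(cell_file)) stop("no cell-name file found next to ", path)
  }
  list(genes = gene_file, cells = cell_file)
}

#' Read an expression matrix
#'
#' Dense delimited files use the common scRNA-seq layout: first row holds
#' cell names, first column gene names. Matrix Market files follow the
#' CellRanger-style trio convention: `foo.mtx` with one-label-per-line
#' companions `foo_genes.txt` and `foo_cells.txt` (or `genes.txt` /
#' `barcodes.txt` in the same directory), 1-based indices, genes in rows.
#'
#' Gene and cell order is preserved exactly as stored; values are read
#' untransformed.
#'
#' @param path input file.
#' @param format one of `"auto"` (infer from extension), `"tsv"`, `"csv"`,
#'   `"mtx"`.
#' @param gene_file,cell_file explicit companion name files for mtx input.
#' @return validated expression matrix (see [as_expression_matrix()]).
#' @export
read_matrix <- function(path, format = "auto",
                        gene_file = NULL, cell_file = NULL) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  format <- .infer_format(path, format)
  if (format == "mtx") {
    comp <- .mtx_companions(path, gene_file, cell_file)
    mm <- Matrix::readMM(path)
    genes <- readLines(comp$genes)
    cells <- readLines(comp$cells)
    if (length(genes) != nrow(mm) || length(cells) != ncol(mm)) {
      stop("name files do not match matrix dimensions")
    }
    m <- as.matrix(mm)
    storage.mode(m) <- "double"
    return(as_expression_matrix(m, genes, cells))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  storage.mode(m) <- "double"
  as_expression_matrix(m, rownames(df), colnames(df))
}

#' Write an expression matrix
#'
#' Inverse of [read_matrix()]: dense TSV/CSV with cell names as header and
#' gene names as first column, or Matrix Market triplets with companion
#' `*_genes.txt` / `*_cells.txt` label files. Round-tripping reproduces
#' labels exactly and values to at least 1e-9 relative tolerance.
#'
#' @param m expression matrix.
#' @param path output file.
#' @param format see [read_matrix()].
#' @param gene_file,cell_file companion file paths for mtx output
#'   (defaults: `<path minus .mtx>_genes.txt` / `_cells.txt`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = "auto",
                         gene_file = NULL, cell_file = NULL) {
  validate_expression_matrix(m, warn_nonint = FALSE)
  format <- .infer_format(path, format)
  if (format == "mtx") {
    base <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(gene_file)) gene_file <- paste0(base, "_genes.txt")
    if (is.null(cell_file)) cell_file <- paste0(base, "_cells.txt")
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    path)
    writeLines(rownames(m), gene_file)
    writeLines(colnames(m), cell_file)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(m)), collapse = sep), con)
  utils::write.table(m, con, sep = sep, quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}
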