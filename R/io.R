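# Readers and writers: Matrix Market triplet directories, dense delimited
# tables, embeddings, groupings, score tables.

#' Read a 10x-style Matrix Market triplet directory
#'
#' Reads a genes-by-cells sparse matrix from Matrix Market coordinate format
#' plus companion gene and barcode label files (one entry per line; the genes
#' file may have one or two tab-separated columns, in which case the second
#' column is adopted as the gene symbol).
#'
#' @param matrix_path Path to the `.mtx` file, or a directory containing
#'   `matrix.mtx`, `genes.tsv` (or `features.tsv`) and `barcodes.tsv`.
#' @param genes_path,barcodes_path Label file paths; inferred from the
#'   directory when `matrix_path` is a directory.
#' @return Sparse `dgCMatrix` with gene rownames and cell colnames.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path = NULL, barcodes_path = NULL) {
  if (dir.exists(matrix_path)) {
    dir <- matrix_path
    matrix_path <- file.path(dir, "matrix.mtx")
    if (is.null(genes_path)) {
      genes_path <- file.path(dir, "genes.tsv")
      if (!file.exists(genes_path)) genes_path <- file.path(dir, "features.tsv")
    }
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
  }
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (is.null(p) || !file.exists(p)) {
      abort(sprintf("file not found: %s", p), "uscore_io_error")
    }
  }
  header <- readLines(matrix_path, n = 1L)
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate", header, ignore.case = TRUE)) {
    abort(sprintf("%s: only Matrix Market 'coordinate' (triplet) format is supported",
                  matrix_path), "uscore_unsupported_format")
  }
  m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")

  gene_lines <- readLines(genes_path, warn = FALSE)
  gene_fields <- strsplit(gene_lines, "\t", fixed = TRUE)
  genes <- vapply(gene_fields, function(f) if (length(f) >= 2L) f[2L] else f[1L], character(1))
  barcodes <- readLines(barcodes_path, warn = FALSE)

  if (length(genes) != nrow(m)) {
    abort(sprintf("gene file has %d entries but matrix header declares %d genes",
                  length(genes), nrow(m)), "uscore_format_error")
  }
  if (length(barcodes) != ncol(m)) {
    abort(sprintf("barcode file has %d entries but matrix header declares %d cells",
                  length(barcodes), ncol(m)), "uscore_format_error")
  }
  if (anyDuplicated(genes)) abort("duplicate gene symbols in genes file", "uscore_label_error")
  if (anyDuplicated(barcodes)) abort("duplicate cell barcodes in barcodes file", "uscore_label_error")
  dimnames(m) <- list(genes, barcodes)
  m
}

#' Write a matrix as a Matrix Market triplet directory
#'
#' Companion to [read_mtx_triplet()]: writes `matrix.mtx`, `genes.tsv` and
#' `barcodes.tsv` into `dir`.
#'
#' @param x Genes-by-cells matrix with dimnames.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx_triplet <- function(x, dir) {
  .check_matrix(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(x), file.path(dir, "genes.tsv"))
  writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

# split delimited lines with basic dialect detection (tab, else comma)
.detect_sep <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

#' Read a dense delimited expression table
#'
#' First row: cell identifiers (with or without a leading corner label);
#' first column: gene symbols; remaining fields numeric. Zeros are stored
#' implicitly in the returned sparse matrix.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field separator; auto-detected from the header when `NULL`.
#' @return Sparse `dgCMatrix`, genes by cells.
#' @export
read_dense_table <- function(path, sep = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "uscore_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    abort(sprintf("%s: need a header row and at least one gene row", path), "uscore_format_error")
  }
  if (is.null(sep)) sep <- .detect_sep(lines[1L])
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], sep, fixed = TRUE)
  width <- length(body[[1L]])
  cells <- if (length(header) == width) header[-1L] else if (length(header) == width - 1L) header else {
    abort(sprintf("%s: header has %d fields but data rows have %d", path,
                  length(header), width), "uscore_format_error")
  }
  genes <- character(length(body))
  vals <- matrix(0, length(body), length(cells))
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != width) {
      abort(sprintf("%s: row %d has %d fields, expected %d", path, i + 1L,
                    length(f), width), "uscore_format_error")
    }
    genes[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) {
      abort(sprintf("%s: row %d contains non-numeric values", path, i + 1L),
            "uscore_format_error")
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(genes)) {
    abort(sprintf("%s: duplicate gene symbols: %s", path,
                  paste(unique(genes[duplicated(genes)]), collapse = ", ")),
          "uscore_label_error")
  }
  dimnames(vals) <- list(genes, cells)
  methods::as(Matrix::Matrix(vals, sparse = TRUE), "CsparseMatrix")
}

#' Write an expression matrix as a dense delimited table
#' @param x Genes-by-cells matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_dense_table <- function(x, path, sep = "\t") {
  .check_matrix(x)
  dense <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(dense)), collapse = sep), con)
  writeLines(paste(rownames(dense),
                   apply(dense, 1L, paste, collapse = sep), sep = sep), con)
  invisible(path)
}

#' Read an expression matrix, dispatching on path type
#'
#' Directories are read as Matrix Market triplet bundles
#' ([read_mtx_triplet()]); `.mtx` files likewise (with sibling label files);
#' delimited files as dense tables ([read_dense_table()]). AnnData `.h5ad`
#' files are recognized but require an HDF5 reader, which this installation
#' does not provide; a clear error asks for conversion to MTX or dense text.
#'
#' @param path Input path.
#' @param layer For `.h5ad` inputs, the named layer to score (unused
#'   otherwise).
#' @return Sparse `dgCMatrix`, genes by cells.
#' @export
read_expression <- function(path, layer = NULL) {
  if (dir.exists(path)) return(read_mtx_triplet(path))
  if (grepl("\\.h5ad$", path, ignore.case = TRUE)) {
    abort(paste0(path, ": .h5ad input requires an HDF5/AnnData reader, which is not ",
                 "available in this installation; export the matrix to a Matrix ",
                 "Market triplet directory or a dense delimited table instead"),
          "uscore_unsupported_format")
  }
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    d <- dirname(path)
    return(read_mtx_triplet(path,
                            genes_path = {
                              g <- file.path(d, "genes.tsv")
                              if (file.exists(g)) g else file.path(d, "features.tsv")
                            },
                            barcodes_path = file.path(d, "barcodes.tsv")))
  }
  read_dense_table(path)
}

#' Read a cells-by-dimensions embedding table
#'
#' Delimited text, first column cell_id, remaining columns numeric
#' dimensions.
#'
#' @param path Input path.
#' @return Numeric matrix with cell rownames.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "uscore_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sep <- .detect_sep(lines[1L])
  rows <- strsplit(lines, sep, fixed = TRUE)
  has_header <- anyNA(suppressWarnings(as.numeric(rows[[1L]][-1L])))
  if (has_header) rows <- rows[-1L]
  ids <- vapply(rows, `[[`, character(1), 1L)
  emb <- t(vapply(rows, function(f) {
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) abort(sprintf("%s: non-numeric embedding values for cell %s", path, f[1L]),
                        "uscore_format_error")
    v
  }, numeric(length(rows[[1L]]) - 1L)))
  rownames(emb) <- ids
  emb
}

#' Read a cell-to-group mapping
#'
#' Two-column delimited text (cell_id, group), optional header.
#'
#' @param path Input path.
#' @return Character vector of group labels named by cell id.
#' @export
read_grouping <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "uscore_io_error")
  df <- utils::read.table(path, sep = .detect_sep(readLines(path, n = 1L)),
                          header = FALSE, stringsAsFactors = FALSE)
  if (identical(tolower(df[1L, 1L]), "cell_id")) df <- df[-1L, , drop = FALSE]
  if (ncol(df) < 2L) abort(sprintf("%s: need cell_id and group columns", path), "uscore_format_error")
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a score table as TSV
#'
#' Header `cell_id` then one column per signature (suffix `_UScore`, or
#' `_UScore_kNN` for smoothed tables); one row per cell; undefined scores
#' written as empty fields.
#'
#' @param table A `score_table`.
#' @param path Output path.
#' @param suffix Column-name suffix appended to each signature name.
#' @param float_format `sprintf` format for score values (default `"%.6g"`,
#'   6 significant digits; use `"%.17g"` for full precision).
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path, suffix = "_UScore", float_format = "%.6g") {
  stopifnot(inherits(table, "score_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cell_id", paste0(table$signature_names, suffix)), collapse = "\t"), con)
  txt <- matrix("", nrow(table$scores), ncol(table$scores))
  defined <- !is.na(table$scores)
  txt[defined] <- sprintf(float_format, table$scores[defined])
  writeLines(paste(table$cell_ids, apply(txt, 1L, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Write per-group aggregates as TSV
#' @param aggregates Data frame from [aggregate_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregates <- function(aggregates, path) {
  utils::write.table(aggregates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
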