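# Per-cell gene ranking with midrank ties and capping at r_max.
#
# Ranks are computed over ALL genes of a cell (rank 1 = highest expression),
# tied values receive their midrank, and the final rank value is capped at
# r_max AFTER midrank assignment, so capped ties are deterministic and
# independent of gene order in the input.

# dense column-wise ranking core: returns length(query) x ncol matrix of
# capped ranks. Used by both the public API and the chunked scorer.
.rank_columns <- function(dense, r_max, query) {
  out <- vapply(seq_len(ncol(dense)), function(j) {
    pmin(rank(-dense[, j], ties.method = "average"), r_max)[query]
  }, numeric(length(query)))
  matrix(out, nrow = length(query), ncol = ncol(dense),
         dimnames = list(NULL, colnames(dense)))
}

.check_rank_args <- function(n_genes, r_max, query_indices) {
  if (!is_count(r_max)) {
    abort("r_max must be a single integer >= 1", "uscore_param_error")
  }
  if (length(query_indices) == 0L ||
      any(query_indices < 1L | query_indices > n_genes | query_indices != floor(query_indices))) {
    abort(sprintf("query indices must be integers in [1, %d]", n_genes),
          "uscore_index_error")
  }
}

#' Rank genes within one cell, with ties and capping
#'
#' Ranks all genes of a single cell by descending expression (rank 1 =
#' highest). Tied values get their midrank (the average of the positions
#' they span), and every rank is then capped at `r_max`, so the long tail of
#' undetected (zero) genes shares one bounded rank value. Only the ranks of
#' `query_indices` are returned.
#'
#' @param expression Numeric vector of expression values for all genes of one
#'   cell (raw counts or normalized values; only the ordering matters).
#' @param r_max Positive integer rank cap.
#' @param query_indices Gene row indices whose ranks to materialize
#'   (default: all genes).
#' @param cell_id Optional cell identifier carried through to the result.
#' @return A `cell_ranks` object: list with `cell_id`, `ranks` (numeric,
#'   named by query index; midranks may be fractional), and `r_max`. Every
#'   rank satisfies `1 <= r <= r_max`.
#' @examples
#' rank_cell(c(5, 3, 0, 0), r_max = 10)
#' @export
rank_cell <- function(expression, r_max, query_indices = seq_along(expression),
                      cell_id = NULL) {
  if (!is.numeric(expression) || length(expression) == 0L) {
    abort("expression must be a non-empty numeric vector", "uscore_input_error")
  }
  .check_rank_args(length(expression), r_max, query_indices)
  r <- pmin(rank(-expression, ties.method = "average"), r_max)[query_indices]
  names(r) <- as.character(query_indices)
  structure(list(cell_id = cell_id, ranks = r, r_max = r_max),
            class = "cell_ranks")
}

#' Rank a chunk of cells
#'
#' Applies [rank_cell()] to every column of a genes-by-cells chunk,
#' preserving cell order. Elementwise identical to ranking each cell alone
#' (chunking transparency).
#'
#' @param chunk Genes-by-cells matrix (dense or `Matrix` sparse) of >= 1 cell.
#' @param r_max Positive integer rank cap.
#' @param query_indices Gene row indices whose ranks to materialize.
#' @return List of `cell_ranks`, one per column.
#' @export
rank_chunk <- function(chunk, r_max, query_indices = seq_len(nrow(chunk))) {
  if (is.null(dim(chunk)) || ncol(chunk) < 1L) {
    abort("chunk must be a matrix with at least one cell (column)", "uscore_input_error")
  }
  .check_rank_args(nrow(chunk), r_max, query_indices)
  dense <- as.matrix(chunk)
  ids <- colnames(chunk)
  lapply(seq_len(ncol(dense)), function(j) {
    r <- tryCatch(
      pmin(rank(-dense[, j], ties.method = "average"), r_max)[query_indices],
      error = function(e) {
        abort(sprintf("ranking failed for cell %s: %s",
                      if (is.null(ids)) j else ids[j], conditionMessage(e)),
              "uscore_input_error")
      }
    )
    names(r) <- as.character(query_indices)
    structure(list(cell_id = if (is.null(ids)) j else ids[j],
                   ranks = r, r_max = r_max),
              class = "cell_ranks")
  })
}
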