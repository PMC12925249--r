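# kNN smoothing of signature scores: decay-weighted average over each cell's
# nearest neighbours in an embedding space (typically PCA).

#' Compute a PCA embedding of cells
#'
#' Standard preprocessing for neighbour search: per-cell total-count scaling
#' to `target_sum`, log1p transform, per-gene centering, then truncated
#' principal components. Component signs follow a deterministic convention
#' (the largest-magnitude gene loading of each component is positive), so the
#' embedding is reproducible across runs.
#'
#' @param x Genes-by-cells matrix with dimnames (counts or normalized values).
#' @param n_components Number of principal components (default 20), at most
#'   `min(n_genes, n_cells)`.
#' @param target_sum Per-cell count target for library-size scaling
#'   (default 10000).
#' @param seed Unused by the deterministic computation; accepted so callers
#'   can treat all pipeline stages uniformly.
#' @return Cells-by-components numeric matrix with cell rownames.
#' @export
compute_embedding <- function(x, n_components = 20L, target_sum = 1e4, seed = NULL) {
  .check_matrix(x)
  if (!is_count(n_components) || n_components > min(dim(x))) {
    abort(sprintf("n_components must be an integer in [1, %d]", min(dim(x))),
          "uscore_param_error")
  }
  cs <- Matrix::colSums(x)
  fac <- ifelse(cs > 0, target_sum / cs, 0)
  dense <- as.matrix(x) %*% diag(fac, ncol(x))  # scale columns
  dense <- log1p(dense)
  centered <- t(dense - rowMeans(dense))        # cells x genes, gene-centered
  if (all(abs(centered) < 1e-12)) {
    abort("matrix is constant across cells; embedding is degenerate", "uscore_degenerate_embedding")
  }
  pc <- stats::prcomp(centered, center = FALSE, scale. = FALSE,
                      rank. = as.integer(n_components))
  emb <- pc$x[, seq_len(min(n_components, ncol(pc$x))), drop = FALSE]
  # deterministic sign: largest |loading| per component is positive
  for (k in seq_len(ncol(emb))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) emb[, k] <- -emb[, k]
  }
  rownames(emb) <- colnames(x)
  colnames(emb) <- paste0("PC", seq_len(ncol(emb)))
  emb
}

#' Exact k nearest neighbours in an embedding
#'
#' Brute-force Euclidean nearest neighbours, self excluded. Distance ties are
#' broken by ascending cell index, so the graph is deterministic.
#'
#' @param embedding Cells-by-dimensions numeric matrix (rownames = cell ids).
#' @param k Neighbour count; truncated to `n_cells - 1` with a warning when
#'   larger.
#' @return A `neighbor_graph`: list with `indices` and `distances`
#'   (n_cells x k matrices, neighbours ordered by increasing distance) and
#'   `k`. With a single cell the graph is empty (k = 0) with a warning.
#' @export
find_knn <- function(embedding, k) {
  if (is.null(dim(embedding)) || !is.numeric(embedding[1])) {
    abort("embedding must be a numeric cells-by-dimensions matrix", "uscore_input_error")
  }
  if (!is_count(k)) abort("k must be a single integer >= 1", "uscore_param_error")
  n <- nrow(embedding)
  if (n == 1L) {
    warn("single cell: neighbour graph is empty", "uscore_knn_warning")
    return(structure(list(indices = matrix(integer(0), 1, 0),
                          distances = matrix(numeric(0), 1, 0),
                          k = 0L, cell_ids = rownames(embedding)),
                     class = "neighbor_graph"))
  }
  if (k >= n) {
    warn(sprintf("k = %d >= n_cells = %d; truncating to %d", k, n, n - 1L),
         "uscore_knn_warning")
    k <- n - 1L
  }
  emb <- as.matrix(embedding)
  sq <- rowSums(emb^2)
  # full pairwise squared distances; exact at desk scale
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(emb)
  d2[d2 < 0] <- 0
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    ord <- order(di, seq_len(n))[seq_len(k)]  # ties -> ascending cell index
    idx[i, ] <- ord
    dst[i, ] <- sqrt(di[ord])
  }
  structure(list(indices = idx, distances = dst, k = as.integer(k),
                 cell_ids = rownames(embedding)),
            class = "neighbor_graph")
}

#' Smooth signature scores over nearest neighbours
#'
#' Replaces each cell's score by a decay-weighted average over the sequence
#' (self, neighbour 1, ..., neighbour k), with weight `(1 - lambda)^i` for
#' the i-th element (self at i = 0, weight 1). `lambda = 1` keeps every score
#' unchanged (no smoothing); `lambda = 0` gives the unweighted mean of self
#' plus neighbours. Undefined (`NA`) scores are dropped from both numerator
#' and denominator; a cell whose every contributor is undefined stays
#' undefined. Smoothed scores are convex combinations, so they remain in
#' \[0, 1\].
#'
#' @param table A `score_table`.
#' @param graph A `neighbor_graph` from [find_knn()] covering the same cells
#'   in the same order.
#' @param lambda Decay in \[0, 1\].
#' @return A new `score_table` of smoothed scores.
#' @export
smooth_scores <- function(table, graph, lambda = 0.1) {
  stopifnot(inherits(table, "score_table"), inherits(graph, "neighbor_graph"))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("lambda must be a single number in [0, 1]", "uscore_param_error")
  }
  n <- nrow(table$scores)
  if (nrow(graph$indices) != n) {
    abort("neighbour graph does not cover the score table's cells", "uscore_input_error")
  }
  if (!is.null(graph$cell_ids) && !identical(graph$cell_ids, table$cell_ids)) {
    abort("neighbour graph cell ids do not match score table", "uscore_input_error")
  }
  k <- graph$k
  w <- (1 - lambda)^(0:k)
  out <- matrix(NA_real_, n, ncol(table$scores),
                dimnames = dimnames(table$scores))
  for (s in seq_len(ncol(table$scores))) {
    v <- table$scores[, s]
    # contributions matrix: column 0 = self, columns 1..k = neighbours
    contrib <- cbind(v, if (k > 0) matrix(v[graph$indices], n, k))
    defined <- !is.na(contrib)
    cw <- matrix(w, n, k + 1L, byrow = TRUE) * defined
    contrib[!defined] <- 0
    den <- rowSums(cw)
    num <- rowSums(cw * contrib)
    out[, s] <- ifelse(den > 0, num / den, NA_real_)
  }
  score_table(out)
}
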