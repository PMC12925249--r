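# Independent naive oracle for rank-based signature scoring.
#
# Deliberately avoids the package's code paths: midranks come from a
# hand-written tie-group walk over a full sort (not base rank()), and scores
# are computed per cell from the direct formulas on a dense matrix.

# descending midranks: rank 1 = highest value; ties get the average of the
# positions they span
oracle_midranks <- function(x) {
  ord <- order(x, decreasing = TRUE)
  r <- numeric(length(x))
  pos <- 1L
  n <- length(x)
  while (pos <= n) {
    end <- pos
    while (end < n && x[ord[end + 1L]] == x[ord[pos]]) end <- end + 1L
    r[ord[pos:end]] <- mean(pos:end)
    pos <- end + 1L
  }
  r
}

oracle_component <- function(ranks, n, r_max, legacy = FALSE) {
  if (r_max < n) return(NA_real_)
  u_max <- if (legacy) n * r_max else n * r_max - n * (n + 1) / 2
  if (u_max <= 0) return(NA_real_)
  u <- sum(ranks) - n * (n + 1) / 2
  min(1, max(0, 1 - u / u_max))
}

# full naive scorer on a dense matrix; sig is a gene_signature; policy and
# legacy flags mirror the package semantics
oracle_scores <- function(dense, sig, r_max, w = 1, policy = "impute_zero",
                          legacy = FALSE) {
  genes <- rownames(dense)
  pos <- sig$positive
  neg <- sig$negative
  if (policy == "impute_zero") {
    missing <- setdiff(c(pos, neg), genes)
    if (length(missing) > 0) {
      dense <- rbind(dense, matrix(0, length(missing), ncol(dense),
                                   dimnames = list(missing, colnames(dense))))
      genes <- rownames(dense)
    }
  } else {
    pos <- intersect(pos, genes)
    neg <- intersect(neg, genes)
  }
  n_pos <- length(pos)
  n_neg <- length(neg)
  if (n_pos == 0L) return(rep(NA_real_, ncol(dense)))
  vapply(seq_len(ncol(dense)), function(j) {
    r <- pmin(oracle_midranks(dense[, j]), r_max)
    sp <- oracle_component(r[match(pos, genes)], n_pos, r_max, legacy)
    if (n_neg == 0L) return(sp)
    sn <- oracle_component(r[match(neg, genes)], n_neg, r_max, legacy)
    if (is.na(sp) || is.na(sn)) return(NA_real_)
    min(1, max(0, sp - w * sn))
  }, numeric(1))
}

# random sparse count fixture with dimnames
random_fixture <- function(n_genes, n_cells, sparsity = 0.8, max_count = 20L) {
  vals <- matrix(
    ifelse(runif(n_genes * n_cells) < sparsity, 0L,
           sample.int(max_count, n_genes * n_cells, replace = TRUE)),
    n_genes, n_cells,
    dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                    sprintf("c%03d", seq_len(n_cells))))
  vals
}

as_sparse <- function(dense) {
  methods::as(Matrix::Matrix(dense, sparse = TRUE), "CsparseMatrix")
}

# random signature drawn from (and possibly beyond) a gene universe
random_signature <- function(genes, n_pos, n_neg = 0L, name = "rand") {
  picked <- sample(genes, n_pos + n_neg)
  parse_signature(name, c(picked[seq_len(n_pos)],
                          if (n_neg > 0) paste0(picked[n_pos + seq_len(n_neg)], "-")))
}
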