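# U-statistic signature scoring: per-cell Mann-Whitney U on capped ranks,
# positive/negative set combination, chunked driver, per-group aggregation.

#' Scoring parameters
#'
#' Bundles the tunables of signature scoring.
#'
#' @param r_max Positive integer rank cap (default 1500, suited to 10X
#'   Chromium scRNA-seq; set it near the median number of detected genes per
#'   cell, and lower it for targeted panels).
#' @param neg_weight Non-negative weight `w` of the negative-set component in
#'   the combined score (default 1).
#' @param missing Missing-gene policy, `"impute_zero"` (default; absent genes
#'   are treated as unexpressed) or `"skip"` (absent genes were not measured
#'   and are excluded).
#' @param chunk_size Positive integer number of cells ranked per mini-batch
#'   (default 500). Results are identical for any chunk size; smaller chunks
#'   bound the memory used by dense per-cell ranking.
#' @param legacy_norm Use the legacy v1 normalization `U_max = n * r_max`
#'   instead of the corrected `U_max = n * r_max - n(n+1)/2`. The legacy
#'   constant overestimates the attainable maximum of U, so legacy scores are
#'   never greater than corrected scores; kept only for comparison.
#' @return A `scoring_params` object.
#' @export
scoring_params <- function(r_max = 1500L, neg_weight = 1, missing = c("impute_zero", "skip"),
                           chunk_size = 500L, legacy_norm = FALSE) {
  if (!is_count(r_max)) abort("r_max must be a single integer >= 1", "uscore_param_error")
  if (!is.numeric(neg_weight) || length(neg_weight) != 1L || is.na(neg_weight) || neg_weight < 0) {
    abort("neg_weight must be a single non-negative number", "uscore_param_error")
  }
  if (!is.character(missing) || !all(missing %in% c("impute_zero", "skip"))) {
    abort(sprintf("unknown missing-gene policy '%s' (use 'impute_zero' or 'skip')",
                  paste(missing, collapse = ",")), "uscore_config_error")
  }
  if (!is_count(chunk_size)) abort("chunk_size must be a single integer >= 1", "uscore_param_error")
  if (!is.logical(legacy_norm) || length(legacy_norm) != 1L || is.na(legacy_norm)) {
    abort("legacy_norm must be TRUE or FALSE", "uscore_param_error")
  }
  structure(list(r_max = as.integer(r_max), neg_weight = neg_weight,
                 missing = missing[1L], chunk_size = as.integer(chunk_size),
                 legacy_norm = legacy_norm),
            class = "scoring_params")
}

#' Mann-Whitney U statistic from capped ranks
#'
#' `U = sum(ranks) - n(n+1)/2`, where `ranks` are the (possibly capped,
#' possibly fractional midrank) ranks of the n signature genes within one
#' cell's full expression profile. U is 0 when the signature genes occupy the
#' top n ranks.
#'
#' @param ranks Numeric vector of capped rank values (each >= 1).
#' @param n Set size; defaults to `length(ranks)` and must equal it.
#' @return The U statistic (non-negative for valid ranks).
#' @export
u_statistic <- function(ranks, n = length(ranks)) {
  if (n < 1L || length(ranks) != n) {
    abort("U statistic undefined: need n >= 1 rank values", "uscore_undefined_statistic")
  }
  sum(ranks) - n * (n + 1) / 2
}

#' Score one gene set from its capped ranks
#'
#' Computes `1 - U / U_max` with `U_max = n * r_max - n(n+1)/2` (or the
#' legacy `n * r_max`). The score is 1 when the set occupies the top n ranks
#' and 0 when every rank is capped at `r_max`. When `r_max < n` (set larger
#' than the cap, where `U_max` may be non-positive) the score is undefined
#' and `NA` is returned.
#'
#' @param ranks Capped rank values for the gene set in one cell.
#' @param n Set size (defaults to `length(ranks)`).
#' @param r_max Rank cap used to produce `ranks`.
#' @param legacy_norm Use the legacy v1 `U_max = n * r_max`.
#' @return Score in \[0, 1\], or `NA` when undefined.
#' @export
u_component <- function(ranks, n = length(ranks), r_max, legacy_norm = FALSE) {
  if (r_max < n) return(NA_real_)
  u_max <- if (legacy_norm) n * r_max else n * r_max - n * (n + 1) / 2
  if (u_max <= 0) return(NA_real_)
  min(1, max(0, 1 - u_statistic(ranks, n) / u_max))
}

#' Combine positive and negative set scores
#'
#' `score = max(0, pos - w * neg)`, clipped at zero so combined scores stay
#' in \[0, 1\]. With no negative set the positive score passes through.
#'
#' @param score_pos Positive-set score in \[0, 1\].
#' @param score_neg Negative-set score in \[0, 1\], or `NULL`/`NA` if absent.
#' @param w Non-negative weight of the negative component.
#' @return Combined score in \[0, 1\].
#' @export
combine_pos_neg <- function(score_pos, score_neg = NULL, w = 1) {
  if (is.null(score_neg) || is.na(score_neg)) return(score_pos)
  if (is.na(score_pos)) return(NA_real_)
  min(1, max(0, score_pos - w * score_neg))
}

# --- score table container ---------------------------------------------------

score_table <- function(scores) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)), !is.null(colnames(scores)))
  structure(list(scores = scores,
                 cell_ids = rownames(scores),
                 signature_names = colnames(scores)),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d cells x %d signatures\n",
              nrow(x$scores), ncol(x$scores)))
  n_undef <- sum(is.na(x$scores))
  if (n_undef > 0) cat(sprintf("  undefined entries: %d\n", n_undef))
  print(utils::head(x$scores, 4L))
  if (nrow(x$scores) > 4L) cat(sprintf("  ... %d more cells\n", nrow(x$scores) - 4L))
  invisible(x)
}

#' @export
as.data.frame.score_table <- function(x, ..., suffix = "_UScore") {
  df <- as.data.frame(x$scores)
  names(df) <- paste0(x$signature_names, suffix)
  cbind(data.frame(cell_id = x$cell_ids, stringsAsFactors = FALSE), df,
        row.names = NULL)
}

# --- chunked scoring driver --------------------------------------------------

.check_matrix <- function(x) {
  if (is.null(dim(x)) || nrow(x) < 1L || ncol(x) < 1L) {
    abort("expression matrix must have at least one gene and one cell", "uscore_input_error")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("expression matrix must carry gene rownames and cell colnames", "uscore_input_error")
  }
  if (anyDuplicated(rownames(x))) abort("duplicate gene symbols in matrix", "uscore_label_error")
  if (anyDuplicated(colnames(x))) abort("duplicate cell identifiers in matrix", "uscore_label_error")
  invisible(x)
}

# append all-zero rows for genes missing from the matrix (impute_zero policy:
# absent genes are unexpressed, so they join the zero tie tail when ranking).
.augment_zero_rows <- function(x, genes) {
  if (length(genes) == 0L) return(x)
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(length(genes), ncol(x)),
                               dimnames = list(genes, colnames(x)))
  rbind(methods::as(x, "CsparseMatrix"), zero)
}

#' Score gene signatures across all cells of an expression matrix
#'
#' For every cell: genes are ranked by descending expression with midrank
#' ties, ranks are capped at `params$r_max`, the positive (and, if present,
#' negative) set is scored as `1 - U/U_max`, and the two components are
#' combined as `max(0, pos - w * neg)`. Cells are processed in chunks of
#' `params$chunk_size`; ranking is shared across signatures within a chunk,
#' and the result is identical for any chunk size or worker count.
#'
#' Missing signature genes are handled per `params$missing`: under
#' `"impute_zero"` they are appended to the matrix as all-zero rows before
#' ranking (exactly equivalent to having measured them as zeros); under
#' `"skip"` they are dropped from the set. A signature with no genes left in
#' its positive set scores `NA` (undefined, never 0) with a warning; a
#' surviving positive set with a fully-missing negative set is scored as
#' positive-only with a warning.
#'
#' @param x Genes-by-cells matrix (sparse `Matrix` or dense) with gene
#'   rownames and cell colnames; raw counts or normalized values (scores
#'   depend only on within-cell ordering, so any per-cell monotone transform
#'   leaves them unchanged).
#' @param signatures A `gene_signature`, list of them, or named list of token
#'   character vectors (parsed via [parse_signature()]).
#' @param params A [scoring_params()] object.
#' @param workers Number of parallel workers for chunk processing (forked via
#'   the parallel package when > 1; output is identical for any count).
#' @return A `score_table`: `$scores` is a cells-by-signatures numeric matrix
#'   with `NA` marking undefined entries.
#' @examples
#' m <- Matrix::Matrix(c(5, 3, 0, 0), nrow = 4, sparse = TRUE,
#'                     dimnames = list(paste0("g", 1:4), "cell1"))
#' sig <- parse_signature("top2", c("g1", "g2"))
#' score_signatures(m, sig, scoring_params(r_max = 10))$scores
#' @export
score_signatures <- function(x, signatures, params = scoring_params(), workers = 1L) {
  .check_matrix(x)
  if (!inherits(params, "scoring_params")) {
    abort("params must be created with scoring_params()", "uscore_param_error")
  }
  if (!is_count(workers)) abort("workers must be a single integer >= 1", "uscore_param_error")
  sigs <- as_signature_list(signatures)

  resolved <- lapply(sigs, resolve_signature, gene_universe = rownames(x),
                     policy = params$missing)

  if (params$missing == "impute_zero") {
    missing_union <- unique(unlist(lapply(resolved, function(r) c(r$pos_missing, r$neg_missing))))
    if (length(missing_union) > 0L) {
      x <- .augment_zero_rows(x, missing_union)
      resolved <- lapply(sigs, resolve_signature, gene_universe = rownames(x),
                         policy = "impute_zero")
    }
  }

  # per-signature scoring plan; warnings about degraded signatures are
  # emitted once here, not per chunk
  plan <- lapply(resolved, function(r) {
    nm <- r$signature$name
    if (length(c(r$pos_missing, r$neg_missing)) > 0L) {
      warn(sprintf("signature '%s': %d gene(s) not in matrix under policy '%s': %s",
                   nm, length(c(r$pos_missing, r$neg_missing)), r$policy,
                   paste(c(r$pos_missing, r$neg_missing), collapse = ", ")),
           "uscore_missing_genes")
    }
    if (r$unscorable || r$n_pos == 0L) {
      warn(sprintf("signature '%s' is unscorable under policy '%s' (no positive genes found); scores reported as undefined",
                   nm, r$policy), "uscore_unscorable")
      return(list(scorable = FALSE))
    }
    use_neg <- r$n_neg > 0L
    if (!use_neg && length(r$signature$negative) > 0L) {
      warn(sprintf("signature '%s': negative set entirely missing under policy 'skip'; scoring positive set only",
                   nm), "uscore_missing_negative")
    }
    list(scorable = TRUE, pos = r$pos_indices, neg = if (use_neg) r$neg_indices,
         n_pos = r$n_pos, n_neg = r$n_neg)
  })

  query <- sort(unique(unlist(lapply(plan, function(p) c(p$pos, p$neg)))))
  if (length(query) == 0L) query <- 1L  # all signatures unscorable; rank something
  qpos <- function(idx) match(idx, query)

  n_cells <- ncol(x)
  starts <- seq(1L, n_cells, by = params$chunk_size)
  chunks <- lapply(starts, function(s) s:min(s + params$chunk_size - 1L, n_cells))

  score_chunk <- function(cols) {
    ranks <- .rank_columns(as.matrix(x[, cols, drop = FALSE]), params$r_max, query)
    out <- matrix(NA_real_, nrow = length(cols), ncol = length(plan))
    for (k in seq_along(plan)) {
      p <- plan[[k]]
      if (!p$scorable) next
      pr <- ranks[qpos(p$pos), , drop = FALSE]
      pos_score <- vapply(seq_len(ncol(pr)), function(j) {
        u_component(pr[, j], p$n_pos, params$r_max, params$legacy_norm)
      }, numeric(1))
      if (!is.null(p$neg)) {
        nr <- ranks[qpos(p$neg), , drop = FALSE]
        neg_score <- vapply(seq_len(ncol(nr)), function(j) {
          u_component(nr[, j], p$n_neg, params$r_max, params$legacy_norm)
        }, numeric(1))
        out[, k] <- mapply(combine_pos_neg, pos_score, neg_score,
                           MoreArgs = list(w = params$neg_weight))
      } else {
        out[, k] <- pos_score
      }
    }
    out
  }

  pieces <- if (workers > 1L) {
    parallel::mclapply(chunks, score_chunk, mc.cores = workers)
  } else {
    lapply(chunks, score_chunk)
  }
  scores <- do.call(rbind, pieces)
  dimnames(scores) <- list(colnames(x), names(sigs))
  score_table(scores)
}

#' Aggregate cell scores to per-group means
#'
#' Cells are rarely independent replicates; comparing score distributions at
#' the single-cell level invites pseudo-replication. This helper computes the
#' mean defined score per (group, signature) — typically with the sample as
#' the group — for use as the unit of downstream statistical tests. Undefined
#' (`NA`) scores are excluded from means; a group with no defined scores gets
#' an undefined aggregate.
#'
#' @param table A `score_table` from [score_signatures()].
#' @param grouping Group label per cell: a vector named by cell id, an
#'   unnamed vector in cell order, or a two-column data frame
#'   (cell_id, group). Every cell must have a label.
#' @return Data frame with columns `group`, `signature`, `mean_score`,
#'   `n_cells` (group size) and `n_defined` (cells contributing to the mean).
#' @export
aggregate_scores <- function(table, grouping) {
  stopifnot(inherits(table, "score_table"))
  cells <- table$cell_ids
  if (is.data.frame(grouping)) {
    if (ncol(grouping) < 2L) abort("grouping data frame needs cell_id and group columns", "uscore_input_error")
    grouping <- stats::setNames(as.character(grouping[[2L]]), as.character(grouping[[1L]]))
  }
  g <- if (!is.null(names(grouping))) unname(grouping[cells]) else {
    if (length(grouping) != length(cells)) {
      abort("unnamed grouping must have one label per cell", "uscore_input_error")
    }
    as.character(grouping)
  }
  if (anyNA(g)) {
    abort(sprintf("cells without a group label: %s",
                  paste(utils::head(cells[is.na(g)], 5L), collapse = ", ")),
          "uscore_input_error")
  }
  groups <- unique(g)
  res <- do.call(rbind, lapply(groups, function(grp) {
    rows <- which(g == grp)
    do.call(rbind, lapply(seq_along(table$signature_names), function(k) {
      v <- table$scores[rows, k]
      nd <- sum(!is.na(v))
      data.frame(group = grp, signature = table$signature_names[k],
                 mean_score = if (nd > 0) mean(v, na.rm = TRUE) else NA_real_,
                 n_cells = length(rows), n_defined = nd,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(res) <- NULL
  res
}
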