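# Gene signature parsing, GMT input, and resolution against a gene universe.

# suffix characters interpreted as set membership when final in a token:
# ASCII '+' -> positive, ASCII '-' or typographic minus U+2212 -> negative.
.NEG_SUFFIX <- c("-", "−")
.POS_SUFFIX <- "+"

#' Parse a gene signature from suffixed tokens
#'
#' A signature is supplied as a list of gene symbols in which each symbol may
#' carry a trailing `+` (positive set) or `-`/`−` (negative set) suffix.
#' Unsuffixed symbols belong to the positive set. Only the final character of
#' a token is interpreted as a suffix; duplicate symbols within a set are
#' collapsed (first occurrence wins), preserving token order.
#'
#' @param name Signature label (single non-empty string).
#' @param tokens Character vector of gene tokens, e.g. `c("CD8A+", "CD4-")`.
#' @return A `gene_signature` object: list with `name`, `positive`,
#'   `negative` (character vectors of bare symbols).
#' @examples
#' parse_signature("cytotoxic", c("GZMB", "PRF1+", "SELL-"))
#' @export
parse_signature <- function(name, tokens) {
  if (!is_string(name)) {
    abort("signature name must be a single non-empty string", "uscore_invalid_signature")
  }
  if (!is.character(tokens) || length(tokens) == 0L) {
    abort(sprintf("signature '%s': token list is empty", name), "uscore_invalid_signature")
  }
  if (anyNA(tokens) || any(!nzchar(tokens))) {
    abort(sprintf("signature '%s': tokens must be non-empty strings", name),
          "uscore_invalid_signature")
  }

  last <- substr(tokens, nchar(tokens), nchar(tokens))
  negative_tok <- last %in% .NEG_SUFFIX
  positive_suf <- last == .POS_SUFFIX
  symbols <- ifelse(negative_tok | positive_suf,
                    substr(tokens, 1L, nchar(tokens) - 1L), tokens)
  if (any(!nzchar(symbols))) {
    bad <- tokens[!nzchar(symbols)][1L]
    abort(sprintf("signature '%s': token '%s' has no gene symbol before its suffix",
                  name, bad), "uscore_invalid_signature")
  }

  positive <- unique(symbols[!negative_tok])
  negative <- unique(symbols[negative_tok])
  both <- intersect(positive, negative)
  if (length(both) > 0L) {
    abort(sprintf("signature '%s': gene(s) %s appear in both the positive and negative set",
                  name, paste(sQuote(both), collapse = ", ")),
          "uscore_conflicting_sign")
  }

  structure(list(name = name, positive = positive, negative = negative),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s\n", x$name))
  cat(sprintf("  positive (%d): %s\n", length(x$positive),
              paste(x$positive, collapse = ", ")))
  if (length(x$negative)) {
    cat(sprintf("  negative (%d): %s\n", length(x$negative),
                paste(x$negative, collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a signature back to suffixed tokens
#'
#' Inverse of [parse_signature()] up to duplicate collapse: positive genes
#' are emitted bare, negative genes with a trailing `-`.
#'
#' @param sig A `gene_signature`.
#' @return Character vector of tokens.
#' @export
signature_tokens <- function(sig) {
  stopifnot(inherits(sig, "gene_signature"))
  c(sig$positive, if (length(sig$negative)) paste0(sig$negative, "-"))
}

#' Read gene signatures from a GMT file
#'
#' GMT (Gene Matrix Transposed) is the community-standard gene-set exchange
#' format: one tab-separated line per set, `name<TAB>description<TAB>gene...`.
#' The description field is ignored; `+`/`-` gene suffixes are honoured as in
#' [parse_signature()]. Blank lines are skipped.
#'
#' @param path Path to a GMT file, or a character vector of lines.
#' @return List of `gene_signature` objects in file order.
#' @export
read_gmt <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  keep <- which(nzchar(trimws(lines)))
  sigs <- vector("list", length(keep))
  names_seen <- character(0)
  for (k in seq_along(keep)) {
    i <- keep[k]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      abort(sprintf("GMT line %d: expected at least 3 tab-separated fields (name, description, genes), got %d",
                    i, length(fields)), "uscore_format_error")
    }
    nm <- fields[1L]
    if (nm %in% names_seen) {
      abort(sprintf("GMT line %d: duplicate signature name '%s'", i, nm),
            "uscore_name_collision")
    }
    names_seen <- c(names_seen, nm)
    sigs[[k]] <- parse_signature(nm, fields[-(1:2)])
  }
  sigs
}

#' Resolve a signature against a matrix's gene universe
#'
#' Maps each signature gene to its row index in `gene_universe` and records
#' genes that are absent. The missing-gene policy determines the effective
#' set size used downstream: under `"impute_zero"` missing genes count as
#' zero-expression members (effective n = original set size, appropriate for
#' whole-transcriptome data where undetected genes were filtered out); under
#' `"skip"` they are excluded (effective n = genes found, appropriate for
#' targeted panels where absent genes were never measured).
#'
#' @param sig A `gene_signature`.
#' @param gene_universe Character vector of unique gene symbols (matrix rows).
#' @param policy `"impute_zero"` or `"skip"`.
#' @return A `resolved_signature`: list with `signature`, `pos_indices`,
#'   `neg_indices` (1-based row indices of found genes), `pos_missing`,
#'   `neg_missing`, `policy`, effective sizes `n_pos`/`n_neg`, and
#'   `unscorable` (TRUE when, under skip, both sets are empty after
#'   resolution — the score must then be reported undefined, never 0).
#' @export
resolve_signature <- function(sig, gene_universe, policy = c("impute_zero", "skip")) {
  stopifnot(inherits(sig, "gene_signature"))
  if (!is.character(policy) || !all(policy %in% c("impute_zero", "skip"))) {
    abort(sprintf("unknown missing-gene policy '%s' (use 'impute_zero' or 'skip')",
                  paste(policy, collapse = ",")), "uscore_config_error")
  }
  policy <- policy[1L]
  if (!is.character(gene_universe) || length(gene_universe) == 0L) {
    abort("gene universe must be a non-empty character vector", "uscore_input_error")
  }
  if (anyDuplicated(gene_universe)) {
    abort("gene universe contains duplicate symbols", "uscore_label_error")
  }

  pos_idx <- match(sig$positive, gene_universe)
  neg_idx <- match(sig$negative, gene_universe)
  pos_missing <- sig$positive[is.na(pos_idx)]
  neg_missing <- sig$negative[is.na(neg_idx)]
  pos_found <- pos_idx[!is.na(pos_idx)]
  neg_found <- neg_idx[!is.na(neg_idx)]

  if (policy == "impute_zero") {
    n_pos <- length(sig$positive)
    n_neg <- length(sig$negative)
  } else {
    n_pos <- length(pos_found)
    n_neg <- length(neg_found)
  }
  unscorable <- policy == "skip" && n_pos == 0L && n_neg == 0L

  structure(list(
    signature = sig,
    pos_indices = pos_found, neg_indices = neg_found,
    pos_missing = pos_missing, neg_missing = neg_missing,
    policy = policy, n_pos = n_pos, n_neg = n_neg,
    unscorable = unscorable
  ), class = "resolved_signature")
}

# Normalize user input (one gene_signature, a list of them, or a named list
# of token character vectors) to a uniquely named list of gene_signature.
as_signature_list <- function(signatures) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  if (!is.list(signatures) || length(signatures) == 0L) {
    abort("signatures must be a non-empty gene_signature or list of signatures/token vectors",
          "uscore_invalid_signature")
  }
  nms <- names(signatures)
  out <- vector("list", length(signatures))
  for (i in seq_along(signatures)) {
    s <- signatures[[i]]
    if (inherits(s, "gene_signature")) {
      out[[i]] <- s
    } else if (is.character(s)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else sprintf("signature%d", i)
      out[[i]] <- parse_signature(nm, s)
    } else {
      abort("each signature must be a gene_signature or a character vector of tokens",
            "uscore_invalid_signature")
    }
  }
  labels <- vapply(out, `[[`, character(1), "name")
  if (anyDuplicated(labels)) {
    abort(sprintf("duplicate signature names: %s",
                  paste(unique(labels[duplicated(labels)]), collapse = ", ")),
          "uscore_name_collision")
  }
  names(out) <- labels
  out
}
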