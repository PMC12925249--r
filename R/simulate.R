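# Synthetic sparse count matrices with planted signature-positive populations.
#
# Counts follow a gamma-Poisson (negative binomial) model: per-gene baseline
# rates (lognormal), per-cell depth factors (lognormal), and a global scale
# calibrated so the expected zero fraction matches the requested sparsity.
# Cells belonging to a planted population have their signature's positive
# genes multiplied by a fold factor and negative genes divided by it.

#' Specify a synthetic single-cell count simulation
#'
#' @param n_genes,n_cells Matrix dimensions.
#' @param sparsity Target fraction of zero entries, in (0, 1) (default 0.9,
#'   typical of droplet scRNA-seq). The realized sparsity is within a few
#'   percentage points of the target.
#' @param populations List of planted populations, each a list with
#'   `signature` (a `gene_signature` over this universe's symbols `g0001`,
#'   `g0002`, ...), `fraction` (member fraction of cells) and `fold`
#'   (expression fold-elevation of positive genes; negative genes are
#'   suppressed by the same factor). Fractions must sum to <= 1, folds be
#'   positive.
#' @param n_samples Number of sample labels assigned to cells (for per-sample
#'   aggregation), default 4.
#' @param dispersion Negative binomial size parameter (default 0.5; smaller
#'   means more overdispersion).
#' @param depth_sdlog Lognormal sd of per-cell depth factors (default 0.35).
#' @param rate_sdlog Lognormal sd of per-gene baseline rates (default 1).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(n_genes = 2000L, n_cells = 1000L, sparsity = 0.9,
                            populations = list(), n_samples = 4L,
                            dispersion = 0.5, depth_sdlog = 0.35,
                            rate_sdlog = 1, seed = 42L) {
  if (!is_count(n_genes) || !is_count(n_cells)) {
    abort("n_genes and n_cells must be positive integers", "uscore_spec_error")
  }
  if (!is.numeric(sparsity) || sparsity <= 0 || sparsity >= 1) {
    abort("sparsity must lie in (0, 1)", "uscore_spec_error")
  }
  fr <- vapply(populations, function(p) p$fraction, numeric(1))
  fo <- vapply(populations, function(p) p$fold, numeric(1))
  if (length(fr) && (any(fr <= 0) || sum(fr) > 1)) {
    abort("population fractions must be positive and sum to <= 1", "uscore_spec_error")
  }
  if (length(fo) && any(fo <= 0)) abort("population folds must be positive", "uscore_spec_error")
  for (p in populations) {
    if (!inherits(p$signature, "gene_signature")) {
      abort("each population needs a gene_signature", "uscore_spec_error")
    }
  }
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 sparsity = sparsity, populations = populations,
                 n_samples = as.integer(n_samples), dispersion = dispersion,
                 depth_sdlog = depth_sdlog, rate_sdlog = rate_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Gene symbols of the synthetic universe
#' @param n_genes Number of genes.
#' @return Character vector `g0001`, `g0002`, ...
#' @export
synthetic_genes <- function(n_genes) sprintf("g%04d", seq_len(n_genes))

# expected zero fraction of NB(mu, size) averaged over a rate/depth grid
.expected_zero <- function(scale, rates, depths, size) {
  mu <- outer(rates, depths) * scale
  mean((size / (size + mu))^size)
}

#' Generate a synthetic sparse count matrix with planted populations
#'
#' Draws overdispersed counts from the model described in
#' [simulation_spec()], plants the requested signature-positive populations,
#' and returns the matrix together with ground-truth cell labels.
#'
#' @param spec A `simulation_spec`.
#' @return List with `matrix` (sparse `dgCMatrix`, genes by cells), `cells`
#'   (data frame: `cell_id`, `population` — `"background"` for unplanted
#'   cells — and `sample`), and `spec`.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  genes <- synthetic_genes(spec$n_genes)
  for (p in spec$populations) {
    sig_genes <- c(p$signature$positive, p$signature$negative)
    if (!all(sig_genes %in% genes)) {
      abort(sprintf("population signature '%s' uses genes outside the %d-gene universe",
                    p$signature$name, spec$n_genes), "uscore_spec_error")
    }
  }
  set.seed(spec$seed)
  cells <- sprintf("cell%05d", seq_len(spec$n_cells))

  rates <- rlnorm(spec$n_genes, meanlog = 0, sdlog = spec$rate_sdlog)
  depths <- rlnorm(spec$n_cells, meanlog = 0, sdlog = spec$depth_sdlog)

  # calibrate a global scale so the expected zero fraction hits the target
  depth_probe <- depths[seq_len(min(200L, spec$n_cells))]
  scale <- uniroot(function(ls) {
    .expected_zero(10^ls, rates, depth_probe, spec$dispersion) - spec$sparsity
  }, interval = c(-8, 8), tol = 1e-4)$root
  scale <- 10^scale

  # population membership: shuffle cells, carve consecutive blocks
  population <- rep("background", spec$n_cells)
  shuffled <- sample.int(spec$n_cells)
  offset <- 0L
  for (p in spec$populations) {
    n_mem <- round(p$fraction * spec$n_cells)
    if (n_mem > 0L) {
      population[shuffled[offset + seq_len(n_mem)]] <- p$signature$name
      offset <- offset + n_mem
    }
  }
  sample_lab <- paste0("sample", sample.int(spec$n_samples, spec$n_cells, replace = TRUE))

  # per-population fold multipliers on gene rates
  fold_mult <- lapply(spec$populations, function(p) {
    m <- rep(1, spec$n_genes)
    m[match(p$signature$positive, genes)] <- p$fold
    if (length(p$signature$negative)) m[match(p$signature$negative, genes)] <- 1 / p$fold
    m
  })
  names(fold_mult) <- vapply(spec$populations, function(p) p$signature$name, character(1))

  counts <- matrix(0L, spec$n_genes, spec$n_cells)
  base_mu <- rates * scale
  for (j in seq_len(spec$n_cells)) {
    mu <- base_mu * depths[j]
    pop <- population[j]
    if (pop != "background") mu <- mu * fold_mult[[pop]]
    counts[, j] <- rnbinom(spec$n_genes, size = spec$dispersion, mu = mu)
  }
  dimnames(counts) <- list(genes, cells)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")

  list(matrix = m,
       cells = data.frame(cell_id = cells, population = population,
                          sample = sample_lab, stringsAsFactors = FALSE),
       spec = spec)
}

#' Write a simulation to disk as reusable fixtures
#'
#' Writes the matrix in MTX-triplet form, the ground-truth labels as a
#' `cell_id<TAB>label` TSV (compatible with the CLI's `--groupby`), and the
#' generating parameters as a plain-text `key=value` manifest.
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory.
#' @param dense Also write a dense TSV copy of the matrix.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, dense = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_triplet(sim$matrix, dir)
  utils::write.table(sim$cells[, c("cell_id", "population")],
                     file.path(dir, "populations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$cells[, c("cell_id", "sample")],
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (dense) write_dense_table(sim$matrix, file.path(dir, "matrix_dense.tsv"))
  sp <- sim$spec
  manifest <- c(
    sprintf("n_genes=%d", sp$n_genes), sprintf("n_cells=%d", sp$n_cells),
    sprintf("sparsity=%g", sp$sparsity), sprintf("n_samples=%d", sp$n_samples),
    sprintf("dispersion=%g", sp$dispersion), sprintf("depth_sdlog=%g", sp$depth_sdlog),
    sprintf("rate_sdlog=%g", sp$rate_sdlog), sprintf("seed=%d", sp$seed),
    vapply(sp$populations, function(p) {
      sprintf("population=%s:fraction=%g:fold=%g:tokens=%s", p$signature$name,
              p$fraction, p$fold, paste(signature_tokens(p$signature), collapse = ","))
    }, character(1))
  )
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}
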