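test_that("U statistic matches the rank-sum formula and the pairwise count", {
  expect_equal(u_statistic(c(1, 2)), 0)
  expect_equal(u_statistic(c(1, 5)), 3)
  expect_equal(u_statistic(c(10, 10)), 17)
  expect_error(u_statistic(numeric(0)), class = "uscore_undefined_statistic")

  # pairwise Mann-Whitney count oracle on an explicit 10-gene cell:
  # U = #{(sig gene, other gene) pairs where the other gene is more highly
  # expressed}, counting ties as 1/2 (uncapped ranks)
  set.seed(31)
  for (i in 1:10) {
    x <- sample(c(0, 0, 0, rpois(7, 4)))
    sig_idx <- sample.int(10, 3)
    ranks <- oracle_midranks(x)[sig_idx]
    pair_u <- sum(vapply(sig_idx, function(g) {
      others <- setdiff(seq_along(x), sig_idx)
      sum(x[others] > x[g]) + 0.5 * sum(x[others] == x[g])
    }, numeric(1)))
    # within-set pairs contribute n(n-1)/2, absorbed by the n(n+1)/2 shift,
    # so U equals the cross-pair count exactly
    expect_equal(u_statistic(ranks), pair_u)
  }
})

test_that("component scores follow 1 - U/U_max with the v2 normalization", {
  expect_equal(u_component(c(1, 2), r_max = 10), 1)
  expect_equal(u_component(c(1, 5), r_max = 10), 1 - 3 / 17)
  expect_equal(u_component(c(10, 10), r_max = 10), 0)
  # legacy v1 constant n*r_max
  expect_equal(u_component(c(1, 5), r_max = 10, legacy_norm = TRUE), 1 - 3 / 20)
  # signature larger than the cap: undefined
  expect_true(is.na(u_component(c(2, 2, 2), n = 3, r_max = 2)))
})

test_that("positive/negative combination is clipped to [0, 1]", {
  expect_equal(combine_pos_neg(0.3, 0.5, w = 1), 0)
  expect_equal(combine_pos_neg(0.8, 0.2, w = 1), 0.6)
  expect_equal(combine_pos_neg(0.8, NULL, w = 1), 0.8)
  expect_equal(combine_pos_neg(0.9, 0.1, w = 3), 0.6)
  expect_true(is.na(combine_pos_neg(NA_real_, 0.2)))
})

test_that("single-cell worked examples score as computed by hand", {
  m <- as_sparse(matrix(c(5, 3, 0, 0), 4, 1,
                        dimnames = list(paste0("g", 1:4), "c1")))
  p <- scoring_params(r_max = 10)
  expect_equal(unname(score_signatures(m, parse_signature("s", c("g1", "g2")), p)$scores[1, 1]), 1)
  # zeros' midrank 3.5; pos n=1 rank 1 -> 1; neg n=1 rank 3.5 -> 1 - 2.5/9;
  # combined = max(0, 1 - (1 - 2.5/9)) = 2.5/9
  expect_equal(unname(score_signatures(m, parse_signature("s", c("g1+", "g3-")), p)$scores[1, 1]),
               2.5 / 9)
})

test_that("scoring matches the naive dense oracle on random sparse fixtures", {
  set.seed(47)
  for (i in 1:30) {
    dense <- random_fixture(sample(20:80, 1), sample(3:30, 1),
                            sparsity = runif(1, 0.5, 0.95))
    r_max <- sample(5:40, 1)
    sig <- random_signature(rownames(dense), sample(2:6, 1), sample(0:4, 1))
    p <- scoring_params(r_max = r_max)
    got <- score_signatures(as_sparse(dense), sig, p)$scores[, 1]
    want <- oracle_scores(dense, sig, r_max)
    expect_equal(unname(got), want, tolerance = 1e-14)
  }
})

test_that("scores are identical for any chunk size and worker count", {
  set.seed(53)
  dense <- random_fixture(60, 37, sparsity = 0.8)
  sigs <- list(a = random_signature(rownames(dense), 4, 2, "a"),
               b = random_signature(rownames(dense), 3, 0, "b"))
  ref <- score_signatures(as_sparse(dense), sigs, scoring_params(r_max = 25, chunk_size = 37L))
  for (cs in c(1L, 7L, 64L)) {
    expect_identical(score_signatures(as_sparse(dense), sigs,
                                      scoring_params(r_max = 25, chunk_size = cs))$scores,
                     ref$scores)
  }
  expect_identical(score_signatures(as_sparse(dense), sigs,
                                    scoring_params(r_max = 25, chunk_size = 7L),
                                    workers = 2L)$scores,
                   ref$scores)
})

test_that("raising positive-set expression never lowers a cell's score", {
  set.seed(59)
  dense <- random_fixture(50, 10, sparsity = 0.7)
  sig <- random_signature(rownames(dense), 5, 0)
  p <- scoring_params(r_max = 20)
  base <- score_signatures(as_sparse(dense), sig, p)$scores
  for (j in 1:10) {
    boosted <- dense
    boosted[sig$positive, j] <- boosted[sig$positive, j] + sample(1:10, 1)
    after <- score_signatures(as_sparse(boosted), sig, p)$scores
    expect_true(after[j, 1] >= base[j, 1] - 1e-12)
  }
})

test_that("missing-gene policies degrade signatures as documented", {
  m <- as_sparse(matrix(c(5, 3, 1, 0), 4, 1,
                        dimnames = list(paste0("g", 1:4), "c1")))
  p_skip <- scoring_params(r_max = 10, missing = "skip")

  collect_warnings <- function(expr) {
    classes <- character(0)
    value <- withCallingHandlers(expr, warning = function(w) {
      classes <<- c(classes, class(w)[1]); invokeRestart("muffleWarning")
    })
    list(value = value, classes = classes)
  }

  # fully-missing signature under skip: undefined, never 0, with warning
  gone <- parse_signature("gone", c("x1", "x2"))
  res <- collect_warnings(score_signatures(m, gone, p_skip))
  expect_true("uscore_unscorable" %in% res$classes)
  tab <- res$value
  expect_true(is.na(tab$scores[1, 1]))

  # surviving positive set + fully-missing negative set: positive-only + warning
  part <- parse_signature("part", c("g1", "x9-"))
  res2 <- collect_warnings(score_signatures(m, part, p_skip))
  expect_true("uscore_missing_negative" %in% res2$classes)
  tab2 <- res2$value
  ponly <- suppressWarnings(score_signatures(m, parse_signature("ponly", "g1"), p_skip))
  expect_equal(tab2$scores[1, 1], ponly$scores[1, 1])

  # impute_zero == scoring with the missing gene appended as an all-zero row
  sig <- parse_signature("s", c("g1", "x1"))
  p_imp <- scoring_params(r_max = 10, missing = "impute_zero")
  got <- suppressWarnings(score_signatures(m, sig, p_imp))$scores[1, 1]
  aug <- rbind(as.matrix(m), matrix(0, 1, 1, dimnames = list("x1", "c1")))
  want <- score_signatures(as_sparse(aug), parse_signature("s", c("g1", "x1")),
                           scoring_params(r_max = 10))$scores[1, 1]
  expect_identical(got, want)

  # skip == scoring the signature with the missing gene removed
  got_skip <- suppressWarnings(score_signatures(m, sig, p_skip))$scores[1, 1]
  want_skip <- score_signatures(m, parse_signature("s", "g1"),
                                scoring_params(r_max = 10))$scores[1, 1]
  expect_identical(got_skip, want_skip)
})

test_that("legacy normalization never scores below the corrected form", {
  set.seed(61)
  for (i in 1:15) {
    dense <- random_fixture(40, 8, sparsity = runif(1, 0.5, 0.9))
    sig <- random_signature(rownames(dense), sample(2:6, 1), 0)
    r_max <- sample(8:30, 1)
    v2 <- score_signatures(as_sparse(dense), sig, scoring_params(r_max = r_max))$scores
    v1 <- score_signatures(as_sparse(dense), sig,
                           scoring_params(r_max = r_max, legacy_norm = TRUE))$scores
    ok <- !is.na(v1) & !is.na(v2)
    expect_true(all(v1[ok] >= v2[ok] - 1e-12))
  }
})

test_that("per-group aggregation averages defined scores only", {
  scores <- matrix(c(0.2, 0.4, NA, 0.6), 4, 1,
                   dimnames = list(paste0("c", 1:4), "sig"))
  tab <- structure(list(scores = scores, cell_ids = rownames(scores),
                        signature_names = "sig"), class = "score_table")

  agg <- aggregate_scores(tab, c(c1 = "g1", c2 = "g1", c3 = "g2", c4 = "g2"))
  expect_equal(agg$mean_score[agg$group == "g1"], 0.3)
  # one undefined + one 0.6: mean 0.6 over 1 of 2 cells
  expect_equal(agg$mean_score[agg$group == "g2"], 0.6)
  expect_equal(agg$n_defined[agg$group == "g2"], 1L)
  expect_equal(agg$n_cells[agg$group == "g2"], 2L)

  # singleton groups reproduce the cell scores
  solo <- aggregate_scores(tab, c(c1 = "a", c2 = "b", c3 = "c", c4 = "d"))
  expect_equal(solo$mean_score[solo$group == "a"], 0.2)
  expect_true(is.na(solo$mean_score[solo$group == "c"]))

  expect_error(aggregate_scores(tab, c(c1 = "a")), class = "uscore_input_error")
})

test_that("defined scores always lie in [0, 1] under fuzzing", {
  set.seed(67)
  for (i in 1:25) {
    dense <- random_fixture(sample(10:60, 1), sample(2:20, 1),
                            sparsity = runif(1, 0.3, 0.97))
    sig <- random_signature(rownames(dense), sample(1:5, 1), sample(0:5, 1))
    r_max <- sample(2:50, 1)
    w <- runif(1, 0, 3)
    sc <- score_signatures(as_sparse(dense), sig,
                           scoring_params(r_max = r_max, neg_weight = w))$scores
    ok <- !is.na(sc)
    expect_true(all(sc[ok] >= 0 & sc[ok] <= 1))
  }
})
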