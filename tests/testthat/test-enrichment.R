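make_ranked <- function(correlations, ids = sprintf("g%d", seq_along(correlations)),
                        mirna_id = "mir-test") {
  structure(list(mirna_id = mirna_id, gene_ids = ids,
                 correlations = correlations), class = "ranked_genes")
}

test_that("spearman correlation equals Pearson on average ranks", {
  expect_equal(spearman_correlation(1:3, 1:3), 1.0)
  expect_equal(spearman_correlation(1:3, 3:1), -1.0)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_correlation(x, y),
               cor(c(1, 2.5, 2.5, 4), c(1, 3, 2, 4)))
  expect_error(spearman_correlation(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_correlation(1:4, 1:3), "equal length")
  expect_error(spearman_correlation(1:2, 2:1), "at least 3")
})

test_that("gene ranking sorts by correlation with deterministic tie-breaks", {
  m <- toy_matrix(c(1, 2, 3,   3, 2, 1,   1, 3, 2), 3, 3, byrow = TRUE)
  rownames(m) <- c("gUp", "gDown", "gMid")
  v <- c(1, 2, 3)
  rk <- rank_genes(m, v, "mir-1")
  expect_identical(rk$gene_ids[1], "gUp")
  expect_equal(rk$correlations[1], 1.0)
  expect_identical(rk$gene_ids[3], "gDown")
  expect_true(all(diff(rk$correlations) <= 0))

  # exact ties -> lexicographically smaller id first
  m2 <- rbind(b_gene = c(1, 2, 3, 4), a_gene = c(1, 2, 3, 4),
              z = c(4, 3, 2, 1))
  colnames(m2) <- paste0("s", 1:4)
  rk2 <- rank_genes(m2, 1:4)
  expect_identical(rk2$gene_ids[1:2], c("a_gene", "b_gene"))

  # constant rows get correlation 0 with a warning
  m3 <- rbind(flat = rep(5, 4), up = 1:4)
  colnames(m3) <- paste0("s", 1:4)
  expect_warning(rk3 <- rank_genes(m3, 1:4), "constant")
  expect_equal(rk3$correlations[rk3$gene_ids == "flat"], 0)

  expect_error(rank_genes(m, c(1, 2)), "number of samples")
})

test_that("running-sum profile reproduces the hand-computed walks", {
  rk <- make_ranked(c(0.9, 0.5, 0.4, 0.2, 0.1))
  p1 <- running_sum_profile(rk, c(g1 = 1, g3 = 1))
  expect_equal(p1, c(0.64, 0.38, 0.52, 0.26, 0.0), tolerance = 1e-12)
  sc1 <- enrichment_score(p1)
  expect_equal(sc1$es, 0.64, tolerance = 1e-12)
  expect_identical(sc1$argmax_index, 1L)

  p2 <- running_sum_profile(rk, c(g4 = 1, g5 = 1))
  expect_equal(p2, c(-0.06, -0.12, -0.18, -0.04, 0.0), tolerance = 1e-12)
  sc2 <- enrichment_score(p2)
  expect_equal(sc2$es, -0.18, tolerance = 1e-12)
  expect_identical(sc2$argmax_index, 3L)

  # all-zero correlations -> all-zero profile, degenerate score
  rk0 <- make_ranked(rep(0, 4))
  p0 <- running_sum_profile(rk0, c(g2 = 0.5))
  expect_equal(p0, rep(0, 4))
  expect_identical(enrichment_score(p0), list(es = 0, argmax_index = 1L))

  expect_error(running_sum_profile(rk, numeric(0)), "empty target set")
  expect_error(running_sum_profile(rk, c(zz = 1)), "outside the ranked")
})

test_that("ES equals the brute-force prefix-sum oracle on random instances", {
  set.seed(61)
  for (i in 1:150) {
    inst <- random_instance()
    alpha <- sample(c(0.5, 1, 2), 1)
    prof <- running_sum_profile(inst$ranked, inst$tset, alpha)
    sc <- enrichment_score(prof)
    full_w <- numeric(inst$n)
    full_w[match(names(inst$tset), inst$ranked$gene_ids)] <- inst$tset
    oracle <- brute_force_walk(inst$ranked$correlations, full_w, alpha)
    expect_equal(sc$es, oracle$es, tolerance = 1e-12)
    expect_identical(sc$argmax_index, oracle$argmax_index)
    # zero-sum walk
    expect_lt(abs(prof[inst$n]), 1e-9)
  }
})

test_that("reversing the ranked list negates the enrichment score", {
  set.seed(62)
  for (i in 1:50) {
    inst <- random_instance()
    rev_ranked <- make_ranked(rev(inst$ranked$correlations),
                              rev(inst$ranked$gene_ids))
    prof <- running_sum_profile(inst$ranked, inst$tset)
    es_fwd <- enrichment_score(prof)$es
    es_rev <- enrichment_score(running_sum_profile(rev_ranked, inst$tset))$es
    if (abs(max(prof) + min(prof)) < 1e-12) {
      # exact two-sided tie: the earliest-position tie-break fixes the sign,
      # so only the magnitude is reversal-invariant
      expect_equal(abs(es_rev), abs(es_fwd), tolerance = 1e-9)
    } else {
      expect_equal(es_rev, -es_fwd, tolerance = 1e-9)
    }
  }
})

test_that("set-size baseline variant drifts negative as expected", {
  rk <- make_ranked(c(0.9, 0.5, 0.4, 0.2, 0.1))
  prof <- running_sum_profile(rk, c(g1 = 1, g3 = 1), baseline = "set_size")
  # b = (0.9 + 0.4)/2 = 0.65; walk ends at total - N*b
  expect_equal(prof[5], (0.9 + 0.4) - 5 * 0.65, tolerance = 1e-12)
})

test_that("permutation null is reproducible, seed-isolated and leaves the RNG alone", {
  inst <- local({ set.seed(63); random_instance(20, 5) })
  n1 <- permutation_null(inst$ranked, inst$tset, n_perm = 25, seed = 7)
  n2 <- permutation_null(inst$ranked, inst$tset, n_perm = 25, seed = 7)
  expect_identical(n1, n2)
  expect_length(n1, 25L)
  n3 <- permutation_null(inst$ranked, inst$tset, n_perm = 25, seed = 8)
  expect_false(identical(n1, n3))

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(permutation_null(inst$ranked, inst$tset,
                                            n_perm = 5, seed = 7))
  expect_identical(rnorm(1), before)

  rk0 <- make_ranked(rep(0, 6))
  expect_equal(permutation_null(rk0, c(g3 = 1), n_perm = 10, seed = 1),
               rep(0, 10))
})

test_that("permuted scores agree with full-profile scores on shuffled lists", {
  set.seed(64)
  for (i in 1:25) {
    inst <- random_instance(25, 6)
    perm <- sample(inst$n)
    shuffled_ids <- inst$ranked$gene_ids[perm]
    es_sparse <- mirTRS:::.es_sparse(match(names(inst$tset), shuffled_ids),
                                     unname(inst$tset),
                                     abs(inst$ranked$correlations),
                                     inst$n, inst$n)
    shuffled <- make_ranked(inst$ranked$correlations, shuffled_ids)
    es_full <- enrichment_score(running_sum_profile(shuffled, inst$tset))$es
    expect_equal(es_sparse, es_full, tolerance = 1e-12)
  }
})

test_that("empirical p-values follow both denominator conventions", {
  expect_equal(empirical_pvalue(1.5, c(-1, 0, 1, 2), denominator = "all"),
               0.25)
  expect_equal(empirical_pvalue(-2, c(-3, -1, 0, 2), denominator = "all"),
               0.25)
  expect_equal(empirical_pvalue(10, c(-1, 0, 1, 2), denominator = "all"), 0)
  expect_equal(empirical_pvalue(0, c(-1, 1)), 1)
  # signed: tail count over same-signed null values
  expect_equal(empirical_pvalue(1.5, c(-1, 0, 1, 2), denominator = "signed"),
               0.5)
  expect_equal(empirical_pvalue(-2, c(-3, -1, 0, 2), denominator = "signed"),
               0.5)
  # smoothing keeps p away from zero
  expect_equal(empirical_pvalue(10, c(-1, 0, 1, 2), denominator = "all",
                                smooth = TRUE), 1 / 5)
  expect_error(empirical_pvalue(1, numeric(0)), "empty")
})

test_that("BH adjustment matches the textbook step-up on random inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0, 5)), rep(0, 5))
  set.seed(65)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), textbook_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("full analysis returns a coherent, deterministic result table", {
  set.seed(66)
  d <- generate_planted_dataset(simulation_config(
    n_genes = 120, n_mirnas = 6, n_samples = 30, targets_per_mirna = 20,
    n_planted_regulators = 2, seed = 9))
  res <- run_mirna_analysis(d$mrna, d$mirna, d$sets, n_perm = 100, seed = 3)
  expect_identical(nrow(res), 6L)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(!is.unsorted(rev(res$es)))
  for (i in seq_len(nrow(res)))
    expect_true(all(res$leading_edge[[i]] %in%
                      names(d$sets[[res$mirna_id[i]]])))
  # identical master seed -> identical table; set order is irrelevant
  res2 <- run_mirna_analysis(d$mrna, d$mirna, d$sets[sample(6)],
                             n_perm = 100, seed = 3)
  expect_equal(res, res2, ignore_attr = TRUE)
  expect_identical(res$es, res2$es)
  expect_identical(res$p_value, res2$p_value)

  bad_mirna <- d$mirna[, rev(colnames(d$mirna))]
  expect_error(run_mirna_analysis(d$mrna, bad_mirna, d$sets),
               "identical ordered sample set")
  expect_error(run_mirna_analysis(d$mrna, d$mirna, list()), "empty|named")
})
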