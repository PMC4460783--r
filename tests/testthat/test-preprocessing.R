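test_that("asinh + quantile normalization matches the order-statistic-mean oracle", {
  set.seed(21)
  m <- toy_matrix(runif(12, 0.1, 100), 4, 3)
  out <- asinh_quantile_normalize(m)
  expect_identical(dimnames(out), dimnames(m))
  # oracle: per-rank means of the asinh-transformed sorted columns
  a <- asinh(m)
  ref <- rowMeans(apply(a, 2, sort))
  for (j in seq_len(ncol(out)))
    expect_equal(sort(out[, j]), ref, tolerance = 1e-12,
                 ignore_attr = TRUE)

  zeros <- toy_matrix(0, 3, 3)
  expect_equal(asinh_quantile_normalize(zeros), zeros, tolerance = 1e-15)

  perm <- cbind(s1 = c(3, 1, 2, 5), s2 = c(1, 2, 5, 3))
  rownames(perm) <- paste0("g", 1:4)
  qp <- asinh_quantile_normalize(perm)
  expect_equal(sort(qp[, 1]), sort(qp[, 2]), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(asinh_quantile_normalize(toy_matrix(1:3, 3, 1)),
               "at least 2 samples")
})

test_that("low-signal filters follow the stated boundary rules literally", {
  # negative in exactly 19 of 20 samples (0.95 >= 0.95): dropped
  neg <- toy_matrix(c(rep(-1, 19), 1, rep(1, 20)), 2, 20, byrow = TRUE)
  f <- filter_low_signal_features(neg, "negative_in_frac", fraction = 0.95)
  expect_identical(rownames(f), "g2")
  # negative in 18 of 20 (0.90 < 0.95): kept
  neg2 <- neg
  neg2["g1", 19] <- 1
  expect_identical(nrow(filter_low_signal_features(neg2, "negative_in_frac",
                                                   fraction = 0.95)), 2L)

  # reads > 10 in exactly 10% of samples: kept; reads == 10 never count
  reads <- toy_matrix(c(c(11, rep(0, 9)), rep(10, 10)), 2, 10, byrow = TRUE,
                      feature_prefix = "f")
  k <- filter_low_signal_features(reads, "min_reads_in_frac",
                                  threshold = 10, fraction = 0.10)
  expect_identical(rownames(k), "f1")

  pos <- toy_matrix(abs(rnorm(20)) + 1, 4, 5)
  expect_identical(filter_low_signal_features(pos, "negative_in_frac",
                                              fraction = 0.95), pos)
  expect_error(filter_low_signal_features(pos, "negative_in_frac",
                                          fraction = 0), "\\(0, 1\\]")
})

test_that("filtering is idempotent and output features are a subset", {
  set.seed(31)
  m <- toy_matrix(rnorm(200), 20, 10)
  once <- filter_low_signal_features(m, "negative_in_frac", fraction = 0.5)
  twice <- filter_low_signal_features(once, "negative_in_frac",
                                      fraction = 0.5)
  expect_identical(once, twice)
  expect_true(all(rownames(once) %in% rownames(m)))
})

test_that("technical replicates average per feature and singletons pass through", {
  m <- toy_matrix(c(2, 10, 4, 20, 7, 30), 2, 3)
  ann <- data.frame(sample_id = c("s1", "s2", "s3"),
                    replicate_group = c("r1", "r1", "r2"))
  out <- average_technical_replicates(m, ann)
  expect_identical(colnames(out), c("r1", "r2"))
  expect_equal(out[, "r1"], c(g1 = 3, g2 = 15))
  expect_equal(out[, "r2"], c(g1 = 7, g2 = 30))

  # identical replicate columns collapse to the same column
  dup <- toy_matrix(c(1, 2, 1, 2), 2, 2)
  anndup <- data.frame(sample_id = c("s1", "s2"),
                       replicate_group = c("r", "r"))
  expect_equal(average_technical_replicates(dup, anndup)[, "r"],
               c(g1 = 1, g2 = 2))

  solo <- data.frame(sample_id = c("s1", "s2", "s3"),
                     replicate_group = c("a", "b", "c"))
  out2 <- average_technical_replicates(m, solo)
  expect_equal(unname(out2), unname(m))

  expect_error(average_technical_replicates(m, ann[1:2, ]),
               "missing from annotation")
})

test_that("batch correction equalizes batch means, preserves grand means, and matches lm", {
  set.seed(41)
  m <- toy_matrix(rnorm(80), 10, 8)
  ann <- data.frame(sample_id = colnames(m),
                    batch = rep(c("A", "B"), each = 4))
  shifted <- m
  shifted[, 5:8] <- shifted[, 5:8] + 5
  out <- remove_batch_effect(shifted, ann)
  for (i in seq_len(nrow(out))) {
    expect_lt(abs(mean(out[i, 1:4]) - mean(out[i, 5:8])), 1e-9)
    expect_lt(abs(mean(out[i, ]) - mean(shifted[i, ])), 1e-9)
  }

  # identical batches: nothing to remove
  same <- cbind(m[, 1:4], m[, 1:4])
  colnames(same) <- paste0("s", 1:8)
  expect_equal(remove_batch_effect(same, ann), same, tolerance = 1e-9)

  # independent least-squares oracle per feature
  batch <- factor(ann$batch)
  for (i in sample(nrow(m), 3)) {
    fit <- lm(shifted[i, ] ~ batch)
    # subtracting the fitted batch deviations leaves residuals + grand mean
    oracle <- residuals(fit) + mean(shifted[i, ])
    expect_equal(unname(out[i, ]), unname(oracle), tolerance = 1e-9)
  }

  single <- data.frame(sample_id = colnames(m),
                       batch = c(rep("A", 7), "B"))
  expect_error(remove_batch_effect(shifted, single), "single sample")
  one <- data.frame(sample_id = colnames(m), batch = "A")
  expect_error(remove_batch_effect(shifted, one), "at least 2 batches")
})
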