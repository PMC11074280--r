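test_that("KNN batch probabilities: separated clusters are one-hot", {
  set.seed(1)
  emb <- rbind(matrix(rnorm(25 * 3), 25), matrix(rnorm(25 * 3) + 1000, 25))
  labs <- rep(c("b1", "b2"), each = 25)
  bp <- knn_batch_probabilities(emb, labs, k = 20)
  expect_equal(bp$batch_order, c("b1", "b2"))
  expect_true(all(bp$probs[1:25, "b1"] == 1))
  expect_true(all(bp$probs[26:50, "b2"] == 1))
  expect_equal(unname(rowSums(bp$probs)), rep(1, 50), tolerance = 1e-9)
  expect_equal(normalized_batch_entropy(bp), 1)
})

test_that("KNN batch probabilities under the null are near 1/2", {
  set.seed(7)
  emb <- matrix(rnorm(500 * 5), 500)
  labs <- sample(rep(c("b1", "b2"), each = 250))
  bp <- knn_batch_probabilities(emb, labs, k = 20)
  own <- bp$probs[cbind(seq_len(500), match(labs, bp$batch_order))]
  expect_lt(abs(mean(own) - 0.5), 0.1)
  # leave-self-out removes the self-neighbour bias
  bp2 <- knn_batch_probabilities(emb, labs, k = 20, include_self = FALSE)
  own2 <- bp2$probs[cbind(seq_len(500), match(labs, bp2$batch_order))]
  expect_lt(mean(own2), mean(own))
})

test_that("KNN preconditions", {
  emb <- matrix(rnorm(10 * 2), 10)
  expect_error(knn_batch_probabilities(emb, rep("b1", 10), k = 20), "samples")
  bp1 <- knn_batch_probabilities(emb, rep("b1", 10), k = 5)
  expect_error(normalized_batch_entropy(bp1), "K >= 2")
})

test_that("batch entropy closed forms", {
  expect_equal(batch_entropy(rep(0.25, 4)), log(4))
  expect_equal(batch_entropy(c(1, 0, 0)), 0)
  # direct evaluation: -0.75 ln 0.75 - 0.25 ln 0.25
  expect_equal(batch_entropy(c(0.75, 0.25)),
               -0.75 * log(0.75) - 0.25 * log(0.25))
  expect_equal(batch_entropy(c(0.75, 0.25)), 0.5623, tolerance = 1e-4)
  expect_error(batch_entropy(c(-0.1, 1.1)), "non-negative")
})

test_that("nBE bounds and intermediate value", {
  uni <- matrix(1 / 4, 40, 4)
  expect_equal(normalized_batch_entropy(uni), 0)
  oh <- matrix(0, 40, 4); oh[cbind(1:40, rep(1:4, 10))] <- 1
  expect_equal(normalized_batch_entropy(oh), 1)
  p <- matrix(rep(c(0.75, 0.25), each = 10), 10, 2)
  be <- -0.75 * log(0.75) - 0.25 * log(0.25)
  expect_equal(normalized_batch_entropy(p), (log(2) - be) / log(2))
  expect_equal(normalized_batch_entropy(p), 0.18872, tolerance = 1e-4)
})

test_that("nBE stays in [0,1] for random probability matrices", {
  set.seed(11)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    raw <- matrix(rexp(30 * K), 30)
    probs <- raw / rowSums(raw)
    v <- normalized_batch_entropy(probs)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("ARI closed forms and invariances", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3)), 1)
  expect_equal(adjusted_rand_index(c(0, 1, 0, 1), c(0, 0, 1, 1)), -0.5)
  set.seed(2)
  a <- sample(1:3, 12, replace = TRUE)
  b <- sample(1:3, 12, replace = TRUE)
  perm <- c("x", "y", "z")[a]
  expect_equal(adjusted_rand_index(perm, b), adjusted_rand_index(a, b))
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("AMI closed forms and invariances", {
  expect_equal(adjusted_mutual_information(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  expect_equal(adjusted_mutual_information(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0)
  set.seed(3)
  a <- sample(1:3, 10, replace = TRUE)
  b <- sample(1:2, 10, replace = TRUE)
  expect_equal(adjusted_mutual_information(c("p", "q", "r")[a], b),
               adjusted_mutual_information(a, b))
  expect_equal(adjusted_mutual_information(a, b),
               adjusted_mutual_information(b, a))
})

test_that("ARI and AMI match the brute-force oracle", {
  # exhaustive over all partition pairs of n <= 5 items into <= 3 clusters
  for (n in 2:5) {
    parts <- rgs_partitions(n, 3)
    for (p1 in parts) for (p2 in parts) {
      expect_equal(adjusted_rand_index(p1, p2), ari_oracle(p1, p2),
                   tolerance = 1e-10)
      expect_equal(adjusted_mutual_information(p1, p2), ami_oracle(p1, p2),
                   tolerance = 1e-10)
    }
  }
  # sampled pairs at n = 6..8
  set.seed(4)
  for (i in 1:400) {
    n <- sample(6:8, 1)
    p1 <- sample(1:3, n, replace = TRUE)
    p2 <- sample(1:3, n, replace = TRUE)
    expect_equal(adjusted_rand_index(p1, p2), ari_oracle(p1, p2),
                 tolerance = 1e-10)
    expect_equal(adjusted_mutual_information(p1, p2), ami_oracle(p1, p2),
                 tolerance = 1e-10)
  }
})

test_that("KNN batch predictions on i.i.d. data give ARI and AMI near 0", {
  set.seed(5)
  emb <- matrix(rnorm(400 * 8), 400)
  labs <- sample(rep(paste0("b", 1:4), each = 100))
  bp <- knn_batch_probabilities(emb, labs, k = 20)
  pred <- bp$batch_order[max.col(bp$probs, ties.method = "first")]
  expect_lt(abs(adjusted_rand_index(pred, labs)), 0.05)
  expect_lt(abs(adjusted_mutual_information(pred, labs)), 0.05)
})

test_that("MCC closed forms and degenerate convention", {
  expect_equal(mcc(c(1, 2, 1, 2), c(1, 2, 1, 2)), 1)
  expect_message(v <- mcc(rep("pos", 10), rep(c("pos", "neg"), 5)),
                 "degenerate")
  expect_equal(v, 0)
  # TP=45 TN=35 FP=5 FN=15
  truth <- c(rep("p", 60), rep("n", 40))
  pred <- c(rep("p", 45), rep("n", 15), rep("p", 5), rep("n", 35))
  expected <- (45 * 35 - 5 * 15) /
    sqrt((45 + 5) * (45 + 15) * (35 + 5) * (35 + 15))
  expect_equal(mcc(pred, truth), expected)
  expect_equal(mcc(pred, truth), 0.6124, tolerance = 1e-4)
})

test_that("binary MCC equals the Pearson correlation of 0/1 encodings", {
  set.seed(6)
  for (i in 1:100) {
    cm <- 1 + rmultinom(1, 40, rep(0.25, 4))  # TP, FN, FP, TN, all >= 1
    truth <- rep(c(1, 1, 0, 0), cm)
    pred <- rep(c(1, 0, 1, 0), cm)
    expect_equal(mcc(pred, truth), cor(pred, truth), tolerance = 1e-12)
  }
})

test_that("multiclass MCC behaves as a generalized correlation", {
  set.seed(8)
  truth <- sample(1:4, 60, replace = TRUE)
  expect_equal(mcc(truth, truth), 1)
  v <- mcc(sample(truth), truth)
  expect_gte(v, -1); expect_lte(v, 1)
})

test_that("qc_apcc closed forms", {
  prof <- c(1, 2, 3)
  m <- omics_matrix(rbind(prof, prof, c(5, 5, 5)),
                    sample_ids = c("q1", "q2", "s1"),
                    batch_labels = c("b1", "b2", "b1"),
                    class_labels = c("QC", "QC", "A"),
                    qc_flags = c(TRUE, TRUE, FALSE))
  expect_equal(qc_apcc(m), 1)

  m2 <- m; m2$values[2, ] <- c(3, 2, 1)
  expect_equal(qc_apcc(m2), -1)

  # three QCs with pairwise correlations {1, 0.5, 0.5} -> mean 2/3
  z1 <- c(-1, 0, 1) / sqrt(2)
  z2 <- c(1, -2, 1) / sqrt(6)
  v3 <- 0.5 * z1 + sqrt(0.75) * z2
  m3 <- omics_matrix(rbind(z1, z1, v3, c(0, 1, 2)) + 10,
                     sample_ids = paste0("s", 1:4),
                     batch_labels = rep("b1", 4),
                     class_labels = c("QC", "QC", "QC", "A"),
                     qc_flags = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(qc_apcc(m3), (1 + 0.5 + 0.5) / 3, tolerance = 1e-12)

  # fewer than 2 QC samples: absent, not an error
  m4 <- m; m4$qc_flags <- c(TRUE, FALSE, FALSE)
  expect_true(is.na(qc_apcc(m4)))
  # constant QC profile excluded with warning
  m5 <- m; m5$values[1, ] <- 4
  expect_warning(expect_true(is.na(qc_apcc(m5))), "constant")
})

test_that("qc_nmed closed forms", {
  # QCs identical -> 0
  qc <- rbind(c(1, 1), c(1, 1), c(1, 1))
  non <- rbind(c(0, 0), c(4, 0), c(2, 2 * sqrt(3)))
  m <- omics_matrix(rbind(qc, non),
                    sample_ids = paste0("s", 1:6),
                    batch_labels = rep("b1", 6),
                    class_labels = c("QC", "QC", "QC", "A", "A", "A"),
                    qc_flags = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(qc_nmed(m), 0)

  # QC mutual distance 2, non-QC median distance 4 -> 0.5
  qc2 <- rbind(c(10, 10), c(12, 10), c(11, 10 + sqrt(3)))
  m2 <- m; m2$values <- rbind(qc2, non)
  expect_equal(qc_nmed(m2), 0.5, tolerance = 1e-12)

  # ratio 1 when QC distances equal the non-QC median
  m3 <- m; m3$values <- rbind(non, non)
  expect_equal(qc_nmed(m3), 1, tolerance = 1e-12)

  # degenerate non-QC geometry is an error
  m4 <- m; m4$values[4:6, ] <- 1
  expect_error(qc_nmed(m4), "degenerate")
})

test_that("evaluate_representation assembles the full panel", {
  set.seed(9)
  m <- quick_sim(seed = 20, batch_additive_sd = 0,
                 batch_multiplicative_sd = 0, n_batches = 6,
                 samples_per_batch = 40, n_features = 30)
  pre <- preprocess(m)
  rep0 <- evaluate_representation(pre$values, m, label_pred = m$class_labels)
  expect_s3_class(rep0, "evaluation_report")
  expect_lt(rep0$nbe, 0.15)           # no batch effect: near-perfect mixing
  expect_equal(rep0$mcc, 1)           # predictions = truth
  expect_true(is.na(rep0$qc_apcc))    # no QC samples

  m2 <- quick_sim(seed = 21, batch_additive_sd = 3, n_batches = 6,
                  samples_per_batch = 40, n_features = 30)
  pre2 <- preprocess(m2)
  rep2 <- evaluate_representation(pre2$values, m2)
  expect_gt(rep2$nbe, 0.9)            # overwhelming additive shift
  expect_true(is.na(rep2$mcc))
})
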