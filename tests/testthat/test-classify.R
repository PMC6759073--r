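test_that("PCA is deterministic, centred and sign-fixed", {
  set.seed(3)
  m <- matrix(rnorm(200), 20, 10)
  p1 <- fit_pca(m)
  p2 <- fit_pca(m)
  expect_identical(p1$loadings, p2$loadings)
  # orthonormal loadings
  expect_equal(unname(crossprod(p1$loadings)), diag(10),
               tolerance = 1e-10)
  # sign convention: largest-|loading| entry positive
  for (j in 1:10) {
    v <- p1$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # explained variance non-increasing and sums to 1
  expect_true(all(diff(p1$explained_variance) <= 1e-12))
  expect_equal(sum(p1$explained_variance), 1)
  # projecting the training matrix reproduces stored scores
  expect_equal(project_pca(p1, m, k = 10), p1$scores, tolerance = 1e-10)
  # duplicated rows get identical scores
  p3 <- fit_pca(rbind(m, m[1, , drop = FALSE]))
  expect_equal(p3$scores[21, ], p3$scores[1, ], tolerance = 1e-10)
  expect_error(fit_pca(matrix(1, 5, 3)), "no variance")
})

test_that("full-rank reconstruction recovers the centred matrix", {
  set.seed(4)
  m <- matrix(rnorm(150), 15, 10)
  p <- fit_pca(m)
  centred <- sweep(m, 2, p$center)
  rec <- project_pca(p, m, k = 10) %*% t(p$loadings)
  expect_lt(max(abs(rec - centred)), 1e-8)
  # rank-1 data: first component carries ~ all variance
  r1 <- outer(rnorm(12), rnorm(6))
  pr <- fit_pca(r1 + matrix(rnorm(72, sd = 1e-6), 12, 6))
  expect_gt(pr$explained_variance[1], 0.999)
})

test_that("scree rule matches brute-force second differences", {
  brute <- function(ev) {
    acc <- vapply(2:(length(ev) - 1), function(k)
      ev[k - 1] - 2 * ev[k] + ev[k + 1], 0)
    (2:(length(ev) - 1))[which.max(acc)] - 1L
  }
  profiles <- list(c(0.9, 0.05, 0.03, 0.02),
                   c(0.4, 0.3, 0.2, 0.05, 0.05),
                   c(0.5, 0.2, 0.15, 0.1, 0.05),
                   c(0.6, 0.25, 0.1, 0.03, 0.02))
  for (ev in profiles) {
    expect_equal(scree_retain(ev), max(1L, brute(ev)))
  }
  expect_equal(scree_retain(c(0.9, 0.05, 0.03, 0.02)), 1L)
  expect_equal(scree_retain(c(0.4, 0.3, 0.2, 0.05, 0.05)), 3L)
  expect_warning(k <- scree_retain(rep(0.2, 5)), "no elbow")
  expect_equal(k, 1L)
  expect_equal(scree_retain(c(0.6, 0.4)), 1L)
})

test_that("separable clouds are classified perfectly; labels recovered", {
  set.seed(5)
  scores <- rbind(matrix(rnorm(60, mean = 0), 30, 2),
                  matrix(rnorm(60, mean = 8), 30, 2))
  labels <- rep(c("A", "B"), each = 30)
  model <- train_classifier(scores, labels, seed = 1)
  expect_gt(model$cv_accuracy_mean, 0.99)
  pred <- predict(model, scores, projected = TRUE)
  expect_equal(as.character(pred$labels), labels)
  expect_equal(unname(rowSums(pred$probabilities)), rep(1, 60),
               tolerance = 1e-9)
  expect_error(train_classifier(scores, rep("A", 60), seed = 1),
               "2 classes")
})

test_that("shuffled labels give chance-level accuracy", {
  set.seed(6)
  scores <- rbind(matrix(rnorm(80, mean = 0), 40, 2),
                  matrix(rnorm(80, mean = 8), 40, 2))
  accs <- vapply(1:5, function(r) {
    labels <- sample(rep(c("A", "B"), each = 40))
    train_classifier(scores, labels, seed = r,
                     cost_grid = 1, gamma_grid = 0.1)$cv_accuracy_mean
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("prediction applies training loadings to held-out vectors", {
  spec3 <- default_domain_specs(2, seed = 31, n_genes = 40)
  corp <- suppressWarnings(generate_corpus(spec3))
  rm <- rscu_matrix(codon_count_matrix(
    codonbias:::corpus_sequences(corp$collections)))
  dom <- domains_per_sequence(corp$collections)[rownames(rm$values)]
  part <- split_train_test(corp$collections, 0.5, seed = 31)
  model <- train_domain_classifier(rm$values[part$train, ],
                                   dom[part$train], seed = 31)
  pred <- predict(model, rm$values[part$test, ])
  expect_equal(unname(rowSums(pred$probabilities)),
               rep(1, length(part$test)), tolerance = 1e-9)
  expect_identical(colnames(pred$probabilities),
                   sort(colnames(pred$probabilities)))
  # projection consistency: training vectors re-predicted from raw RSCU
  # agree with prediction from stored scores
  pr_raw <- predict(model, rm$values[part$train, ])
  pr_scores <- predict(model, project_pca(model$pca,
                                          rm$values[part$train, ]),
                       projected = TRUE)
  expect_identical(pr_raw$labels, pr_scores$labels)
  expect_error(predict(model, rm$values[, 1:10]), "dimension mismatch")
})

test_that("evaluation reports accuracy, per-class AUC and length bins", {
  spec3 <- default_domain_specs(2, seed = 32, n_genes = 40)
  corp <- suppressWarnings(generate_corpus(spec3))
  seqs <- codonbias:::corpus_sequences(corp$collections)
  rm <- rscu_matrix(codon_count_matrix(seqs))
  dom <- domains_per_sequence(corp$collections)[rownames(rm$values)]
  part <- split_train_test(corp$collections, 0.3, seed = 32)
  model <- train_domain_classifier(rm$values[part$train, ],
                                   dom[part$train], seed = 32)
  ev <- evaluate_classifier(model, rm$values[part$test, ], dom[part$test],
                            lengths_nt = nchar(seqs[part$test]))
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_equal(sum(ev$confusion), length(part$test))
  expect_equal(as.numeric(rowSums(ev$confusion)),
               as.numeric(table(factor(dom[part$test],
                                       levels = model$classes))))
  expect_s3_class(ev$length_accuracy, "data.frame")
  # label-independent probabilities give AUC ~ 0.5
  set.seed(33)
  fake_labels <- sample(dom[part$test])
  ev2 <- evaluate_classifier(model, rm$values[part$test, ], fake_labels)
  expect_lt(abs(mean(ev2$auc) - 0.5), 0.12)
})
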