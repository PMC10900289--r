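test_that("Youden threshold maximizes J with ties broken toward the larger cut", {
  # perfectly separated: J = 1 at the smallest positive score
  expect_equal(youden_threshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 0.8)
  # hand-enumerated: max J = 2/3 at cuts 0.4 and 0.6; tie goes to 0.6
  expect_equal(youden_threshold(c(0.9, 0.6, 0.4, 0.5, 0.3, 0.1),
                                c(1, 1, 1, 0, 0, 0)), 0.6)
  expect_warning(th <- youden_threshold(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)),
                 "constant")
  expect_equal(th, 0.5)
  expect_error(youden_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("Youden threshold equals the exhaustive scan on random fixtures", {
  set.seed(9)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties sometimes
    expect_equal(youden_threshold(scores, labels), youden_brute(scores, labels))
  }
})

test_that("evaluation metrics cover the closed-form corner cases", {
  # perfect predictions
  ev <- evaluate_predictions(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0), 0.5)
  for (m in c("balanced_accuracy", "sensitivity", "specificity", "f1", "mcc",
              "auc_roc", "auc_pr")) {
    expect_equal(ev[[m]], 1.0)
  }
  # constant classifier: AUCPR = prevalence, AUC-ROC = 0.5
  ev2 <- evaluate_predictions(rep(0.5, 90), c(rep(1, 65), rep(0, 25)), 0.5)
  expect_equal(ev2$auc_pr, 65 / 90)
  expect_equal(ev2$auc_roc, 0.5)
  # all-positive predictions at threshold 0
  ev3 <- evaluate_predictions(runif(40), c(rep(1, 20), rep(0, 20)), 0)
  expect_equal(ev3$sensitivity, 1)
  expect_equal(ev3$specificity, 0)
  expect_equal(ev3$balanced_accuracy, 0.5)
  # single-class labels: AUCs NA, thresholded metrics still computed
  ev4 <- evaluate_predictions(c(0.9, 0.2), c(1, 1), 0.5)
  expect_true(is.na(ev4$auc_roc) && is.na(ev4$auc_pr))
  expect_equal(ev4$sensitivity, 0.5)
})

test_that("AUC metrics agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    y <- c(0, 1, rbinom(48, 1, 0.6))
    s <- runif(50)
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))))
    expect_equal(evaluate_predictions(s, y, 0.5)$auc_roc, ref, tolerance = 1e-10)
  }
})

test_that("threshold rescaling maps the operating point to 0.5", {
  expect_equal(threshold_rescale(0.4, 0.4), 0.5)
  expect_equal(threshold_rescale(0, 0.3), 0)
  expect_equal(threshold_rescale(1, 0.3), 1)
  # hand-evaluated ensemble example: (t=0.4, p=0.8) and (t=0.6, p=0.3)
  s1 <- threshold_rescale(0.8, 0.4)
  s2 <- threshold_rescale(0.3, 0.6)
  expect_equal(s1, 0.5 + 0.5 * (0.4 / 0.6))
  expect_equal(s2, 0.25)
  expect_equal(mean(c(s1, s2)), 0.5417, tolerance = 1e-4)
  expect_true(mean(c(s1, s2)) >= 0.5)   # predicted toxic
})

test_that("cross-validated training separates signal, is deterministic, and guards leakage", {
  set.seed(0)
  n <- 300L
  y <- rbinom(n, 1, 0.5)
  x <- cbind(signal = y * 2 + rnorm(n, sd = 0.3),
             matrix(rnorm(n * 20), n, dimnames = list(NULL, paste0("f", 1:20))))
  rownames(x) <- paste0("k", 1:n)
  lab <- data.frame(key = rownames(x), label = y)
  m <- cv_train(x, lab, seed = 0L)
  ev <- evaluate_predictions(m$oof_scores, m$oof_labels, m$threshold)
  expect_gt(ev$auc_roc, 0.95)
  expect_true(m$threshold > 0 && m$threshold < 1)
  # determinism: same seed, same everything
  m2 <- cv_train(x, lab, seed = 0L)
  expect_identical(m$hyperparameters, m2$hyperparameters)
  expect_equal(m$oof_scores, m2$oof_scores)
  expect_equal(m$threshold, m2$threshold)
  # single-class and undersized inputs error
  expect_error(cv_train(x, transform(lab, label = 1L), seed = 1L), "single class")
  expect_error(cv_train(x[1:12, ], lab[1:12, ], seed = 1L), "per class")
})

test_that("oversampling duplicates only the minority inside the training side", {
  set.seed(5)
  y <- c(rep(1L, 30), rep(0L, 10))
  idx <- dictox:::oversample_indices(y)
  expect_identical(sum(y[idx] == 1L), sum(y[idx] == 0L))  # balanced
  expect_true(all(seq_along(y) %in% idx))                 # originals kept
  extra <- idx[-seq_along(y)]
  expect_true(all(y[extra] == 0L))                        # only minority duplicated
  # fold assignment partitions all compounds, stratified
  fold <- dictox:::stratified_folds(y, 5L)
  expect_true(all(fold %in% 1:5))
  expect_true(all(table(fold, y) >= 1))
})

test_that("permuted labels yield chance-level out-of-fold AUC", {
  set.seed(1)
  n <- 300L
  x <- matrix(rnorm(n * 15), n, dimnames = list(paste0("k", 1:n), paste0("f", 1:15)))
  aucs <- sapply(1:10, function(s) {
    y <- sample(rep(c(0L, 1L), each = n / 2))
    m <- cv_train(x, data.frame(key = rownames(x), label = y),
                  seed = s, n_candidates = 4L)
    auc <- evaluate_predictions(m$oof_scores, m$oof_labels, 0.5)$auc_roc
    auc
  })
  # out-of-fold CV AUC under the null is centred on 0.5 but noisier than a
  # single-split AUC (fold-level overfitting adds variance in both tails),
  # so assert a tight bound on the mean and a loose one per seed
  expect_gt(mean(aucs), 0.45)
  expect_lt(mean(aucs), 0.55)
  expect_true(all(aucs > 0.35 & aucs < 0.65))
})

test_that("ensembles reduce to their members in the degenerate cases", {
  set.seed(4)
  n <- 80L
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(s = y + rnorm(n, sd = 0.5),
             matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("f", 1:5))))
  rownames(x) <- paste0("k", 1:n)
  attr(x, "space_tag") <- "physchem"
  lab <- data.frame(key = rownames(x), label = y)
  m <- cv_train(x, lab, seed = 4L, n_candidates = 4L)
  feats <- list(physchem = x)
  single <- ensemble_predict(list(m), feats, rownames(x))
  direct <- as.integer(dictox:::model_scores(m, x) >= m$threshold)
  expect_identical(single$label, direct)
  # k copies of one model reproduce that model for any k
  triple <- ensemble_predict(list(m, m, m), feats, rownames(x))
  expect_identical(triple$label, single$label)
  expect_equal(triple$score, single$score)
  expect_error(ensemble_predict(list(m), list(), rownames(x)), "missing feature space")
})

test_that("applicability-domain bins match direct per-bin recomputation", {
  set.seed(6)
  n <- 60L
  y <- rep(c(0L, 1L), each = n / 2)
  bits <- lapply(1:n, function(i) sort(sample(1:64, 12)))
  names(bits) <- paste0("k", 1:n)
  fp <- make_fp(bits, nbits = 64L)
  # pad to the 2048-bit structure contract? not needed: ad_report takes any
  # binary matrix; model trains on the same features
  attr(fp, "space_tag") <- "structure"
  lab <- data.frame(key = rownames(fp), label = y)
  train_keys <- paste0("k", 1:40)
  test_keys <- paste0("k", 41:60)
  m <- cv_train(fp[train_keys, ], lab[1:40, ], seed = 6L, n_candidates = 2L)
  rep <- ad_report(test_keys, m, fp, lab)
  expect_equal(sum(rep$per_bin$n), length(test_keys))
  expect_equal(rep$bins, seq(0, 1, by = 0.2))
  # independent recomputation of similarities and bin metrics
  scores <- dictox:::model_scores(m, fp, test_keys)
  for (i in seq_along(test_keys)) {
    pool <- intersect(m$training_keys, lab$key[lab$label == y[40 + i]])
    sim_ref <- max(sapply(pool, function(k) tanimoto(fp[test_keys[i], ], fp[k, ])))
    expect_equal(unname(rep$similarity[test_keys[i]]), sim_ref)
  }
  b <- findInterval(rep$similarity, rep$bins, rightmost.closed = TRUE)
  for (bi in unique(b)) {
    sel <- b == bi
    ev <- evaluate_predictions(scores[sel], y[40 + which(sel)], m$threshold)
    expect_equal(rep$per_bin$balanced_accuracy[bi], ev$balanced_accuracy)
  }
  # identical compound in train and test lands in the top bin
  fp2 <- rbind(fp, dup = fp["k1", ])
  attr(fp2, "space_tag") <- "structure"
  lab2 <- rbind(lab, data.frame(key = "dup", label = y[1]))
  rep2 <- ad_report("dup", m, fp2, lab2)
  expect_equal(unname(rep2$similarity["dup"]), 1.0)
  expect_equal(rep2$per_bin$n[5], 1L)
})

test_that("unlabeled prediction emits bounded scores and flags training overlap", {
  set.seed(8)
  n <- 60L
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 8), n, dimnames = list(paste0("k", 1:n), paste0("f", 1:8)))
  m <- cv_train(x, data.frame(key = rownames(x), label = y), seed = 8L,
                n_candidates = 2L)
  new_x <- matrix(rnorm(16), 2, dimnames = list(c("n1", "n2"), paste0("f", 1:8)))
  out <- predict_unlabeled(m, new_x)
  expect_identical(out$key, c("n1", "n2"))
  expect_true(all(out$score >= 0 & out$score <= 1))
  expect_message(predict_unlabeled(m, x[1:2, ]), "overlap")
  empty <- predict_unlabeled(m, x[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
  expect_error(predict_unlabeled(m, new_x[, 1:3]), "schema")
})
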