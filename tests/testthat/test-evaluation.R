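test_that("one-vs-rest confusion counts match hand enumeration", {
  # truth (F,F,P,N), pred (F,P,P,N): for FALL TP=1, FN=1, FP=0, TN=2
  truth <- c(FALL, FALL, PRE_FALL, NON_FALL)
  pred <- c(FALL, PRE_FALL, PRE_FALL, NON_FALL)
  cc <- confusion_counts(pred, truth)
  expect_equal(unname(cc$tp[3]), 1L)
  expect_equal(unname(cc$fn[3]), 1L)
  expect_equal(unname(cc$fp[3]), 0L)
  expect_equal(unname(cc$tn[3]), 2L)
  # totals per class always sum to the number of evaluated blocks
  for (i in 1:3) {
    expect_equal(unname(cc$tp[i] + cc$fp[i] + cc$tn[i] + cc$fn[i]), 4L)
  }
  expect_equal(sum(cc$tp), sum(pred == truth))

  expect_error(confusion_counts(c(0L, 1L), c(0L, 1L, 2L)), "lengths differ")
  expect_error(confusion_counts(integer(0), integer(0)), "empty")
})

test_that("per-class metrics follow their defining formulas", {
  # 100 blocks: 10 true falls (8 detected), 1 false alarm among 90 others
  truth <- c(rep(FALL, 10), rep(NON_FALL, 90))
  pred <- c(rep(FALL, 8), rep(NON_FALL, 2), FALL, rep(NON_FALL, 89))
  m <- class_metrics(confusion_counts(pred, truth))
  fall_row <- m[m$class == "fall", ]
  expect_equal(fall_row$sensitivity, 0.80)
  expect_equal(fall_row$specificity, 89 / 90)
  expect_equal(fall_row$accuracy, 0.97)

  perfect <- class_metrics(confusion_counts(truth, truth))
  expect_true(all(perfect$accuracy == 1))
  expect_true(all(perfect$specificity == 1))
  # a class absent from both pred and truth has undefined (0/0) sensitivity
  expect_true(is.na(perfect$sensitivity[perfect$class == "pre_fall"]))
})

test_that("metrics match an independent brute-force oracle on random inputs", {
  set.seed(77)
  for (i in 1:300) {
    n <- sample(2:40, 1)
    truth <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    got <- class_metrics(confusion_counts(pred, truth))
    want <- brute_force_metrics(pred, truth)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
})

test_that("ROC curves behave at the extremes and match the pairwise AUC oracle", {
  # perfect separation passes through (0, 1)
  truth <- c(rep(FALL, 5), rep(NON_FALL, 5))
  scores <- c(runif(5, 0.8, 1), runif(5, 0, 0.2))
  pts <- roc_points(scores, truth, FALL)
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))
  expect_equal(auc_trapezoid(pts), 1)

  # uninformative constant scores give the chance diagonal
  flat <- roc_points(rep(0.5, 10), truth, FALL)
  expect_equal(flat$fpr, c(0, 1))
  expect_equal(flat$tpr, c(0, 1))
  expect_equal(auc_trapezoid(flat), 0.5)

  # sweep AUC equals the fraction of correctly ordered (pos, neg) pairs
  set.seed(31)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    truth_i <- c(0L, 2L, sample(c(0L, 2L), n - 2, replace = TRUE))
    s <- round(runif(n), 2)   # duplicate scores exercise tie handling
    pts_i <- roc_points(s, truth_i, FALL)
    expect_equal(auc_trapezoid(pts_i), pairwise_auc(s, truth_i == FALL))
    expect_true(all(diff(pts_i$fpr) >= 0))
    expect_true(all(diff(pts_i$tpr) >= 0))
  }

  expect_error(roc_points(runif(4), rep(FALL, 4), FALL), "degenerate")
})

test_that("sweep AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(55)
  truth <- sample(c(0L, 2L), 60, replace = TRUE)
  truth[1:2] <- c(0L, 2L)
  s <- runif(60)
  ours <- auc_trapezoid(roc_points(s, truth, FALL))
  ref <- as.numeric(pROC::auc(pROC::roc(
    truth == FALL, s, quiet = TRUE, direction = "<",
    levels = c(FALSE, TRUE))))
  expect_equal(ours, ref)
})

test_that("evaluation reports are self-consistent across replicates", {
  set.seed(42)
  test_ds <- make_blocks(30, W = 8L, C = 3L,
                         labels = rep(0:2, each = 10), seed = 42)
  spec <- tiny_spec()
  m1 <- build_class_ensemble(spec)

  single <- evaluation_report(m1, test_ds)
  expect_equal(single$n_runs, 1L)
  expect_false("accuracy_sd" %in% names(single$metrics))

  # identical replicates have zero dispersion
  triple <- evaluation_report(list(m1, m1, m1), test_ds)
  expect_equal(triple$n_runs, 3L)
  expect_true(all(triple$metrics$accuracy_sd == 0))
  expect_true(all(triple$metrics$sensitivity_sd == 0, na.rm = TRUE))
  expect_equal(triple$metrics$accuracy_mean, single$metrics$accuracy_mean)

  # per-class accuracy is recomputable from the emitted confusion matrix
  cm <- single$confusion
  for (i in 1:3) {
    tp <- cm[i, i]
    acc <- (tp + sum(cm[-i, -i])) / sum(cm)
    expect_equal(single$metrics$accuracy_mean[i], acc)
  }

  # CSV outputs land in the requested directory
  out <- withr::local_tempdir()
  evaluation_report(m1, test_ds, out_dir = out)
  expect_true(file.exists(file.path(out, "metrics.csv")))
  expect_true(file.exists(file.path(out, "confusion.csv")))
})
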