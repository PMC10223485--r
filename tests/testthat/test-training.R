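test_that("subject-wise splits partition the data without leakage", {
  set.seed(13)
  n <- 130L
  subjects <- sample(sprintf("SA%02d", 1:8), n, replace = TRUE)
  subjects[1:10] <- sprintf("SE%02d", rep(1:2, 5))
  ds <- make_blocks(n, labels = sample(0:2, n, replace = TRUE,
                                       prob = c(0.6, 0.2, 0.2)),
                    subjects = subjects)
  sp <- split_spec(test_subjects = c("SA01", "SE01"))
  spl <- make_splits(ds, sp)
  expect_setequal(unique(spl$test$subject_id), c("SA01", "SE01"))
  expect_length(intersect(unique(c(spl$train$subject_id, spl$val$subject_id)),
                          unique(spl$test$subject_id)), 0L)
  expect_equal(n_blocks(spl$train) + n_blocks(spl$val) + n_blocks(spl$test), n)

  expect_error(make_splits(ds, split_spec(test_subjects = "SA99")), "absent")
  expect_error(make_splits(make_blocks(10), split_spec()), "3 subjects")
})

test_that("the 80-20 train/validation split is exact and stratified", {
  # 100 non-test blocks -> exactly 80 train / 20 val
  labels <- c(rep(0L, 50), rep(1L, 30), rep(2L, 20), rep(0L, 10))
  subjects <- c(rep("SA01", 50), rep("SA02", 50), rep("SE01", 10))
  ds <- make_blocks(110, labels = labels, subjects = subjects)
  spl <- make_splits(ds, split_spec(test_subjects = "SE01"))
  expect_equal(n_blocks(spl$train), 80L)
  expect_equal(n_blocks(spl$val), 20L)

  # per-class deviation from the global ratio below one block
  rest_counts <- tabulate(ds$label[ds$subject_id != "SE01"] + 1L, 3L)
  train_counts <- tabulate(spl$train$label + 1L, 3L)
  expect_true(all(abs(train_counts - 0.8 * rest_counts) < 1))
})

test_that("inverse-frequency class weights are normalized to a unit minimum", {
  expect_equal(class_weights_auto(rep(0:2, each = 100)), rep(1, 3))
  w <- class_weights_auto(c(rep(0L, 800), rep(1L, 100), rep(2L, 100)))
  expect_equal(w, c(1, 8, 8))
  expect_error(class_weights_auto(rep(0L, 50)), "absent")
})

test_that("weighted binary cross-entropy has its closed-form values", {
  # perfect one-hot scores: loss at the clipping floor, effectively zero
  expect_lt(weighted_bce_loss(c(1, 0, 0), NON_FALL, rep(1, 3)), 1e-5)
  # indifferent scores: 3 * ln 2 regardless of the target
  for (target in 0:2) {
    expect_equal(weighted_bce_loss(c(0.5, 0.5, 0.5), target, rep(1, 3)),
                 3 * log(2))
  }
  # linear in the weights
  s <- c(0.8, 0.3, 0.4)
  expect_equal(weighted_bce_loss(s, FALL, c(2, 4, 6)),
               2 * weighted_bce_loss(s, FALL, c(1, 2, 3)))
  # batch form averages per-sample losses
  m <- rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(weighted_bce_loss(m, c(0L, 1L), rep(1, 3)), 3 * log(2))
})

make_train_val <- function(seed = 1L) {
  set.seed(seed)
  n <- 40L
  ds <- make_blocks(n, W = 32L, C = 6L,
                    labels = rep(0:2, length.out = n),
                    subjects = rep(c("SA01", "SA02"), each = n / 2),
                    seed = seed)
  list(train = ds[1:30], val = ds[31:40])
}

small_spec <- tiny_spec(input_shape = c(32L, 6L), recurrent_widths = c(4L, 4L))

test_that("a zero learning rate leaves parameters unchanged", {
  d <- make_train_val()
  fit <- train_fall_detector(
    d$train, d$val, small_spec,
    train_config(batch_size = 16L, max_epochs = 1L, learning_rate = 0,
                 rng_seed = 5L),
    augmentation_config(augmented_fraction = 0))
  set.seed(5L)
  init <- build_class_ensemble(fit$final_model$spec)
  expect_equal(fit$final_model$params, init$params, tolerance = 1e-12)
})

test_that("identical seeds reproduce the first-epoch loss exactly", {
  d <- make_train_val()
  run <- function() {
    train_fall_detector(
      d$train, d$val, small_spec,
      train_config(batch_size = 16L, max_epochs = 1L, rng_seed = 17L),
      augmentation_config())$history$train_loss[1]
  }
  expect_lt(abs(run() - run()), 1e-6)

  # different seeds explore different initializations/orders
  other <- train_fall_detector(
    d$train, d$val, small_spec,
    train_config(batch_size = 16L, max_epochs = 1L, rng_seed = 18L),
    augmentation_config())$history$train_loss[1]
  expect_gt(abs(run() - other), 0)
})

test_that("training loss decreases on an easy separable problem", {
  # three cleanly separated block prototypes
  set.seed(23)
  n <- 60L
  proto <- list(function(W) matrix(0.1, W, 6),
                function(W) cbind(matrix(0.8, W, 3), matrix(-0.8, W, 3)),
                function(W) matrix(rep(c(-0.9, 0.9), length.out = W), W, 6))
  W <- 32L
  samples <- array(0, c(n, W, 6))
  labels <- rep(0:2, length.out = n)
  for (i in seq_len(n)) {
    samples[i, , ] <- proto[[labels[i] + 1]](W) + matrix(rnorm(W * 6, 0, 0.05), W, 6)
  }
  ds <- block_dataset(samples, labels, rep(c("SA01", "SA02"), n / 2),
                      paste0("t", seq_len(n)), rep(0L, n))
  fit <- train_fall_detector(
    ds[1:48], ds[49:60], small_spec,
    train_config(batch_size = 16L, max_epochs = 5L, learning_rate = 0.005,
                 rng_seed = 3L),
    augmentation_config(augmented_fraction = 0))
  h <- fit$history
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_equal(names(h)[1:3], c("epoch", "train_loss", "val_loss"))
})

test_that("replicate mode runs one training per seed", {
  d <- make_train_val()
  fits <- train_replicates(
    d$train, d$val, small_spec,
    train_config(batch_size = 16L, max_epochs = 1L),
    augmentation_config(augmented_fraction = 0),
    seeds = c(4L, 5L, 6L))
  expect_length(fits, 3L)
  expect_s3_class(fits[[1]]$model, "fall_ensemble")
})
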