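test_that("the head halves the temporal axis per residual block", {
  expect_equal(head_output_shape(ensemble_spec()), c(32L, 16L))
  expect_equal(head_output_shape(ensemble_spec(head_blocks = 4L)), c(16L, 16L))
  expect_equal(head_output_shape(ensemble_spec(head_blocks = 0L,
                                               head_widths = integer(0))),
               c(256L, 6L))

  set.seed(1)
  head <- build_head_model(ensemble_spec())
  x <- array(rnorm(4 * 256 * 6), c(4, 256, 6))
  expect_equal(dim(head_features(head, x)), c(4L, 32L, 16L))

  id_head <- build_head_model(ensemble_spec(head_blocks = 0L,
                                            head_widths = integer(0)))
  expect_identical(head_features(id_head, x), x)

  expect_error(build_head_model(ensemble_spec(input_shape = c(100L, 6L))),
               "not divisible")
})

test_that("parameter counts match the closed-form recurrent formulas", {
  feat <- 16L  # head output channels feeding the sub-models
  dense_n <- function(I) I + 1L

  set.seed(2)
  for (cell in c("lstm", "gru")) {
    cnt_fun <- if (cell == "lstm") lstm_param_count else gru_param_count
    spec <- ensemble_spec(recurrent_cell = cell)
    sub <- fallnet:::sub_init(spec, feat)
    expect_equal(count_params(sub),
                 cnt_fun(feat, 16) + cnt_fun(16, 16) + dense_n(16L))
  }
  spec_bi <- ensemble_spec(recurrent_cell = "bilstm")
  sub_bi <- fallnet:::sub_init(spec_bi, feat)
  expect_equal(count_params(sub_bi),
               2 * lstm_param_count(feat, 16) + 2 * lstm_param_count(32, 16) +
                 dense_n(32L))

  # GRU is strictly smaller than LSTM at equal widths
  n_lstm <- count_params(fallnet:::sub_init(ensemble_spec(), feat))
  n_gru <- count_params(fallnet:::sub_init(
    ensemble_spec(recurrent_cell = "gru"), feat))
  expect_lt(n_gru, n_lstm)

  # parameters grow monotonically with width
  narrow <- count_params(fallnet:::sub_init(ensemble_spec(), feat))
  wide <- count_params(fallnet:::sub_init(
    ensemble_spec(recurrent_widths = c(32L, 64L)), feat))
  expect_lt(narrow, wide)
})

test_that("the class ensemble has one sub-model per class with disjoint parameters", {
  set.seed(3)
  model <- build_class_ensemble(ensemble_spec())
  expect_length(model$params$subs, 3L)

  # gradients with only class-i loss active leave other sub-models untouched
  x <- array(rnorm(2 * 256 * 6), c(2, 256, 6))
  fw <- fallnet:::ensemble_forward(model, x)
  dlogits <- matrix(0, 2, 3)
  dlogits[, 2] <- 1   # only the pre-fall sub-model's output path
  g <- fallnet:::ensemble_backward(model, fw, dlogits)$grads
  flat_abs_sum <- function(p) {
    if (is.numeric(p)) return(sum(abs(p)))
    sum(vapply(p, flat_abs_sum, 0))
  }
  expect_equal(flat_abs_sum(g$subs[[1]]), 0)
  expect_equal(flat_abs_sum(g$subs[[3]]), 0)
  expect_gt(flat_abs_sum(g$subs[[2]]), 0)
  expect_gt(flat_abs_sum(g$head), 0)  # the shared head learns from any class
})

test_that("forward passes give one bounded score per class for any configuration", {
  set.seed(4)
  for (cell in c("lstm", "gru", "bilstm")) {
    for (conv in c("separable", "standard")) {
      spec <- tiny_spec(recurrent_cell = cell, conv_type = conv,
                        pooling = sample(c("max", "average"), 1),
                        activation = sample(c("swish", "relu"), 1))
      model <- build_class_ensemble(spec)
      x <- array(rnorm(5 * 8 * 3), c(5, 8, 3))
      s <- predict_scores(model, x)
      expect_equal(dim(s), c(5L, 3L))
      expect_true(all(s >= 0 & s <= 1))
    }
  }
})

test_that("argmax fusion follows the severity tie-break rule", {
  expect_equal(fuse_proposed(c(0.1, 0.7, 0.2)), PRE_FALL)
  expect_equal(fuse_proposed(c(0, 0, 1)), FALL)
  # tie between NON_FALL and PRE_FALL resolves to the more severe PRE_FALL
  expect_equal(fuse_proposed(c(0.4, 0.4, 0.1)), PRE_FALL)
  expect_equal(fuse_proposed(c(0.4, 0.1, 0.4)), FALL)
  expect_error(fuse_proposed(c(0.1, NaN, 0.3)), "NA|NaN")

  m <- rbind(c(0.9, 0.1, 0.1), c(0.1, 0.1, 0.9))
  expect_equal(fuse_proposed(m), c(NON_FALL, FALL))
  # one-hot scores recover the class index exactly
  expect_equal(fuse_proposed(diag(3)), c(NON_FALL, PRE_FALL, FALL))
})

test_that("weighted-average fusion reduces to argmax at unit weights", {
  set.seed(6)
  s <- matrix(runif(30), 10, 3)
  expect_equal(fuse_weighted_average(s, c(1, 1, 1)), fuse_proposed(s))
  expect_equal(fuse_weighted_average(c(0.6, 0.5, 0.1), c(0.5, 1, 1)), PRE_FALL)
  expect_error(fuse_weighted_average(c(0.5, 0.5, 0.5), c(1, -1, 1)),
               "non-negative")
  expect_error(fuse_weighted_average(c(0.5, 0.5, 0.5), c(1, 1)), "length")
})

test_that("the stacked reference ensemble outputs a softmax distribution", {
  set.seed(7)
  model <- build_stacked_ensemble(tiny_spec())
  x <- array(rnorm(6 * 8 * 3), c(6, 8, 3))
  p <- predict_stacked(model, x)
  expect_equal(dim(p), c(6L, 3L))
  expect_equal(rowSums(p), rep(1, 6))
  expect_true(all(p >= 0))
  pred <- fuse_proposed(p)
  expect_equal(pred, apply(p, 1, which.max) - 1L)
})
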