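test_that("zero-phase Butterworth keeps DC and strongly attenuates high frequencies", {
  cfg <- preprocess_config()

  const <- annotate_trial(make_trial(matrix(3.7, 1000, 3)), rep(0L, 1000))
  out <- lowpass_filter(const, cfg)
  expect_equal(out$trial$samples, const$trial$samples, tolerance = 1e-6)
  expect_identical(out$labels, const$labels)

  # 50 Hz sinusoid vs 5 Hz cutoff: forward-backward 4th-order Butterworth
  # has |H|^2 = 1/(1 + (f/fc)^8)^... far below 5% here
  tt <- (0:3999) / 200
  sine <- annotate_trial(make_trial(matrix(sin(2 * pi * 50 * tt), ncol = 1)),
                         rep(0L, 4000))
  filt <- lowpass_filter(sine, cfg)
  mid <- 1000:3000
  expect_lt(max(abs(filt$trial$samples[mid, 1])), 0.05)

  short <- annotate_trial(make_trial(matrix(0, cfg$filter_order, 2)),
                          rep(0L, cfg$filter_order))
  expect_error(lowpass_filter(short, cfg), "too short")
})

test_that("normalization maps into [-1, 1] in every mode", {
  set.seed(3)
  train <- make_trial(matrix(rnorm(500 * 3, mean = c(2, -1, 0)), 500, 3,
                             byrow = TRUE))
  stats <- norm_stats(train)

  # constant channel at the training mean -> zeros under z-scoring
  at <- annotate_trial(make_trial(matrix(stats$mean, 100, 3, byrow = TRUE)),
                       rep(0L, 100))
  z <- normalize_trial(at, stats, preprocess_config(normalization = "zscore_clip"))
  expect_equal(max(abs(z$trial$samples)), 0)

  # mu + 10 sigma clips to exactly +1
  big <- annotate_trial(
    make_trial(matrix(stats$mean + 10 * stats$sd, 10, 3, byrow = TRUE)),
    rep(0L, 10))
  expect_equal(unique(as.vector(
    normalize_trial(big, stats, preprocess_config())$trial$samples)), 1)

  # minmax endpoints map to -1 and +1
  ends <- annotate_trial(make_trial(rbind(stats$min, stats$max)), c(0L, 0L))
  mm <- normalize_trial(ends, stats, preprocess_config(normalization = "minmax"))
  expect_equal(mm$trial$samples[1, ], rep(-1, 3), ignore_attr = TRUE)
  expect_equal(mm$trial$samples[2, ], rep(1, 3), ignore_attr = TRUE)

  # arbitrary data stays bounded in all modes, even outside the training range
  wild <- annotate_trial(make_trial(matrix(rnorm(200 * 3, 0, 50), 200, 3)),
                         rep(0L, 200))
  for (mode in c("zscore_clip", "minmax", "zscore_tanh")) {
    y <- normalize_trial(wild, stats, preprocess_config(normalization = mode))
    expect_true(all(y$trial$samples >= -1 & y$trial$samples <= 1))
  }
})

test_that("zero-variance channels get sd substituted with a warning", {
  flat <- make_trial(cbind(rnorm(100), rep(5, 100)))
  expect_warning(st <- norm_stats(flat), "substituting sd = 1")
  expect_equal(st$sd[2], 1, ignore_attr = TRUE)
  expect_equal(st$sd_substituted, 2L, ignore_attr = TRUE)
})

test_that("segmentation produces the documented window grid", {
  cfg <- preprocess_config()
  mk <- function(T_) annotate_trial(make_trial(matrix(rnorm(T_ * 2), T_, 2)),
                                    rep(0L, T_))
  b1024 <- segment_blocks(mk(1024), cfg)
  expect_equal(n_blocks(b1024), 7L)
  expect_equal(b1024$start_index, seq(0L, 768L, by = 128L))

  expect_equal(n_blocks(segment_blocks(mk(256), cfg)), 1L)
  expect_message(b0 <- segment_blocks(mk(255), cfg), "no blocks")
  expect_equal(n_blocks(b0), 0L)
})

test_that("window counts match brute-force enumeration over random configurations", {
  set.seed(41)
  for (i in 1:60) {
    W <- sample(4:64, 1)
    T_ <- sample(W:(8 * W), 1)
    ov <- runif(1, 0, 0.9)
    cfg <- preprocess_config(block_width = W, overlap_fraction = ov,
                             filter_cutoff_hz = 5)
    stride <- max(1L, as.integer(round(W * (1 - ov))))
    at <- annotate_trial(make_trial(matrix(0, T_, 1)), rep(0L, T_))
    got <- suppressMessages(segment_blocks(at, cfg))
    starts <- brute_force_starts(T_, W, stride)
    expect_equal(n_blocks(got), length(starts))
    expect_equal(got$start_index, starts)
  }
})

test_that("block labeling is majority vote with severity tie-breaking", {
  cfg <- preprocess_config()
  expect_equal(label_block(c(rep(FALL, 200), rep(PRE_FALL, 56)), cfg), FALL)
  expect_equal(label_block(c(rep(FALL, 128), rep(NON_FALL, 128)), cfg), FALL)
  expect_equal(label_block(rep(NON_FALL, 256), cfg), NON_FALL)
  # tie between the two less-severe classes resolves to PRE_FALL
  expect_equal(label_block(c(rep(NON_FALL, 128), rep(PRE_FALL, 128)), cfg),
               PRE_FALL)
  # permutation invariance
  set.seed(5)
  labs <- sample(c(rep(0L, 100), rep(1L, 100), rep(2L, 56)))
  expect_equal(label_block(labs, cfg), label_block(sort(labs), cfg))
  # a configurable priority changes tie outcomes
  alt <- preprocess_config(tie_break_priority = c(NON_FALL, PRE_FALL, FALL))
  expect_equal(label_block(c(rep(FALL, 128), rep(NON_FALL, 128)), alt), NON_FALL)
})

test_that("blocks carry provenance and slices of the whole-trial signal", {
  set.seed(9)
  T_ <- 600
  at <- annotate_trial(
    make_trial(matrix(rnorm(T_ * 2), T_, 2), subject_id = "SE05",
               group = "elderly", activity_code = "F03",
               activity_class = "FALL", trial_index = 4L),
    sample(0:2, T_, replace = TRUE))
  cfg <- preprocess_config(block_width = 128L)
  filt <- lowpass_filter(at, cfg)
  blocks <- segment_blocks(filt, cfg)
  expect_true(all(blocks$subject_id == "SE05"))
  expect_true(all(blocks$source_trial == "F03_SE05_R04"))
  for (i in seq_len(n_blocks(blocks))) {
    s <- blocks$start_index[i]
    expect_equal(get_block(blocks, i)$samples,
                 filt$trial$samples[(s + 1):(s + 128), ], ignore_attr = TRUE)
  }
})
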