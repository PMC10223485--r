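test_that("generated trials have the requested duration and label structure", {
  cfg <- synthetic_config(trial_duration_s = 10)
  set.seed(1)
  adl <- generate_trial("ADL", cfg)
  expect_equal(nrow(adl$trial$samples), 2000L)
  expect_length(adl$labels, 2000L)
  expect_equal(unique(adl$labels), NON_FALL)
  expect_equal(ncol(adl$trial$samples), 9L)

  near <- generate_trial("NEAR_FALL", cfg)
  expect_setequal(unique(near$labels), c(NON_FALL, PRE_FALL))

  fall <- generate_trial("FALL_WITH_IMPACT", cfg)
  expect_setequal(unique(fall$labels), c(NON_FALL, PRE_FALL, FALL))
})

test_that("label transitions follow the event grammar", {
  cfg <- synthetic_config()
  set.seed(2)
  for (i in 1:30) {
    kind <- sample(c("ADL", "NEAR_FALL", "FALL_WITH_IMPACT"), 1)
    at <- generate_trial(kind, cfg)
    trans <- unique(cbind(at$labels[-length(at$labels)], at$labels[-1]))
    trans <- trans[trans[, 1] != trans[, 2], , drop = FALSE]
    allowed <- rbind(c(NON_FALL, PRE_FALL), c(PRE_FALL, FALL),
                     c(PRE_FALL, NON_FALL), c(FALL, NON_FALL))
    for (r in seq_len(nrow(trans))) {
      expect_true(any(trans[r, 1] == allowed[, 1] & trans[r, 2] == allowed[, 2]),
                  label = sprintf("transition %d->%d in %s",
                                  trans[r, 1], trans[r, 2], kind))
    }
  }
})

test_that("the impact peak lies inside the fall-labeled span", {
  cfg <- synthetic_config()
  set.seed(3)
  for (i in 1:100) {
    at <- generate_trial("FALL_WITH_IMPACT", cfg)
    norms <- sqrt(rowSums(at$trial$samples[, 1:3]^2))
    expect_equal(at$labels[which.max(norms)], FALL)
  }
})

test_that("ADL acceleration stays gravity-dominated and the impact dwarfs it", {
  cfg <- synthetic_config()
  set.seed(4)
  adl_max_dev <- 0
  for (i in 1:20) {
    at <- generate_trial("ADL", cfg)
    norms <- sqrt(rowSums(at$trial$samples[, 1:3]^2))
    adl_max_dev <- max(adl_max_dev, max(abs(norms - 1)))
  }
  expect_lt(adl_max_dev, cfg$adl_amplitude_g)
  fall <- generate_trial("FALL_WITH_IMPACT", cfg)
  peak <- max(sqrt(rowSums(fall$trial$samples[, 1:3]^2)))
  expect_gt(peak, 2 * (1 + cfg$adl_amplitude_g))
})

test_that("datasets have the configured roster and are seed-deterministic", {
  cfg <- synthetic_config(n_young = 4L, n_elderly = 2L,
                          trials_per_subject = 5L, rng_seed = 9L)
  d1 <- generate_dataset(cfg)
  expect_length(d1$trials, 30L)
  expect_equal(nrow(d1$roster), 6L)
  expect_equal(sum(d1$roster$group == "elderly"), 2L)
  subj <- vapply(d1$trials, function(t) t$trial$subject_id, "")
  expect_setequal(unique(subj), d1$roster$subject_id)
  expect_equal(unname(table(subj)[d1$roster$subject_id]),
               rep(5L, 6L), ignore_attr = TRUE)

  d2 <- generate_dataset(cfg)
  expect_identical(d1, d2)
})

test_that("generated data pass the whole reader and preprocessing path", {
  cfg <- synthetic_config(n_young = 2L, n_elderly = 1L,
                          trials_per_subject = 3L, trial_duration_s = 3,
                          rng_seed = 5L)
  d <- generate_dataset(cfg)
  raw_dir <- withr::local_tempdir(); annot_dir <- withr::local_tempdir()
  paths <- write_sisfall_dataset(d, raw_dir, annot_dir)
  expect_length(paths, 9L)

  trials <- lapply(paths, function(p) {
    select_channels(read_annotations(file.path(annot_dir, basename(p)),
                                     read_raw_trial(p)))
  })
  pp <- preprocess_trials(trials)
  expect_s3_class(pp$blocks, "block_dataset")
  expect_gt(n_blocks(pp$blocks), 0L)
  expect_true(all(pp$blocks$samples >= -1 & pp$blocks$samples <= 1))
})

test_that("block-label histograms are imbalanced with Non-Fall modal", {
  cfg <- synthetic_config(n_young = 2L, n_elderly = 1L,
                          trials_per_subject = 8L, rng_seed = 6L)
  d <- generate_dataset(cfg)
  d$trials <- lapply(d$trials, select_channels)
  pp <- preprocess_trials(d$trials)
  counts <- tabulate(pp$blocks$label + 1L, 3L)
  expect_equal(which.max(counts), 1L)       # NON_FALL modal
  expect_true(all(counts > 0L))             # all three classes present
})

test_that("the hard preset narrows the class separation", {
  easy <- synthetic_config()
  hard <- synthetic_config(difficulty = "hard")
  expect_lt(hard$fall_peak_g, easy$fall_peak_g)
  expect_gt(hard$noise_std, easy$noise_std)
  set.seed(8)
  at <- generate_trial("FALL_WITH_IMPACT", hard)
  expect_lte(max(sqrt(rowSums(at$trial$samples[, 1:3]^2))),
             hard$fall_peak_g + 1)
})
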