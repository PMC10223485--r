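# Shared fixtures and independent oracles, all built in code at test time.

make_trial <- function(samples, subject_id = "SA01", group = "young",
                       activity_code = "D01", activity_class = "ADL",
                       trial_index = 1L, rate = 200) {
  fallnet:::new_raw_trial(
    as.matrix(samples),
    list(subject_id = subject_id, subject_group = group,
         activity_code = activity_code, activity_class = activity_class,
         trial_index = trial_index),
    rate
  )
}

# write integer ADC rows in the SisFall on-disk dialect
write_trial_file <- function(counts, dir = NULL, name = "D01_SA01_R01.txt") {
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  path <- file.path(dir, name)
  writeLines(paste0(apply(counts, 1L, paste, collapse = ","), ";"), path)
  path
}

# a small labeled block dataset with controllable labels/subjects
make_blocks <- function(n, W = 16L, C = 6L, labels = rep(NON_FALL, n),
                        subjects = rep("SA01", n), seed = 1L) {
  set.seed(seed)
  block_dataset(
    samples = array(rnorm(n * W * C), c(n, W, C)),
    label = labels, subject_id = subjects,
    source_trial = paste0("trial", seq_len(n)),
    start_index = rep(0L, n)
  )
}

# independent windowing oracle: enumerate every admissible start
brute_force_starts <- function(T_, W, stride) {
  starts <- integer(0)
  s <- 0L
  while (s + W <= T_) {
    starts <- c(starts, s)
    s <- s + stride
  }
  starts
}

# independent per-class confusion/metric oracle (scalar loops, no sharing
# with the package implementation)
brute_force_metrics <- function(pred, truth, n_classes = 3L) {
  out <- NULL
  for (cl in seq_len(n_classes) - 1L) {
    tp <- tn <- fp <- fn <- 0L
    for (i in seq_along(pred)) {
      p <- pred[i] == cl
      t_ <- truth[i] == cl
      if (p && t_) tp <- tp + 1L
      else if (!p && !t_) tn <- tn + 1L
      else if (p && !t_) fp <- fp + 1L
      else fn <- fn + 1L
    }
    out <- rbind(out, data.frame(
      class = cl,
      accuracy = (tp + tn) / length(pred),
      sensitivity = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
    ))
  }
  out
}

# pairwise-comparison AUC oracle: fraction of (positive, negative) pairs
# correctly ordered, ties counting one half
pairwise_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# closed-form recurrent parameter counts
lstm_param_count <- function(I, H) 4 * (H * (H + I) + H)
gru_param_count <- function(I, H) 3 * (H * (H + I) + H)

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(head_blocks = 1L, head_widths = 4L, conv_type = "separable",
                   activation = "swish", pooling = "max",
                   recurrent_layers = 2L, recurrent_widths = c(4L, 3L),
                   recurrent_cell = "lstm", dropout_rate = 0,
                   kernel_size = 3L, input_shape = c(8L, 3L))
  do.call(ensemble_spec, utils::modifyList(defaults, args))
}
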