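#' Preprocessing configuration
#'
#' Controls the filter -> normalize -> segment pipeline. Defaults follow the
#' annotated-SisFall convention: 256-sample blocks (1.28 s at 200 Hz) with 50%
#' overlap, a 4th-order low-pass Butterworth at 5 Hz applied zero-phase, and
#' per-channel z-scoring clipped into [-1, +1].
#'
#' @param filter_order Butterworth order (>= 1).
#' @param filter_cutoff_hz Low-pass cutoff in Hz; must be below Nyquist.
#' @param block_width Window width in samples (default 256).
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)` (default 0.5).
#' @param normalization One of `"zscore_clip"` (z-score then hard clip to
#'   \[-1, 1\]), `"minmax"` (affine map of the training range onto \[-1, 1\]),
#'   `"zscore_tanh"` (tanh-squashed z-score).
#' @param tie_break_priority Label priority used to resolve block-label ties.
#' @param sample_rate_hz Sampling rate assumed for cutoff validation.
#' @return A `preprocess_config`.
#' @export
preprocess_config <- function(filter_order = 4L,
                              filter_cutoff_hz = 5,
                              block_width = 256L,
                              overlap_fraction = 0.5,
                              normalization = c("zscore_clip", "minmax", "zscore_tanh"),
                              tie_break_priority = default_tie_break(),
                              sample_rate_hz = 200) {
  normalization <- match.arg(normalization)
  stopifnot(
    filter_order >= 1L, filter_cutoff_hz > 0,
    block_width >= 2L, overlap_fraction >= 0, overlap_fraction < 1,
    sample_rate_hz > 0
  )
  if (filter_cutoff_hz >= sample_rate_hz / 2) {
    stop("filter_cutoff_hz must be below the Nyquist frequency ",
         sample_rate_hz / 2, " Hz", call. = FALSE)
  }
  tie_break_priority <- validate_labels(tie_break_priority, "tie_break_priority")
  stopifnot(length(unique(tie_break_priority)) == 3L)
  structure(
    list(
      filter_order = as.integer(filter_order),
      filter_cutoff_hz = filter_cutoff_hz,
      block_width = as.integer(block_width),
      overlap_fraction = overlap_fraction,
      normalization = normalization,
      tie_break_priority = tie_break_priority,
      sample_rate_hz = sample_rate_hz
    ),
    class = "preprocess_config"
  )
}

#' Zero-phase low-pass Butterworth filtering
#'
#' Each channel is filtered independently with a forward-backward (zero-phase)
#' Butterworth low-pass, which removes high-frequency noise without shifting
#' the signal relative to its per-sample labels. Labels are untouched.
#'
#' @param at An `annotated_trial` (or `raw_trial`).
#' @param cfg A [preprocess_config()].
#' @return Object of the same class with filtered samples.
#' @export
lowpass_filter <- function(at, cfg = preprocess_config()) {
  if (inherits(at, "annotated_trial")) {
    at$trial <- lowpass_filter(at$trial, cfg)
    return(at)
  }
  stopifnot(inherits(at, "raw_trial"))
  x <- at$samples
  if (nrow(x) <= 3L * cfg$filter_order) {
    stop("trial too short to filter: need more than ", 3L * cfg$filter_order,
         " samples, have ", nrow(x), call. = FALSE)
  }
  rate <- at$sample_rate_hz
  if (cfg$filter_cutoff_hz >= rate / 2) {
    stop("cutoff at or above Nyquist for this trial", call. = FALSE)
  }
  bf <- signal::butter(cfg$filter_order, cfg$filter_cutoff_hz / (rate / 2),
                       type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (filtfilt alone pads with zeros); the pad is sized
  # from the dominant pole so the zero-state transient decays below 1e-9
  # within it
  T_ <- nrow(x)
  pole_max <- max(Mod(polyroot(rev(bf$a))))
  decay_len <- if (pole_max < 1) ceiling(log(1e-9) / log(pole_max)) else T_
  pl <- min(max(3L * (cfg$filter_order + 1L), decay_len), T_ - 1L)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    pre <- 2 * v[1L] - v[(pl + 1L):2L]
    post <- 2 * v[T_] - v[(T_ - 1L):(T_ - pl)]
    f <- signal::filtfilt(bf, c(pre, v, post))
    x[, j] <- f[(pl + 1L):(pl + T_)]
  }
  at$samples <- x
  at
}

#' Fit per-channel normalization statistics
#'
#' Statistics (mean, sd, min, max per channel) must be fitted on training
#' subjects only and frozen for validation/test, preventing leakage in the
#' subject-wise protocol. A zero-variance channel gets sd substituted by 1,
#' with a warning.
#'
#' @param trials A list of `annotated_trial`/`raw_trial` objects (or one such
#'   object), all with the same channel count.
#' @return A `norm_stats` object.
#' @export
norm_stats <- function(trials) {
  if (inherits(trials, c("annotated_trial", "raw_trial"))) trials <- list(trials)
  mats <- lapply(trials, function(t) {
    if (inherits(t, "annotated_trial")) t$trial$samples else t$samples
  })
  stopifnot(length(mats) > 0L, length(unique(vapply(mats, ncol, 0L))) == 1L)
  x <- do.call(rbind, mats)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  substituted <- !is.finite(sdv) | sdv == 0
  if (any(substituted)) {
    warning("zero/undefined sd on channel(s) ",
            paste(which(substituted), collapse = ", "),
            "; substituting sd = 1")
    sdv[substituted] <- 1
  }
  structure(
    list(mean = mu, sd = sdv, min = apply(x, 2L, min), max = apply(x, 2L, max),
         sd_substituted = which(substituted)),
    class = "norm_stats"
  )
}

#' Normalize a trial into \[-1, +1\]
#'
#' Default mode `zscore_clip`: per-channel `(x - mean) / sd` with the frozen
#' training statistics, then hard clipping to \[-1, +1\]. `minmax` affinely
#' maps the training range onto \[-1, +1\] (values outside the training range
#' are clipped); `zscore_tanh` squashes z-scores through tanh. Every output
#' value is guaranteed to lie in \[-1, +1\].
#'
#' @param at An `annotated_trial` (or `raw_trial`).
#' @param stats A [norm_stats()] object fitted on training data.
#' @param cfg A [preprocess_config()] selecting the mode.
#' @return Object of the same class with normalized samples.
#' @export
normalize_trial <- function(at, stats, cfg = preprocess_config()) {
  if (inherits(at, "annotated_trial")) {
    at$trial <- normalize_trial(at$trial, stats, cfg)
    return(at)
  }
  stopifnot(inherits(at, "raw_trial"), inherits(stats, "norm_stats"))
  x <- at$samples
  stopifnot(ncol(x) == length(stats$mean))
  z <- sweep(sweep(x, 2L, stats$mean, `-`), 2L, stats$sd, `/`)
  y <- switch(cfg$normalization,
    zscore_clip = pmin(pmax(z, -1), 1),
    zscore_tanh = tanh(z),
    minmax = {
      rng <- stats$max - stats$min
      rng[rng == 0] <- 1
      m <- sweep(sweep(x, 2L, stats$min, `-`), 2L, rng, `/`) * 2 - 1
      pmin(pmax(m, -1), 1)
    }
  )
  dimnames(y) <- dimnames(x)
  at$samples <- y
  at
}

#' Majority label of a window
#'
#' A block inherits the most frequent per-sample label it covers; ties are
#' broken by severity priority (default Fall > Pre-Fall > Non-Fall).
#'
#' @param window_labels Integer label vector covering the window.
#' @param cfg A [preprocess_config()] (only `tie_break_priority` is used).
#' @return A single class label code.
#' @export
label_block <- function(window_labels, cfg = preprocess_config()) {
  window_labels <- validate_labels(window_labels, "window labels")
  counts <- tabulate(window_labels + 1L, nbins = 3L)
  argmax_with_priority(counts, cfg$tie_break_priority)
}

#' Segment a trial into fixed-width overlapping blocks
#'
#' Windows of `block_width` samples start at multiples of
#' `stride = round(block_width * (1 - overlap_fraction))` (0-based, half-open
#' `[start, start + W)`); the trailing partial window is discarded. Each block
#' is labeled by [label_block()].
#'
#' @param at An `annotated_trial`.
#' @param cfg A [preprocess_config()].
#' @return A `block_dataset` (possibly empty when the trial is shorter than
#'   one window).
#' @export
segment_blocks <- function(at, cfg = preprocess_config()) {
  stopifnot(inherits(at, "annotated_trial"))
  x <- at$trial$samples
  T_ <- nrow(x); C <- ncol(x); W <- cfg$block_width
  stride <- max(1L, as.integer(round(W * (1 - cfg$overlap_fraction))))
  trial_name <- sprintf("%s_%s_R%02d", at$trial$activity_code,
                        at$trial$subject_id, at$trial$trial_index)
  if (T_ < W) {
    message("trial ", trial_name, " shorter than one block (", T_, " < ", W,
            "); producing no blocks")
    return(empty_block_dataset(W, C))
  }
  starts <- seq.int(0L, T_ - W, by = stride)
  n <- length(starts)
  samples <- array(0, dim = c(n, W, C))
  labels <- integer(n)
  for (i in seq_len(n)) {
    idx <- (starts[i] + 1L):(starts[i] + W)
    samples[i, , ] <- x[idx, ]
    labels[i] <- label_block(at$labels[idx], cfg)
  }
  block_dataset(
    samples, labels,
    subject_id   = rep(at$trial$subject_id, n),
    source_trial = rep(trial_name, n),
    start_index  = starts
  )
}

#' Run the full preprocessing pipeline over a collection of trials
#'
#' Filters, normalizes (with frozen statistics), and segments each trial,
#' returning one combined block dataset. When `stats` is `NULL` the
#' statistics are fitted on the *filtered* versions of `fit_trials`
#' (defaulting to `trials`); pass the training subset explicitly to keep the
#' subject-wise protocol leak-free.
#'
#' @param trials List of `annotated_trial` objects.
#' @param cfg A [preprocess_config()].
#' @param stats Optional pre-fitted [norm_stats()].
#' @param fit_trials Trials used to fit statistics when `stats` is `NULL`.
#' @return List with `blocks` (a `block_dataset`) and `stats`.
#' @export
preprocess_trials <- function(trials, cfg = preprocess_config(), stats = NULL,
                              fit_trials = trials) {
  filtered <- lapply(trials, lowpass_filter, cfg = cfg)
  if (is.null(stats)) {
    fit_filtered <- if (identical(fit_trials, trials)) {
      filtered
    } else {
      lapply(fit_trials, lowpass_filter, cfg = cfg)
    }
    stats <- norm_stats(fit_filtered)
  }
  segs <- lapply(filtered, function(tr) {
    segment_blocks(normalize_trial(tr, stats, cfg), cfg)
  })
  list(blocks = do.call(combine_blocks, segs), stats = stats)
}
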