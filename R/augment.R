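#' Augmentation configuration
#'
#' Parameters of the three label-preserving transforms and of online
#' half-batch augmentation: a random 3-D rotation (angle uniform in
#' `(-pi, pi)`, axis uniform on the sphere, the same rotation applied to every
#' xyz sensor triplet of the block), multiplication by a scalar drawn from
#' `N(1, 0.1)`, and element-wise Gaussian jitter with sd 0.01. During batch
#' assembly, half of the batch is replaced by transformed copies, each
#' receiving exactly one transform drawn from `transform_probs`.
#'
#' @param rotation_angle_range Interval (radians) for the rotation angle.
#' @param scale_mean,scale_std Normal law of the scaling factor.
#' @param jitter_std Standard deviation of the additive noise.
#' @param transform_probs Probabilities for (rotation, scaling, jitter);
#'   must be non-negative and sum to 1.
#' @param augmented_fraction Fraction of each batch replaced by augmented
#'   copies (default 0.5).
#' @param per_channel_scale Draw one scaling factor per channel instead of
#'   per block.
#' @param rng_seed Optional seed applied by [augment_batch()] for
#'   reproducible batches.
#' @return An `augmentation_config`.
#' @export
augmentation_config <- function(rotation_angle_range = c(-pi, pi),
                                scale_mean = 1.0,
                                scale_std = 0.1,
                                jitter_std = 0.01,
                                transform_probs = c(rotation = 1/3,
                                                    scaling  = 1/3,
                                                    jitter   = 1/3),
                                augmented_fraction = 0.5,
                                per_channel_scale = FALSE,
                                rng_seed = NULL) {
  stopifnot(
    length(rotation_angle_range) == 2L,
    rotation_angle_range[1L] <= rotation_angle_range[2L],
    scale_std >= 0, jitter_std >= 0,
    length(transform_probs) == 3L, all(transform_probs >= 0),
    abs(sum(transform_probs) - 1) < 1e-8,
    augmented_fraction >= 0, augmented_fraction <= 1
  )
  structure(
    list(
      rotation_angle_range = rotation_angle_range,
      scale_mean = scale_mean, scale_std = scale_std,
      jitter_std = jitter_std,
      transform_probs = unname(transform_probs),
      augmented_fraction = augmented_fraction,
      per_channel_scale = isTRUE(per_channel_scale),
      rng_seed = rng_seed
    ),
    class = "augmentation_config"
  )
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula; `axis` is normalized internally.
#'
#' @param axis Length-3 axis of rotation.
#' @param angle Rotation angle in radians.
#' @return A 3x3 orthogonal matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  stopifnot(length(axis) == 3L)
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3L], -u[2L],
                -u[3L], 0, u[1L],
                u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

as_block <- function(block) {
  stopifnot(is.list(block), is.matrix(block$samples))
  block
}

#' Rotate all sensor triplets of a block
#'
#' One rotation (axis uniform on the unit sphere, angle uniform in the
#' configured range) is drawn and applied to every timestep and to every xyz
#' triplet — accelerometer and gyroscope rotate together, as a physical
#' re-orientation of the device would rotate both sensors identically. The
#' label is unchanged.
#'
#' @param block A block as returned by [get_block()]: `samples` is `W x C`
#'   with `C` a multiple of 3.
#' @param cfg An [augmentation_config()].
#' @return The transformed block.
#' @export
rotate_block <- function(block, cfg = augmentation_config()) {
  block <- as_block(block)
  C <- ncol(block$samples)
  if (C %% 3L != 0L) {
    stop("channel count ", C, " is not a multiple of 3 (xyz triplets)",
         call. = FALSE)
  }
  axis <- stats::rnorm(3L)
  angle <- stats::runif(1L, cfg$rotation_angle_range[1L],
                        cfg$rotation_angle_range[2L])
  R <- rotation_matrix(axis, angle)
  for (j in seq_len(C / 3L)) {
    idx <- (3L * j - 2L):(3L * j)
    block$samples[, idx] <- block$samples[, idx] %*% t(R)
  }
  block
}

#' Scale a block by a random factor
#'
#' One scalar is drawn from `N(scale_mean, scale_std)` per block (or one per
#' channel with `per_channel_scale`) and multiplies every sample. The label
#' is unchanged.
#'
#' @inheritParams rotate_block
#' @return The transformed block.
#' @export
scale_block <- function(block, cfg = augmentation_config()) {
  block <- as_block(block)
  if (cfg$per_channel_scale) {
    s <- stats::rnorm(ncol(block$samples), cfg$scale_mean, cfg$scale_std)
    block$samples <- sweep(block$samples, 2L, s, `*`)
  } else {
    s <- stats::rnorm(1L, cfg$scale_mean, cfg$scale_std)
    block$samples <- block$samples * s
  }
  block
}

#' Add Gaussian jitter to a block
#'
#' I.i.d. zero-mean noise with sd `jitter_std` is added element-wise,
#' simulating sensor noise. The label is unchanged.
#'
#' @inheritParams rotate_block
#' @return The transformed block.
#' @export
jitter_block <- function(block, cfg = augmentation_config()) {
  block <- as_block(block)
  block$samples <- block$samples +
    matrix(stats::rnorm(length(block$samples), 0, cfg$jitter_std),
           nrow(block$samples), ncol(block$samples))
  block
}

#' Online augmentation of a training batch
#'
#' Exactly `floor(augmented_fraction * N)` blocks, chosen uniformly without
#' replacement, are replaced in place by transformed copies; each selected
#' block receives exactly one transform drawn from `transform_probs`. Batch
#' size, block shapes, order, labels, and subject provenance are all
#' preserved. Nothing is written to disk: augmentation happens during batch
#' assembly only.
#'
#' @param batch A non-empty `block_dataset`.
#' @param cfg An [augmentation_config()]; when `cfg$rng_seed` is set, the
#'   seed is applied first so identical seeds give identical batches.
#' @return The augmented `block_dataset`.
#' @export
augment_batch <- function(batch, cfg = augmentation_config()) {
  stopifnot(inherits(batch, "block_dataset"))
  n <- n_blocks(batch)
  if (n == 0L) stop("batch is empty", call. = FALSE)
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  k <- floor(cfg$augmented_fraction * n)
  if (k == 0L) return(batch)
  chosen <- sample.int(n, k)
  transforms <- list(rotate_block, scale_block, jitter_block)
  which_tf <- sample.int(3L, k, replace = TRUE, prob = cfg$transform_probs)
  for (m in seq_len(k)) {
    i <- chosen[m]
    b <- get_block(batch, i)
    b <- transforms[[which_tf[m]]](b, cfg)
    batch$samples[i, , ] <- b$samples
  }
  batch
}
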