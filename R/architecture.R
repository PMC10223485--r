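#' Ensemble architecture specification
#'
#' Describes the full network: a shared convolutional head (a stack of
#' "skipped" residual convolution blocks, each halving the temporal axis by
#' pooling) feeding one recurrent one-vs-rest sub-model per event class.
#' Defaults are the configuration found best in the hyperparameter study:
#' three separable-convolution residual blocks of width 16 with swish
#' activation and max pooling, two LSTM layers of width 16, dropout 0.5.
#'
#' @param n_classes Number of event classes (and of ensemble sub-models).
#' @param head_blocks Number of residual convolution blocks in the head.
#' @param head_widths Integer vector of per-block filter counts
#'   (length `head_blocks`).
#' @param conv_type `"separable"` (depthwise + pointwise) or `"standard"`.
#' @param pooling `"max"` or `"average"`, stride 2.
#' @param activation `"swish"` or `"relu"`.
#' @param recurrent_layers Number of stacked recurrent layers per sub-model.
#' @param recurrent_widths Integer vector of per-layer units
#'   (length `recurrent_layers`).
#' @param recurrent_cell `"lstm"`, `"gru"`, or `"bilstm"`.
#' @param dropout_rate Dropout before the sub-model output unit, in `[0, 1)`.
#' @param kernel_size Odd convolution kernel length.
#' @param input_shape `c(block_width, channels)` of one input block.
#' @return An `ensemble_spec`.
#' @export
ensemble_spec <- function(n_classes = 3L,
                          head_blocks = 3L,
                          head_widths = rep(16L, head_blocks),
                          conv_type = c("separable", "standard"),
                          pooling = c("max", "average"),
                          activation = c("swish", "relu"),
                          recurrent_layers = 2L,
                          recurrent_widths = rep(16L, recurrent_layers),
                          recurrent_cell = c("lstm", "gru", "bilstm"),
                          dropout_rate = 0.5,
                          kernel_size = 5L,
                          input_shape = c(256L, 6L)) {
  conv_type <- match.arg(conv_type)
  pooling <- match.arg(pooling)
  activation <- match.arg(activation)
  recurrent_cell <- match.arg(recurrent_cell)
  stopifnot(
    n_classes >= 2L, head_blocks >= 0L,
    length(head_widths) == head_blocks,
    recurrent_layers >= 1L,
    length(recurrent_widths) == recurrent_layers,
    dropout_rate >= 0, dropout_rate < 1,
    kernel_size >= 1L, kernel_size %% 2L == 1L,
    length(input_shape) == 2L, all(input_shape >= 1L)
  )
  structure(
    list(
      n_classes = as.integer(n_classes),
      head_blocks = as.integer(head_blocks),
      head_widths = as.integer(head_widths),
      conv_type = conv_type, pooling = pooling, activation = activation,
      recurrent_layers = as.integer(recurrent_layers),
      recurrent_widths = as.integer(recurrent_widths),
      recurrent_cell = recurrent_cell,
      dropout_rate = dropout_rate,
      kernel_size = as.integer(kernel_size),
      input_shape = as.integer(input_shape)
    ),
    class = "ensemble_spec"
  )
}

#' Feature-map shape produced by the head model
#'
#' Each residual block halves the temporal axis (pooling stride 2), so a
#' `(W, C)` block becomes `(W / 2^head_blocks, last_width)`.
#'
#' @param spec An [ensemble_spec()].
#' @return Integer `c(timesteps, channels)` of the head output.
#' @export
head_output_shape <- function(spec) {
  W <- spec$input_shape[1L]
  if (spec$head_blocks == 0L) return(spec$input_shape)
  if (W %% 2L^spec$head_blocks != 0L) {
    stop("block width ", W, " is not divisible by 2^", spec$head_blocks,
         call. = FALSE)
  }
  c(W %/% 2L^spec$head_blocks, spec$head_widths[spec$head_blocks])
}

conv_ops <- function(conv_type) {
  if (conv_type == "separable") {
    list(init = sepconv1d_init, fwd = sepconv1d_forward, bwd = sepconv1d_backward)
  } else {
    list(init = conv1d_init, fwd = conv1d_forward, bwd = conv1d_backward)
  }
}

head_init <- function(spec) {
  head_output_shape(spec)  # validates divisibility at build time
  ops <- conv_ops(spec$conv_type)
  c_in <- spec$input_shape[2L]
  blocks <- vector("list", spec$head_blocks)
  for (i in seq_len(spec$head_blocks)) {
    w <- spec$head_widths[i]
    blk <- list(c1 = ops$init(spec$kernel_size, c_in, w),
                c2 = ops$init(spec$kernel_size, w, w))
    if (c_in != w) blk$proj <- conv1d_init(1L, c_in, w)  # 1x1 skip projection
    blocks[[i]] <- blk
    c_in <- w
  }
  list(blocks = blocks)
}

# One block: conv -> activation -> conv -> additive skip -> pool(stride 2).
head_forward <- function(params, spec, x) {
  ops <- conv_ops(spec$conv_type)
  caches <- vector("list", spec$head_blocks)
  for (i in seq_len(spec$head_blocks)) {
    blk <- params$blocks[[i]]
    f1 <- ops$fwd(blk$c1, x)
    a1 <- act_forward(spec$activation, f1$y)
    f2 <- ops$fwd(blk$c2, a1$y)
    if (!is.null(blk$proj)) {
      fp <- conv1d_forward(blk$proj, x)
      r <- f2$y + fp$y
      proj_cache <- fp$cache
    } else {
      r <- f2$y + x
      proj_cache <- NULL
    }
    pl <- pool_forward(r, spec$pooling)
    caches[[i]] <- list(c1 = f1$cache, a1 = a1$cache, c2 = f2$cache,
                        proj = proj_cache, pool = pl$cache)
    x <- pl$y
  }
  list(y = x, caches = caches)
}

head_backward <- function(params, spec, caches, dy) {
  ops <- conv_ops(spec$conv_type)
  gblocks <- vector("list", spec$head_blocks)
  for (i in rev(seq_len(spec$head_blocks))) {
    blk <- params$blocks[[i]]
    cc <- caches[[i]]
    dr <- pool_backward(cc$pool, dy)
    g2 <- ops$bwd(blk$c2, cc$c2, dr)
    da1 <- act_backward(spec$activation, cc$a1, g2$dx)
    g1 <- ops$bwd(blk$c1, cc$c1, da1)
    gb <- list(c1 = g1$grads, c2 = g2$grads)
    if (!is.null(blk$proj)) {
      gp <- conv1d_backward(blk$proj, cc$proj, dr)
      gb$proj <- gp$grads
      dy <- g1$dx + gp$dx
    } else {
      dy <- g1$dx + dr
    }
    gblocks[[i]] <- gb
  }
  list(grads = list(blocks = gblocks), dx = dy)
}

sub_init <- function(spec, in_dim) {
  ops <- rnn_ops(spec$recurrent_cell)
  layers <- vector("list", spec$recurrent_layers)
  for (j in seq_len(spec$recurrent_layers)) {
    layers[[j]] <- ops$init(in_dim, spec$recurrent_widths[j])
    in_dim <- spec$recurrent_widths[j] * ops$out_mult
  }
  list(rnn = layers, out = dense_init(in_dim, 1L))
}

sub_forward <- function(params, spec, feat, train = FALSE) {
  ops <- rnn_ops(spec$recurrent_cell)
  L <- spec$recurrent_layers
  rnn_caches <- vector("list", L)
  y <- feat
  for (j in seq_len(L)) {
    rr <- ops$fwd(params$rnn[[j]], y, return_seq = j < L)
    rnn_caches[[j]] <- rr$cache
    y <- rr$y
  }
  dp <- dropout_forward(y, spec$dropout_rate, train)
  dn <- dense_forward(params$out, dp$y)
  p <- sigmoid(dn$y[, 1L])
  list(score = p,
       cache = list(rnn = rnn_caches, drop = dp$cache, dense = dn$cache, p = p))
}

# dlogit: gradient of the loss w.r.t. the pre-sigmoid output, length N.
sub_backward <- function(params, spec, cache, dlogit) {
  ops <- rnn_ops(spec$recurrent_cell)
  L <- spec$recurrent_layers
  gd <- dense_backward(params$out, cache$dense, matrix(dlogit, ncol = 1L))
  dy <- dropout_backward(cache$drop, gd$dx)
  grnn <- vector("list", L)
  for (j in rev(seq_len(L))) {
    gr <- ops$bwd(params$rnn[[j]], cache$rnn[[j]], dy)
    grnn[[j]] <- gr$grads
    dy <- gr$dx
  }
  list(grads = list(rnn = grnn, out = gd$grads), dfeat = dy)
}

#' Build the shared convolutional head model
#'
#' The head acts as a feature extractor: it turns an input block into an
#' abstract temporal feature map that all ensemble sub-models consume.
#'
#' @param spec An [ensemble_spec()].
#' @return A `head_model` with initialized parameters; apply it with
#'   [head_features()].
#' @export
build_head_model <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  structure(list(spec = spec, params = head_init(spec)), class = "head_model")
}

#' Compute the head feature map for a batch of blocks
#'
#' @param head A `head_model` (or a full `fall_ensemble`).
#' @param x Array `N x W x C` of input blocks.
#' @return Array `N x T' x C'` feature map.
#' @export
head_features <- function(head, x) {
  if (inherits(head, "fall_ensemble")) {
    return(head_forward(head$params$head, head$spec, x)$y)
  }
  stopifnot(inherits(head, "head_model"))
  head_forward(head$params, head$spec, x)$y
}

#' Build the class-based ensemble model
#'
#' One recurrent binary sub-model per event class, all reading the shared
#' head's feature map; each sub-model ends in a single sigmoid unit, so its
#' output is a one-vs-rest probability for its class. Sub-model parameters
#' are pairwise disjoint outside the shared head.
#'
#' @param spec An [ensemble_spec()].
#' @return A `fall_ensemble` with freshly initialized parameters.
#' @export
build_class_ensemble <- function(spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  feat_dim <- head_output_shape(spec)[2L]
  structure(
    list(spec = spec,
         params = list(
           head = head_init(spec),
           subs = lapply(seq_len(spec$n_classes),
                         function(i) sub_init(spec, feat_dim))
         )),
    class = "fall_ensemble"
  )
}

ensemble_forward <- function(model, x, train = FALSE) {
  spec <- model$spec
  hf <- head_forward(model$params$head, spec, x)
  n <- spec$n_classes
  N <- dim(x)[1L]
  scores <- matrix(0, N, n)
  sub_caches <- vector("list", n)
  for (i in seq_len(n)) {
    sf <- sub_forward(model$params$subs[[i]], spec, hf$y, train)
    scores[, i] <- sf$score
    sub_caches[[i]] <- sf$cache
  }
  list(scores = scores, head_cache = hf$caches, sub_caches = sub_caches)
}

# dlogits: N x n_classes matrix of loss gradients w.r.t. pre-sigmoid outputs.
ensemble_backward <- function(model, fw, dlogits) {
  spec <- model$spec
  n <- spec$n_classes
  gsubs <- vector("list", n)
  dfeat <- NULL
  for (i in seq_len(n)) {
    sb <- sub_backward(model$params$subs[[i]], spec, fw$sub_caches[[i]],
                       dlogits[, i])
    gsubs[[i]] <- sb$grads
    dfeat <- if (is.null(dfeat)) sb$dfeat else dfeat + sb$dfeat
  }
  hb <- head_backward(model$params$head, spec, fw$head_cache, dfeat)
  list(grads = list(head = hb$grads, subs = gsubs), dx = hb$dx)
}

#' Per-class one-vs-rest scores for a batch of blocks
#'
#' @param model A trained (or freshly built) `fall_ensemble`.
#' @param x Array `N x W x C`, or a `block_dataset`.
#' @param batch_size Forward-pass chunk size (memory bound only).
#' @return `N x n_classes` matrix of sigmoid scores in `[0, 1]`, columns
#'   named after the classes.
#' @export
predict_scores <- function(model, x, batch_size = 512L) {
  stopifnot(inherits(model, "fall_ensemble"))
  if (inherits(x, "block_dataset")) x <- x$samples
  stopifnot(length(dim(x)) == 3L)
  N <- dim(x)[1L]
  out <- matrix(0, N, model$spec$n_classes)
  for (start in seq.int(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    out[idx, ] <- ensemble_forward(model, x[idx, , , drop = FALSE])$scores
  }
  if (model$spec$n_classes == 3L) colnames(out) <- names(class_labels())
  out
}

#' Argmax fusion of the class-based ensemble
#'
#' The predicted class is the one whose sub-model score is maximal; ties
#' among maxima are broken by severity priority.
#'
#' @param scores Numeric vector of one score per class, or an `N x n` matrix.
#' @param priority Tie-break priority over class codes.
#' @return Class label code(s).
#' @export
fuse_proposed <- function(scores, priority = default_tie_break()) {
  if (is.matrix(scores)) {
    return(vapply(seq_len(nrow(scores)),
                  function(i) argmax_with_priority(scores[i, ], priority), 0L))
  }
  argmax_with_priority(scores, priority)
}

#' Weighted-average fusion
#'
#' Argmax of element-wise weighted scores; with unit weights this reduces to
#' [fuse_proposed()].
#'
#' @param scores Numeric vector or `N x n` matrix of per-class scores.
#' @param weights Non-negative weight per class.
#' @param priority Tie-break priority over class codes.
#' @return Class label code(s).
#' @export
fuse_weighted_average <- function(scores, weights,
                                  priority = default_tie_break()) {
  n <- if (is.matrix(scores)) ncol(scores) else length(scores)
  if (length(weights) != n) stop("weights length must match class count",
                                 call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (is.matrix(scores)) {
    fuse_proposed(sweep(scores, 2L, weights, `*`), priority)
  } else {
    fuse_proposed(scores * weights, priority)
  }
}

#' Build the stacked-ensemble reference variant
#'
#' Reference combiner for comparison experiments: `n_classes` recurrent
#' sub-models read the raw block directly, and their concatenated sigmoid
#' outputs feed a final dense softmax learner.
#'
#' @param spec An [ensemble_spec()].
#' @return A `stacked_ensemble`.
#' @export
build_stacked_ensemble <- function(spec = ensemble_spec()) {
  stopifnot(inherits(spec, "ensemble_spec"))
  n <- spec$n_classes
  structure(
    list(spec = spec,
         params = list(
           subs = lapply(seq_len(n), function(i) sub_init(spec, spec$input_shape[2L])),
           combiner = dense_init(n, n)
         )),
    class = "stacked_ensemble"
  )
}

#' Softmax class probabilities of the stacked ensemble
#'
#' @param model A `stacked_ensemble`.
#' @param x Array `N x W x C` or `block_dataset`.
#' @return `N x n_classes` matrix of probabilities summing to 1 per row.
#' @export
predict_stacked <- function(model, x) {
  stopifnot(inherits(model, "stacked_ensemble"))
  if (inherits(x, "block_dataset")) x <- x$samples
  spec <- model$spec
  n <- spec$n_classes
  s <- vapply(seq_len(n), function(i) {
    sub_forward(model$params$subs[[i]], spec, x)$score
  }, numeric(dim(x)[1L]))
  s <- matrix(s, ncol = n)
  z <- dense_forward(model$params$combiner, s)$y
  e <- exp(z - apply(z, 1L, max))
  e / rowSums(e)
}
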