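# Core tensor layers of the network engine.
#
# Batched sequences are stored as arrays of dim (N, T, C): batch, time,
# channels. R's column-major layout makes the (N*T, C) matrix view of such an
# array free (just a dim change), so every layer reduces to dense matrix
# products: convolutions use an im2col expansion (one large GEMM per pass,
# with the input gradient computed as a correlation against the flipped
# kernel rather than by scatter-add). All backward passes are hand-derived
# and verified against finite-difference oracles in the test suite.

## --- parameter-tree utilities -------------------------------------------

tree_map <- function(x, f) {
  if (is.numeric(x)) return(f(x))
  out <- lapply(x, tree_map, f = f)
  names(out) <- names(x)
  out
}

tree_map2 <- function(x, y, f) {
  if (is.numeric(x)) return(f(x, y))
  out <- vector("list", length(x))
  names(out) <- names(x)
  for (i in seq_along(x)) out[[i]] <- tree_map2(x[[i]], y[[i]], f)
  out
}

tree_add <- function(x, y) tree_map2(x, y, `+`)

#' Total number of trainable parameters in a parameter tree or model
#'
#' @param x A model built by [build_class_ensemble()] /
#'   [build_stacked_ensemble()] / [build_head_model()], or any nested list of
#'   numeric arrays.
#' @return Integer parameter count.
#' @export
count_params <- function(x) {
  if (is.numeric(x)) return(length(x))
  if (inherits(x, c("fall_ensemble", "stacked_ensemble", "head_model"))) {
    return(count_params(x$params))
  }
  if (is.list(x)) return(sum(vapply(x, count_params, 0)))
  0L
}

## --- initialization ------------------------------------------------------

glorot <- function(dims, fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

# add a row vector to every row of a matrix without sweep/aperm
addrow <- function(m, b) m + rep(b, each = nrow(m))

## --- activations ---------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

act_forward <- function(name, x) {
  switch(name,
    relu  = list(y = pmax(x, 0), cache = list(x = x)),
    swish = {
      s <- sigmoid(x)
      list(y = x * s, cache = list(s = s, x = x))
    },
    stop("unknown activation: ", name)
  )
}

act_backward <- function(name, cache, dy) {
  switch(name,
    relu  = dy * (cache$x > 0),
    swish = {
      s <- cache$s
      dy * (s * (1 + cache$x * (1 - s)))
    }
  )
}

## --- 1-D convolution (standard) -----------------------------------------

# forward/backward kernels live in src/conv_ops.cpp; caches keep only the
# layer input (and, for separable, the depthwise intermediate).

conv1d_init <- function(K, C, F_) {
  list(W = glorot(c(K, C, F_), K * C, K * F_), b = numeric(F_))
}

# 'same' padding, stride 1, odd kernel
conv1d_forward <- function(p, x) {
  d <- dim(x)
  y <- .conv_fwd(x, d, p$W, dim(p$W), p$b)
  list(y = y, cache = list(x = x, d = d))
}

conv1d_backward <- function(p, cache, dy) {
  g <- .conv_bwd(cache$x, cache$d, p$W, dim(p$W), dy)
  list(grads = list(W = g$W, b = g$b), dx = g$dx)
}

## --- 1-D separable convolution ------------------------------------------

# depthwise (one K-tap filter per input channel) followed by pointwise 1x1
sepconv1d_init <- function(K, C, F_) {
  list(
    dw = glorot(c(K, C), K, K),
    pw = glorot(c(C, F_), C, F_),
    b  = numeric(F_)
  )
}

sepconv1d_forward <- function(p, x) {
  d <- dim(x)
  r <- .sepconv_fwd(x, d, p$dw, p$pw, p$b)
  list(y = r$y, cache = list(x = x, z = r$z, d = d))
}

sepconv1d_backward <- function(p, cache, dy) {
  g <- .sepconv_bwd(cache$x, cache$d, p$dw, p$pw, cache$z, dy)
  list(grads = list(dw = g$dw, pw = g$pw, b = g$b), dx = g$dx)
}

## --- pooling (size 2, stride 2) -----------------------------------------

pool_forward <- function(x, type = c("max", "average")) {
  type <- match.arg(type)
  d <- dim(x); T_ <- d[2L]
  stopifnot(T_ %% 2L == 0L)
  a <- x[, seq.int(1L, T_, 2L), , drop = FALSE]
  b <- x[, seq.int(2L, T_, 2L), , drop = FALSE]
  if (type == "max") {
    mask <- a >= b   # ties route to the earlier timestep
    list(y = pmax(a, b), cache = list(mask = mask, T_ = T_, type = type))
  } else {
    list(y = (a + b) / 2, cache = list(T_ = T_, type = type))
  }
}

pool_backward <- function(cache, dy) {
  d <- dim(dy)
  dx <- array(0, c(d[1L], cache$T_, d[3L]))
  if (cache$type == "max") {
    dx[, seq.int(1L, cache$T_, 2L), ] <- dy * cache$mask
    dx[, seq.int(2L, cache$T_, 2L), ] <- dy * !cache$mask
  } else {
    dx[, seq.int(1L, cache$T_, 2L), ] <- dy / 2
    dx[, seq.int(2L, cache$T_, 2L), ] <- dy / 2
  }
  dx
}

## --- dense ---------------------------------------------------------------

dense_init <- function(I, O) list(W = glorot(c(I, O), I, O), b = numeric(O))

dense_forward <- function(p, x) {
  list(y = addrow(x %*% p$W, p$b), cache = list(x = x))
}

dense_backward <- function(p, cache, dy) {
  list(grads = list(W = crossprod(cache$x, dy), b = colSums(dy)),
       dx = dy %*% t(p$W))
}

## --- dropout (inverted) --------------------------------------------------

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  mask <- (matrix(stats::runif(length(x)), nrow(x), ncol(x)) >= rate) / (1 - rate)
  list(y = x * mask, cache = mask)
}

dropout_backward <- function(cache, dy) {
  if (is.null(cache)) dy else dy * cache
}

## --- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = tree_map(params, function(p) p * 0),
       v = tree_map(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g * g)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = tree_map2(params, upd, `-`), state = state)
}
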