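# Recurrent layers: LSTM, GRU, and bidirectional LSTM, with full
# backpropagation through time. The input projection (x W_x) and all weight
# gradients are computed as single batched GEMMs outside the time loop; only
# the hidden-state recursion runs step by step. Parameter layout matches the
# usual closed-form counts: LSTM 4*(H*(H+I)+H), GRU 3*(H*(H+I)+H), BiLSTM
# twice the LSTM count. The LSTM forget-gate bias is initialized to 1.

lstm_init <- function(I, H) {
  b <- numeric(4L * H)
  b[(H + 1L):(2L * H)] <- 1   # forget-gate bias
  list(Wx = glorot(c(I, 4L * H), I, H),
       Wh = glorot(c(H, 4L * H), H, H),
       b  = b)
}

lstm_forward <- function(p, x, return_seq = TRUE) {
  d <- dim(x); N <- d[1L]; T_ <- d[2L]; I <- d[3L]
  H <- ncol(p$Wh) / 4L
  X2 <- x; dim(X2) <- c(N * T_, I)
  XW <- addrow(X2 %*% p$Wx, p$b)               # (N*T, 4H)
  iH <- seq_len(H); fH <- H + iH; gH <- 2L * H + iH; oH <- 3L * H + iH
  h <- matrix(0, N, H); cc <- matrix(0, N, H)
  Gi <- array(0, c(N, T_, H)); Gf <- Gi; Gg <- Gi; Go <- Gi
  Cc <- Gi; Tc <- Gi; Hs <- Gi
  for (t in seq_len(T_)) {
    rt <- ((t - 1L) * N + 1L):(t * N)
    a <- XW[rt, , drop = FALSE] + h %*% p$Wh
    gi <- sigmoid(a[, iH, drop = FALSE])
    gf <- sigmoid(a[, fH, drop = FALSE])
    gg <- tanh(a[, gH, drop = FALSE])
    go <- sigmoid(a[, oH, drop = FALSE])
    cc <- gf * cc + gi * gg
    tc <- tanh(cc)
    h <- go * tc
    Gi[, t, ] <- gi; Gf[, t, ] <- gf; Gg[, t, ] <- gg; Go[, t, ] <- go
    Cc[, t, ] <- cc; Tc[, t, ] <- tc; Hs[, t, ] <- h
  }
  list(y = if (return_seq) Hs else h,
       cache = list(X2 = X2, Gi = Gi, Gf = Gf, Gg = Gg, Go = Go,
                    Cc = Cc, Tc = Tc, Hs = Hs,
                    N = N, T_ = T_, I = I, H = H, return_seq = return_seq))
}

# dy: (N,T,H) array when the layer returned a sequence, else (N,H) matrix
# applied at the final step.
lstm_backward <- function(p, cache, dy) {
  N <- cache$N; T_ <- cache$T_; I <- cache$I; H <- cache$H
  dA <- array(0, c(N, T_, 4L * H))
  dh_next <- matrix(0, N, H); dc_next <- matrix(0, N, H)
  tWh <- t(p$Wh)
  for (t in rev(seq_len(T_))) {
    dh <- dh_next
    if (cache$return_seq) {
      dh <- dh + matrix(dy[, t, ], N, H)
    } else if (t == T_) {
      dh <- dh + dy
    }
    gi <- matrix(cache$Gi[, t, ], N, H); gf <- matrix(cache$Gf[, t, ], N, H)
    gg <- matrix(cache$Gg[, t, ], N, H); go <- matrix(cache$Go[, t, ], N, H)
    tc <- matrix(cache$Tc[, t, ], N, H)
    cprev <- if (t > 1L) matrix(cache$Cc[, t - 1L, ], N, H) else matrix(0, N, H)
    do_ <- dh * tc * go * (1 - go)
    dc <- dh * go * (1 - tc^2) + dc_next
    di <- dc * gg * gi * (1 - gi)
    df <- dc * cprev * gf * (1 - gf)
    dg <- dc * gi * (1 - gg^2)
    da <- cbind(di, df, dg, do_)
    dA[, t, ] <- da
    dh_next <- da %*% tWh
    dc_next <- dc * gf
  }
  dAm <- dA; dim(dAm) <- c(N * T_, 4L * H)
  Hp <- array(0, c(N, T_, H))
  if (T_ > 1L) Hp[, 2:T_, ] <- cache$Hs[, 1:(T_ - 1L), ]
  dim(Hp) <- c(N * T_, H)
  dx <- dAm %*% t(p$Wx)
  dim(dx) <- c(N, T_, I)
  list(grads = list(Wx = crossprod(cache$X2, dAm),
                    Wh = crossprod(Hp, dAm),
                    b = colSums(dAm)),
       dx = dx)
}

gru_init <- function(I, H) {
  list(Wx = glorot(c(I, 3L * H), I, H),
       Wh = glorot(c(H, 3L * H), H, H),
       b  = numeric(3L * H))
}

gru_forward <- function(p, x, return_seq = TRUE) {
  d <- dim(x); N <- d[1L]; T_ <- d[2L]; I <- d[3L]
  H <- ncol(p$Wh) / 3L
  zH <- seq_len(H); rH <- H + zH; nH <- 2L * H + zH
  X2 <- x; dim(X2) <- c(N * T_, I)
  XW <- addrow(X2 %*% p$Wx, p$b)               # (N*T, 3H)
  Wh_zr <- p$Wh[, c(zH, rH), drop = FALSE]
  Whn <- p$Wh[, nH, drop = FALSE]
  h <- matrix(0, N, H)
  Z <- array(0, c(N, T_, H)); R <- Z; Nn <- Z; RH <- Z; Hs <- Z
  for (t in seq_len(T_)) {
    rt <- ((t - 1L) * N + 1L):(t * N)
    azr <- XW[rt, c(zH, rH), drop = FALSE] + h %*% Wh_zr
    z <- sigmoid(azr[, seq_len(H), drop = FALSE])
    r <- sigmoid(azr[, H + seq_len(H), drop = FALSE])
    rh <- r * h
    n <- tanh(XW[rt, nH, drop = FALSE] + rh %*% Whn)
    h_new <- (1 - z) * n + z * h
    Z[, t, ] <- z; R[, t, ] <- r; Nn[, t, ] <- n; RH[, t, ] <- rh
    h <- h_new
    Hs[, t, ] <- h
  }
  list(y = if (return_seq) Hs else h,
       cache = list(X2 = X2, Z = Z, R = R, Nn = Nn, RH = RH, Hs = Hs,
                    N = N, T_ = T_, I = I, H = H, return_seq = return_seq))
}

gru_backward <- function(p, cache, dy) {
  N <- cache$N; T_ <- cache$T_; I <- cache$I; H <- cache$H
  zH <- seq_len(H); rH <- H + zH; nH <- 2L * H + zH
  Wh_zr <- p$Wh[, c(zH, rH), drop = FALSE]
  Whn <- p$Wh[, nH, drop = FALSE]
  tWh_zr <- t(Wh_zr); tWhn <- t(Whn)
  dA <- array(0, c(N, T_, 3L * H))
  dh_next <- matrix(0, N, H)
  for (t in rev(seq_len(T_))) {
    dh <- dh_next
    if (cache$return_seq) {
      dh <- dh + matrix(dy[, t, ], N, H)
    } else if (t == T_) {
      dh <- dh + dy
    }
    z <- matrix(cache$Z[, t, ], N, H); r <- matrix(cache$R[, t, ], N, H)
    n <- matrix(cache$Nn[, t, ], N, H)
    hprev <- if (t > 1L) matrix(cache$Hs[, t - 1L, ], N, H) else matrix(0, N, H)
    dz <- dh * (hprev - n) * z * (1 - z)
    dan <- dh * (1 - z) * (1 - n^2)
    drh <- dan %*% tWhn
    dar <- drh * hprev * r * (1 - r)
    dA[, t, ] <- cbind(dz, dar, dan)
    dh_next <- dh * z + cbind(dz, dar) %*% tWh_zr + drh * r
  }
  dAm <- dA; dim(dAm) <- c(N * T_, 3L * H)
  Hp <- array(0, c(N, T_, H))
  if (T_ > 1L) Hp[, 2:T_, ] <- cache$Hs[, 1:(T_ - 1L), ]
  dim(Hp) <- c(N * T_, H)
  RHm <- cache$RH; dim(RHm) <- c(N * T_, H)
  dWh <- matrix(0, H, 3L * H)
  dWh[, c(zH, rH)] <- crossprod(Hp, dAm[, c(zH, rH), drop = FALSE])
  dWh[, nH] <- crossprod(RHm, dAm[, nH, drop = FALSE])
  dx <- dAm %*% t(p$Wx)
  dim(dx) <- c(N, T_, I)
  list(grads = list(Wx = crossprod(cache$X2, dAm),
                    Wh = dWh,
                    b = colSums(dAm)),
       dx = dx)
}

bilstm_init <- function(I, H) {
  list(fwd = lstm_init(I, H), bwd = lstm_init(I, H))
}

rev_time <- function(x) {
  x[, rev(seq_len(dim(x)[2L])), , drop = FALSE]
}

# output width is 2H: forward and backward passes concatenated
bilstm_forward <- function(p, x, return_seq = TRUE) {
  ff <- lstm_forward(p$fwd, x, return_seq)
  bb <- lstm_forward(p$bwd, rev_time(x), return_seq)
  if (return_seq) {
    H <- ff$cache$H
    d <- dim(ff$y)
    y <- array(0, c(d[1L], d[2L], 2L * H))
    y[, , seq_len(H)] <- ff$y
    y[, , H + seq_len(H)] <- rev_time(bb$y)
  } else {
    y <- cbind(ff$y, bb$y)
  }
  list(y = y, cache = list(f = ff$cache, b = bb$cache, H = ff$cache$H,
                           return_seq = return_seq))
}

bilstm_backward <- function(p, cache, dy) {
  H <- cache$H
  if (cache$return_seq) {
    dyf <- dy[, , seq_len(H), drop = FALSE]
    dyb <- rev_time(dy[, , H + seq_len(H), drop = FALSE])
  } else {
    dyf <- dy[, seq_len(H), drop = FALSE]
    dyb <- dy[, H + seq_len(H), drop = FALSE]
  }
  gf <- lstm_backward(p$fwd, cache$f, dyf)
  gb <- lstm_backward(p$bwd, cache$b, dyb)
  list(grads = list(fwd = gf$grads, bwd = gb$grads),
       dx = gf$dx + rev_time(gb$dx))
}

rnn_ops <- function(cell) {
  switch(cell,
    lstm   = list(init = lstm_init, fwd = lstm_forward, bwd = lstm_backward,
                  out_mult = 1L),
    gru    = list(init = gru_init, fwd = gru_forward, bwd = gru_backward,
                  out_mult = 1L),
    bilstm = list(init = bilstm_init, fwd = bilstm_forward, bwd = bilstm_backward,
                  out_mult = 2L),
    stop("unknown recurrent cell: ", cell)
  )
}
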