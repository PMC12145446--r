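# Bidirectional LSTM over short day sequences, with backpropagation through
# time. Direction parameters: W (D x 4H input), U (H x 4H recurrent),
# b (4H); gate column order [input | forget | cell | output].

init_lstm_dir <- function(d, h) {
  b <- rep(0, 4 * h)
  b[h + 1:h] <- 1   # forget-gate bias 1, the usual LSTM stabilisation
  list(W = tn_mat(d, 4 * h), U = tn_mat(h, 4 * h), b = b)
}

# X: T x D. Returns final hidden state (length H) and per-step cache.
lstm_dir_fwd <- function(X, p) {
  h_dim <- nrow(p$U)
  tt <- nrow(X)
  h <- numeric(h_dim)
  cc <- numeric(h_dim)
  steps <- vector("list", tt)
  for (t in seq_len(tt)) {
    z <- drop(X[t, ] %*% p$W + h %*% p$U) + p$b
    i <- sigmoid(z[1:h_dim])
    f <- sigmoid(z[h_dim + 1:h_dim])
    g <- tanh(z[2 * h_dim + 1:h_dim])
    o <- sigmoid(z[3 * h_dim + 1:h_dim])
    c_prev <- cc
    h_prev <- h
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, tc = tc,
                       c_prev = c_prev, h_prev = h_prev)
  }
  list(h = h, cache = list(steps = steps, X = X))
}

# dh_final: gradient wrt the final hidden state.
lstm_dir_bwd <- function(dh_final, cache, p) {
  X <- cache$X
  tt <- nrow(X)
  h_dim <- length(dh_final)
  dW <- p$W * 0; dU <- p$U * 0; db <- p$b * 0
  dX <- X * 0
  dh <- dh_final
  dc <- numeric(h_dim)
  for (t in rev(seq_len(tt))) {
    s <- cache$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dc <- dc * s$f
    dz <- c(di * s$i * (1 - s$i),
            df * s$f * (1 - s$f),
            dg * (1 - s$g^2),
            do * s$o * (1 - s$o))
    dW <- dW + outer(X[t, ], dz)
    dU <- dU + outer(s$h_prev, dz)
    db <- db + dz
    dX[t, ] <- p$W %*% dz
    dh <- drop(p$U %*% dz)
  }
  list(dX = dX, g = list(W = dW, U = dU, b = db))
}

# Bi-LSTM pooling: concatenated final forward and final backward hidden
# states (feature length 2H).
bilstm_fwd <- function(X, p) {
  fw <- lstm_dir_fwd(X, p$f)
  bw <- lstm_dir_fwd(X[rev(seq_len(nrow(X))), , drop = FALSE], p$b)
  list(h = c(fw$h, bw$h), cache = list(fw = fw$cache, bw = bw$cache))
}

bilstm_bwd <- function(dh, cache, p) {
  h_dim <- length(dh) / 2
  fw <- lstm_dir_bwd(dh[1:h_dim], cache$fw, p$f)
  bw <- lstm_dir_bwd(dh[h_dim + 1:h_dim], cache$bw, p$b)
  dX <- fw$dX + bw$dX[rev(seq_len(nrow(bw$dX))), , drop = FALSE]
  list(dX = dX, g = list(f = fw$g, b = bw$g))
}
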