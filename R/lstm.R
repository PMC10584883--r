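# Bidirectional LSTM sequence network: forward pass, backpropagation
# through time, and parameter utilities. Written against plain R matrices;
# a batch is an array with dims (B, T, F) and a boolean mask (B, T) marks
# real (non-padded) positions. Gate order inside the fused weight matrices
# is input, forget, cell, output.

sigmoid <- function(x) 1 / (1 + exp(-x))

slice_t <- function(A, t) {
  d <- dim(A)
  matrix(A[, t, ], d[1], d[3])
}

# flat named parameter list for one model
init_lstm_params <- function(n_features, hidden, n_layers, n_classes) {
  params <- list()
  uinit <- function(nr, nc) {
    lim <- 1 / sqrt(nr)
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  d_in <- n_features
  for (l in seq_len(n_layers)) {
    for (dir in c("fwd", "bwd")) {
      key <- sprintf("l%d.%s.", l, dir)
      params[[paste0(key, "W")]] <- uinit(d_in, 4 * hidden)
      params[[paste0(key, "U")]] <- uinit(hidden, 4 * hidden)
      b <- numeric(4 * hidden)
      b[(hidden + 1):(2 * hidden)] <- 1   # forget-gate bias
      params[[paste0(key, "b")]] <- b
    }
    d_in <- 2 * hidden
  }
  params[["fc.W"]] <- uinit(d_in, n_classes)
  params[["fc.b"]] <- numeric(n_classes)
  params
}

# one direction of one LSTM layer over a (B, T, D) input
lstm_dir_forward <- function(X, W, U, b, reverse = FALSE) {
  d <- dim(X); B <- d[1]; T_ <- d[2]; H <- nrow(U)
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  Hs <- array(0, c(B, T_, H))
  I <- array(0, c(B, T_, H)); Fg <- I; G <- I; O <- I
  TC <- I; Cprev <- I; Hprev <- I
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  bm <- matrix(b, B, 4 * H, byrow = TRUE)
  for (t in ord) {
    Cprev[, t, ] <- cc; Hprev[, t, ] <- h
    Z <- slice_t(X, t) %*% W + h %*% U + bm
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    cc <- f * cc + i * g
    tc <- tanh(cc)
    h <- o * tc
    I[, t, ] <- i; Fg[, t, ] <- f; G[, t, ] <- g; O[, t, ] <- o
    TC[, t, ] <- tc; Hs[, t, ] <- h
  }
  list(H = Hs, cache = list(I = I, Fg = Fg, G = G, O = O, TC = TC,
                            Cprev = Cprev, Hprev = Hprev, ord = ord))
}

lstm_dir_backward <- function(dH, X, W, U, cache) {
  d <- dim(X); B <- d[1]; T_ <- d[2]; D <- d[3]; H <- nrow(U)
  dW <- matrix(0, D, 4 * H); dU <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dX <- array(0, c(B, T_, D))
  dh_rec <- matrix(0, B, H); dc_rec <- matrix(0, B, H)
  for (t in rev(cache$ord)) {
    i <- slice_t(cache$I, t); f <- slice_t(cache$Fg, t)
    g <- slice_t(cache$G, t); o <- slice_t(cache$O, t)
    tc <- slice_t(cache$TC, t)
    cprev <- slice_t(cache$Cprev, t); hprev <- slice_t(cache$Hprev, t)
    dh <- slice_t(dH, t) + dh_rec
    do_ <- dh * tc
    dtc <- dh * o * (1 - tc^2) + dc_rec
    dc_rec <- dtc * f
    di <- dtc * g; df <- dtc * cprev; dg <- dtc * i
    dZ <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do_ * o * (1 - o))
    xt <- slice_t(X, t)
    dW <- dW + crossprod(xt, dZ)
    dU <- dU + crossprod(hprev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- dZ %*% t(W)
    dh_rec <- dZ %*% t(U)
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# full network forward: returns probabilities (B, T, C) and caches for BPTT
network_forward <- function(params, X, config, train = FALSE,
                            dropout_masks = NULL) {
  n_layers <- config$n_bilstm_layers
  caches <- vector("list", n_layers)
  inp <- X
  for (l in seq_len(n_layers)) {
    fwd <- lstm_dir_forward(inp, params[[sprintf("l%d.fwd.W", l)]],
                            params[[sprintf("l%d.fwd.U", l)]],
                            params[[sprintf("l%d.fwd.b", l)]], reverse = FALSE)
    bwd <- lstm_dir_forward(inp, params[[sprintf("l%d.bwd.W", l)]],
                            params[[sprintf("l%d.bwd.U", l)]],
                            params[[sprintf("l%d.bwd.b", l)]], reverse = TRUE)
    d <- dim(fwd$H)
    out <- array(0, c(d[1], d[2], 2 * d[3]))
    out[, , seq_len(d[3])] <- fwd$H
    out[, , d[3] + seq_len(d[3])] <- bwd$H
    if (train && config$dropout_rate > 0) {
      out <- out * dropout_masks[[l]]
    }
    caches[[l]] <- list(fwd = fwd, bwd = bwd, input = inp, out_dim = dim(out))
    inp <- out
  }
  d <- dim(inp); B <- d[1]; T_ <- d[2]; Fh <- d[3]
  flat <- inp; dim(flat) <- c(B * T_, Fh)
  logits <- flat %*% params[["fc.W"]] +
    matrix(params[["fc.b"]], B * T_, config$n_classes, byrow = TRUE)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs_flat <- e / rowSums(e)
  probs <- array(probs_flat, c(B, T_, config$n_classes))
  list(probs = probs, caches = caches, top = inp)
}

# backward from dLogits (B*T, C); returns flat named gradient list
network_backward <- function(params, config, fwd_out, dlogits_flat,
                             dropout_masks = NULL) {
  n_layers <- config$n_bilstm_layers
  top <- fwd_out$top
  d <- dim(top); B <- d[1]; T_ <- d[2]; Fh <- d[3]
  flat <- top; dim(flat) <- c(B * T_, Fh)
  grads <- list()
  grads[["fc.W"]] <- crossprod(flat, dlogits_flat)
  grads[["fc.b"]] <- colSums(dlogits_flat)
  dtop_flat <- dlogits_flat %*% t(params[["fc.W"]])
  dOut <- array(dtop_flat, c(B, T_, Fh))
  for (l in rev(seq_len(n_layers))) {
    cache <- fwd_out$caches[[l]]
    if (!is.null(dropout_masks) && config$dropout_rate > 0) {
      dOut <- dOut * dropout_masks[[l]]
    }
    H <- dim(cache$fwd$H)[3]
    dHf <- dOut[, , seq_len(H), drop = FALSE]
    dHb <- dOut[, , H + seq_len(H), drop = FALSE]
    bf <- lstm_dir_backward(dHf, cache$input, params[[sprintf("l%d.fwd.W", l)]],
                            params[[sprintf("l%d.fwd.U", l)]], cache$fwd$cache)
    bb <- lstm_dir_backward(dHb, cache$input, params[[sprintf("l%d.bwd.W", l)]],
                            params[[sprintf("l%d.bwd.U", l)]], cache$bwd$cache)
    grads[[sprintf("l%d.fwd.W", l)]] <- bf$dW
    grads[[sprintf("l%d.fwd.U", l)]] <- bf$dU
    grads[[sprintf("l%d.fwd.b", l)]] <- bf$db
    grads[[sprintf("l%d.bwd.W", l)]] <- bb$dW
    grads[[sprintf("l%d.bwd.U", l)]] <- bb$dU
    grads[[sprintf("l%d.bwd.b", l)]] <- bb$db
    dOut <- bf$dX + bb$dX
  }
  grads
}

global_grad_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

clip_gradients <- function(grads, threshold) {
  nrm <- global_grad_norm(grads)
  if (nrm > threshold) {
    grads <- lapply(grads, function(g) g * (threshold / nrm))
    nrm <- threshold
  }
  list(grads = grads, norm = nrm)
}
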