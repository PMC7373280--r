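# Minimal neural-network engine: 1D convolution, max pooling, LSTM,
# inverted dropout, dense softmax, Adam. Written against base R matrix ops;
# everything is deterministic given the RNG state, and backward passes are
# verified against numerical gradients in the test suite.
#
# Array layout: activations are N x L x C arrays (batch, time, channels).
# Conv weights are (k * C_in) x F matrices with im2col column order
# (c - 1) * k + j for kernel offset j in 1..k.

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_conv1d_forward <- function(A, W, b) {
  N <- dim(A)[1L]; L <- dim(A)[2L]; C <- dim(A)[3L]
  k <- nrow(W) / C
  Lout <- L - k + 1L
  if (Lout < 1L) stop("input too short for the convolution kernel",
                      call. = FALSE)
  Xc <- matrix(0, N * Lout, k * C)
  for (c in seq_len(C)) {
    for (j in seq_len(k)) {
      Xc[, (c - 1L) * k + j] <- A[, j:(j + Lout - 1L), c]
    }
  }
  out <- Xc %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = array(out, c(N, Lout, ncol(W))), Xc = Xc,
       dims = c(N = N, L = L, C = C, k = k, Lout = Lout))
}

nn_conv1d_backward <- function(dOut, cache, W, need_dx = TRUE) {
  d <- cache$dims
  dM <- matrix(dOut, d[["N"]] * d[["Lout"]], ncol(W))
  dW <- crossprod(cache$Xc, dM)
  db <- colSums(dM)
  dA <- NULL
  if (need_dx) {
    dXc <- tcrossprod(dM, W)
    dA <- array(0, c(d[["N"]], d[["L"]], d[["C"]]))
    for (c in seq_len(d[["C"]])) {
      for (j in seq_len(d[["k"]])) {
        dA[, j:(j + d[["Lout"]] - 1L), c] <-
          dA[, j:(j + d[["Lout"]] - 1L), c] +
          matrix(dXc[, (c - 1L) * d[["k"]] + j], d[["N"]], d[["Lout"]])
      }
    }
  }
  list(dW = dW, db = db, dA = dA)
}

nn_pool2_forward <- function(A) {
  N <- dim(A)[1L]; L <- dim(A)[2L]; F <- dim(A)[3L]
  T <- L %/% 2L
  i1 <- seq(1L, 2L * T, by = 2L)
  A1 <- A[, i1, , drop = FALSE]
  A2 <- A[, i1 + 1L, , drop = FALSE]
  m <- A1 >= A2  # ties take the earlier sample
  list(out = pmax(A1, A2), mask = m, L = L)
}

nn_pool2_backward <- function(dOut, cache) {
  dm <- dim(dOut)
  T <- dm[2L]
  dA <- array(0, c(dm[1L], cache$L, dm[3L]))
  i1 <- seq(1L, 2L * T, by = 2L)
  dA[, i1, ] <- dOut * cache$mask
  dA[, i1 + 1L, ] <- dOut * !cache$mask
  dA
}

nn_lstm_forward <- function(Z, Wx, Wh, b) {
  N <- dim(Z)[1L]; T <- dim(Z)[2L]; C <- dim(Z)[3L]
  H <- nrow(Wh)
  iI <- seq_len(H); iF <- H + iI; iG <- 2L * H + iI; iO <- 3L * H + iI
  h <- matrix(0, N, H); cs <- matrix(0, N, H)
  arr <- function() array(0, c(N, T, H))
  I <- arr(); Fg <- arr(); G <- arr(); O <- arr()
  Tc <- arr(); Cprev <- arr(); Hprev <- arr()
  bmat <- matrix(b, N, 4L * H, byrow = TRUE)
  for (t in seq_len(T)) {
    Zt <- matrix(Z[, t, ], N, C)
    gates <- Zt %*% Wx + h %*% Wh + bmat
    i <- sigmoid(gates[, iI, drop = FALSE])
    f <- sigmoid(gates[, iF, drop = FALSE])
    g <- tanh(gates[, iG, drop = FALSE])
    o <- sigmoid(gates[, iO, drop = FALSE])
    Cprev[, t, ] <- cs; Hprev[, t, ] <- h
    cs <- f * cs + i * g
    tc <- tanh(cs)
    h <- o * tc
    I[, t, ] <- i; Fg[, t, ] <- f; G[, t, ] <- g; O[, t, ] <- o
    Tc[, t, ] <- tc
  }
  list(h = h, I = I, Fg = Fg, G = G, O = O, Tc = Tc, Cprev = Cprev,
       Hprev = Hprev, Z = Z, N = N, T = T, C = C, H = H)
}

nn_lstm_backward <- function(dhT, cache, Wx, Wh) {
  N <- cache$N; T <- cache$T; C <- cache$C; H <- cache$H
  dWx <- matrix(0, C, 4L * H); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dZ <- array(0, c(N, T, C))
  dh <- dhT; dc <- matrix(0, N, H)
  for (t in rev(seq_len(T))) {
    i <- matrix(cache$I[, t, ], N, H)
    f <- matrix(cache$Fg[, t, ], N, H)
    g <- matrix(cache$G[, t, ], N, H)
    o <- matrix(cache$O[, t, ], N, H)
    tc <- matrix(cache$Tc[, t, ], N, H)
    cprev <- matrix(cache$Cprev[, t, ], N, H)
    hprev <- matrix(cache$Hprev[, t, ], N, H)
    Zt <- matrix(cache$Z[, t, ], N, C)
    do <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    di <- dc * g
    df <- dc * cprev
    dg <- dc * i
    dG <- cbind(di * i * (1 - i), df * f * (1 - f),
                dg * (1 - g^2), do * o * (1 - o))
    dWx <- dWx + crossprod(Zt, dG)
    dWh <- dWh + crossprod(hprev, dG)
    db <- db + colSums(dG)
    dZ[, t, ] <- tcrossprod(dG, Wx)
    dh <- tcrossprod(dG, Wh)
    dc <- dc * f
  }
  list(dWx = dWx, dWh = dWh, db = db, dZ = dZ)
}

nn_softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

# Full forward pass. `train` enables dropout (mask drawn from the current
# RNG stream, so the caller controls reproducibility).
nn_forward <- function(params, X, cfg, train = FALSE) {
  N <- nrow(X)
  A0 <- array(X, c(N, ncol(X), 1L))
  c1 <- nn_conv1d_forward(A0, params$W1, params$b1)
  r1 <- c1$out * (c1$out > 0)
  p1 <- nn_pool2_forward(r1)
  c2 <- nn_conv1d_forward(p1$out, params$W2, params$b2)
  r2 <- c2$out * (c2$out > 0)
  p2 <- nn_pool2_forward(r2)
  ls <- nn_lstm_forward(p2$out, params$Wx, params$Wh, params$bl)
  mask <- if (train && cfg$dropout > 0) {
    (matrix(stats::runif(N * ls$H), N, ls$H) >= cfg$dropout) /
      (1 - cfg$dropout)
  } else {
    1
  }
  hd <- ls$h * mask
  logits <- hd %*% params$Wd + rep(params$bd, each = N)
  probs <- nn_softmax(logits)
  list(probs = probs,
       cache = list(c1 = c1, p1 = p1, c2 = c2, p2 = p2, ls = ls,
                    mask = mask, hd = hd, r1pos = c1$out > 0,
                    r2pos = c2$out > 0))
}

nn_loss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

nn_backward <- function(params, fwd, y) {
  cache <- fwd$cache
  probs <- fwd$probs
  N <- nrow(probs)
  Y <- matrix(0, N, ncol(probs))
  Y[cbind(seq_len(N), y)] <- 1
  dlogits <- (probs - Y) / N
  dWd <- crossprod(cache$hd, dlogits)
  dbd <- colSums(dlogits)
  dhd <- tcrossprod(dlogits, params$Wd)
  dhT <- dhd * cache$mask
  lb <- nn_lstm_backward(dhT, cache$ls, params$Wx, params$Wh)
  dr2 <- nn_pool2_backward(lb$dZ, cache$p2)
  dc2 <- dr2 * cache$r2pos
  cb2 <- nn_conv1d_backward(dc2, cache$c2, params$W2, need_dx = TRUE)
  dr1 <- nn_pool2_backward(cb2$dA, cache$p1)
  dc1 <- dr1 * cache$r1pos
  cb1 <- nn_conv1d_backward(dc1, cache$c1, params$W1, need_dx = FALSE)
  list(W1 = cb1$dW, b1 = cb1$db, W2 = cb2$dW, b2 = cb2$db,
       Wx = lb$dWx, Wh = lb$dWh, bl = lb$db,
       Wd = dWd, bd = dbd)
}

nn_adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

nn_adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
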