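# Numeric primitives for the hand-written networks.  Everything operates
# on plain base-R matrices; sequences are stored column-wise (one column
# per time step).

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Softmax of a numeric vector
#'
#' Numerically stable (max-shifted) softmax.
#'
#' @param x numeric vector of scores.
#' @return probability vector summing to 1.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

softmax_cols <- function(S) {
  E <- exp(sweep(S, 2L, apply(S, 2L, max)))
  sweep(E, 2L, colSums(E), "/")
}

# uniform init in (-r, r), as used for all feature embeddings
init_uniform <- function(nrow, ncol, r = 0.01) {
  matrix(runif(nrow * ncol, -r, r), nrow, ncol)
}

# scaled uniform init for weight matrices and LSTM parameters
init_glorot <- function(nrow, ncol) {
  r <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -r, r), nrow, ncol)
}

# One LSTM parameter set.  Gate order along rows of W/U/b: input, forget,
# output, candidate.  No peephole connections.
lstm_params <- function(input_dim, hidden_dim) {
  list(W = init_glorot(4L * hidden_dim, input_dim),
       U = init_glorot(4L * hidden_dim, hidden_dim),
       b = numeric(4L * hidden_dim))
}

# Run an LSTM left-to-right over X (D x N, one column per step), starting
# from zero state.  Returns hidden states H (H x N) and the cache needed
# for backpropagation.
lstm_forward <- function(X, W, U, b) {
  N <- ncol(X)
  H <- length(b) %/% 4L
  ii <- seq_len(H); fi <- H + ii; oi <- 2L * H + ii; gi <- 3L * H + ii
  Hs <- matrix(0, H, N); Cs <- matrix(0, H, N)
  I <- matrix(0, H, N); F <- matrix(0, H, N)
  O <- matrix(0, H, N); G <- matrix(0, H, N)
  WX <- W %*% X + b
  hprev <- numeric(H); cprev <- numeric(H)
  for (t in seq_len(N)) {
    z <- WX[, t] + as.numeric(U %*% hprev)
    i <- sigmoid(z[ii]); f <- sigmoid(z[fi])
    o <- sigmoid(z[oi]); g <- tanh(z[gi])
    c_ <- f * cprev + i * g
    h <- o * tanh(c_)
    I[, t] <- i; F[, t] <- f; O[, t] <- o; G[, t] <- g
    Cs[, t] <- c_; Hs[, t] <- h
    hprev <- h; cprev <- c_
  }
  list(H = Hs, cache = list(X = X, I = I, F = F, O = O, G = G, C = Cs, Hs = Hs))
}

# Backpropagate through lstm_forward.  dH is the gradient of the loss
# with respect to every hidden state (H x N).  Returns parameter
# gradients and the gradient with respect to the inputs X.
lstm_backward <- function(W, U, cache, dH) {
  X <- cache$X
  N <- ncol(X)
  H <- nrow(dH)
  dW <- matrix(0, 4L * H, nrow(X))
  dU <- matrix(0, 4L * H, H)
  db <- numeric(4L * H)
  dX <- matrix(0, nrow(X), N)
  dh_next <- numeric(H); dc_next <- numeric(H)
  for (t in rev(seq_len(N))) {
    i <- cache$I[, t]; f <- cache$F[, t]
    o <- cache$O[, t]; g <- cache$G[, t]
    c_ <- cache$C[, t]
    cprev <- if (t > 1L) cache$C[, t - 1L] else numeric(H)
    hprev <- if (t > 1L) cache$Hs[, t - 1L] else numeric(H)
    tc <- tanh(c_)
    dh <- dH[, t] + dh_next
    do_ <- dh * tc
    dc <- dh * o * (1 - tc^2) + dc_next
    di <- dc * g; dg <- dc * i; df <- dc * cprev
    dc_next <- dc * f
    dz <- c(di * i * (1 - i), df * f * (1 - f),
            do_ * o * (1 - o), dg * (1 - g^2))
    dW <- dW + tcrossprod(dz, X[, t])
    dU <- dU + tcrossprod(dz, hprev)
    db <- db + dz
    dX[, t] <- as.numeric(crossprod(W, dz))
    dh_next <- as.numeric(crossprod(U, dz))
  }
  list(dW = dW, dU = dU, db = db, dX = dX)
}

# elementwise addition of two same-shaped gradient lists (NULL-tolerant)
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
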