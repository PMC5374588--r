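# Character-level CNN and the shared bidirectional sentence LSTM.

#' Character window of embeddings
#'
#' Concatenates the embeddings of the `2C + 1` characters centred at
#' position `i` of `word`; positions outside the word use the learned
#' padding vector.
#'
#' @param word normalized word string.
#' @param i 1-based character position.
#' @param model a `bionerel_model`.
#' @return numeric vector of length `(2C + 1) * dim_char`.
#' @export
char_window <- function(word, i, model) {
  if (!nzchar(word)) stop("cannot build character windows for an empty word")
  ids <- char_ids(model$vocab, word)
  stopifnot(i >= 1L, i <= length(ids))
  C <- model$config$char_window
  pad <- char_pad_id(model$vocab)
  padded <- c(rep(pad, C), ids, rep(pad, C))
  rows <- padded[i:(i + 2L * C)]
  as.numeric(t(model$params$Echar[rows, , drop = FALSE]))
}

#' Character convolution
#'
#' One kernel application: `tanh(W1 %*% window + b1)`.
#'
#' @param window numeric vector from [char_window()].
#' @param model a `bionerel_model`.
#' @return numeric vector of length `dim_char_repr`, components in
#'   (-1, 1).
#' @export
char_conv <- function(window, model) {
  if (length(window) != ncol(model$params$W1))
    stop("window length ", length(window), " does not match kernel input ",
         ncol(model$params$W1))
  as.numeric(tanh(model$params$W1 %*% window + model$params$b1))
}

#' Max-pool kernel outputs into a character-level representation
#'
#' @param outputs list of equal-length numeric vectors (one per
#'   character position).
#' @return elementwise maximum across positions.
#' @export
char_pool <- function(outputs) {
  if (length(outputs) == 0L) stop("cannot pool an empty output list")
  do.call(pmax, outputs)
}

# Forward pass of the character CNN for one word.  Returns the pooled
# representation and the cache used by char_cnn_backward.
char_cnn_forward <- function(word, params, vocab, config) {
  ids <- char_ids(vocab, word)
  L <- length(ids)
  C <- config$char_window
  S <- 2L * C + 1L
  dc <- config$dim_char
  pad <- char_pad_id(vocab)
  padded <- c(rep(pad, C), ids, rep(pad, C))
  M <- vapply(seq_len(L), function(i) padded[i:(i + S - 1L)], integer(S))
  M <- matrix(M, nrow = S)               # S x L window char ids
  Et <- t(params$Echar)                  # dc x rows
  Z <- matrix(Et[, as.vector(M)], nrow = S * dc, ncol = L)
  O <- tanh(params$W1 %*% Z + params$b1) # kc x L
  amax <- max.col(O, ties.method = "first")
  r <- O[cbind(seq_len(nrow(O)), amax)]
  list(r = r, cache = list(M = M, Z = Z, O = O, amax = amax))
}

# Backward pass for one word: dr is the gradient at the pooled
# representation.  Accumulates into grads$W1, grads$b1, grads$Echar.
char_cnn_backward <- function(dr, cache, params, grads) {
  kc <- length(dr)
  L <- ncol(cache$O)
  dc <- ncol(params$Echar)
  dO <- matrix(0, kc, L)
  sel <- cbind(seq_len(kc), cache$amax)
  dO[sel] <- dr * (1 - cache$O[sel]^2)
  grads$W1 <- grads$W1 + dO %*% t(cache$Z)
  grads$b1 <- grads$b1 + rowSums(dO)
  dZ <- crossprod(params$W1, dO)                    # (S*dc) x L
  dZr <- matrix(dZ, nrow = dc)                      # dc x (S*L)
  contrib <- rowsum(t(dZr), group = as.vector(cache$M))
  rows <- as.integer(rownames(contrib))
  grads$Echar[rows, ] <- grads$Echar[rows, , drop = FALSE] + contrib
  grads
}

# Shared encoder forward pass: builds per-token inputs (word embedding,
# POS embedding, character representation; disabled features contribute
# zeros) and runs the two sentence LSTMs.  Forward states depend only on
# tokens <= i, backward states only on tokens >= i.
encoder_forward <- function(model, sent) {
  params <- model$params; vocab <- model$vocab; config <- model$config
  n <- nrow(sent$tokens)
  if (n == 0L) stop("cannot encode an empty sentence")
  wid <- word_ids(vocab, sent$tokens$norm)
  pid <- pos_ids(vocab, sent$tokens$pos)
  Tw <- t(params$Eword[wid, , drop = FALSE])
  Tp <- if (config$features$pos) t(params$Epos[pid, , drop = FALSE])
        else matrix(0, config$dim_feat, n)
  char_caches <- NULL
  if (config$features$char) {
    cc <- lapply(sent$tokens$norm, char_cnn_forward, params = params,
                 vocab = vocab, config = config)
    Tc <- vapply(cc, `[[`, numeric(config$dim_char_repr), "r")
    Tc <- matrix(Tc, nrow = config$dim_char_repr)
    char_caches <- lapply(cc, `[[`, "cache")
  } else {
    Tc <- matrix(0, config$dim_char_repr, n)
  }
  X <- rbind(Tw, Tp, Tc)
  fwd <- lstm_forward(X, params$lstmf.W, params$lstmf.U, params$lstmf.b)
  rev_idx <- rev(seq_len(n))
  bwd <- lstm_forward(X[, rev_idx, drop = FALSE],
                      params$lstmb.W, params$lstmb.U, params$lstmb.b)
  list(hf = fwd$H, hb = bwd$H[, rev_idx, drop = FALSE],
       cache = list(X = X, fwd = fwd$cache, bwd = bwd$cache,
                    wid = wid, pid = pid, char = char_caches, n = n))
}

# Backward through the shared encoder given gradients at every forward
# and backward hidden state.  Word embeddings are frozen and receive no
# gradient.
encoder_backward <- function(model, enc, dHf, dHb, grads) {
  params <- model$params; config <- model$config
  n <- enc$cache$n
  rev_idx <- rev(seq_len(n))
  gf <- lstm_backward(params$lstmf.W, params$lstmf.U, enc$cache$fwd, dHf)
  gb <- lstm_backward(params$lstmb.W, params$lstmb.U, enc$cache$bwd,
                      dHb[, rev_idx, drop = FALSE])
  grads$lstmf.W <- grads$lstmf.W + gf$dW
  grads$lstmf.U <- grads$lstmf.U + gf$dU
  grads$lstmf.b <- grads$lstmf.b + gf$db
  grads$lstmb.W <- grads$lstmb.W + gb$dW
  grads$lstmb.U <- grads$lstmb.U + gb$dU
  grads$lstmb.b <- grads$lstmb.b + gb$db
  dX <- gf$dX + gb$dX[, rev_idx, drop = FALSE]
  dw <- config$dim_word; df <- config$dim_feat
  if (config$features$pos) {
    dP <- dX[(dw + 1L):(dw + df), , drop = FALSE]
    contrib <- rowsum(t(dP), group = enc$cache$pid)
    rows <- as.integer(rownames(contrib))
    grads$Epos[rows, ] <- grads$Epos[rows, , drop = FALSE] + contrib
  }
  if (config$features$char) {
    off <- dw + df
    for (i in seq_len(n)) {
      dr <- dX[(off + 1L):(off + config$dim_char_repr), i]
      grads <- char_cnn_backward(dr, enc$cache$char[[i]], params, grads)
    }
  }
  grads
}

#' Encode a sentence into shared per-token hidden states
#'
#' Runs the character CNN and the two directions of the shared sentence
#' LSTM. The forward state of token `i` depends only on tokens `1..i`,
#' the backward state only on tokens `i..n`.
#'
#' @param model a `bionerel_model`.
#' @param sent an `annotated_sentence`.
#' @return list with matrices `hf` and `hb` (`dim_hidden` x n) and the
#'   internal `cache` consumed by training.
#' @export
encode_sentence <- function(model, sent) {
  encoder_forward(model, sent)
}
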