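# Greedy left-to-right BILOU tagging head with previous-label feedback.

# hidden-layer input for step i: [hf_i, hb_i, emb(prev label)]; the label
# block is zeroed when the label feature is disabled
ner_input <- function(model, states, i, prev_id) {
  lab <- if (model$config$features$label)
    as.numeric(model$params$Elabel[prev_id, ]) else
    numeric(model$config$dim_feat)
  c(states$hf[, i], states$hb[, i], lab)
}

#' One tagging step
#'
#' Computes the label distribution for token `i` given the shared hidden
#' states and the previous label:
#' `softmax(W3 tanh(W2 [hf_i, hb_i, emb(prev)] + b2) + b3)`.
#'
#' @param model a `bionerel_model`.
#' @param states encoder output from [encode_sentence()].
#' @param i token index.
#' @param prev_label previous entity label, or `"<START>"` at `i = 1`.
#' @return list with `label` (argmax) and `distribution` (named
#'   probability vector over the entity-label set).
#' @export
ner_step <- function(model, states, i, prev_label = "<START>") {
  vocab <- model$vocab
  prev_id <- if (identical(prev_label, "<START>")) start_label_id(vocab)
             else elabel_id(vocab, prev_label)
  z <- ner_input(model, states, i, prev_id)
  h <- tanh(as.numeric(model$params$W2 %*% z) + model$params$b2)
  y <- softmax(as.numeric(model$params$W3 %*% h) + model$params$b3)
  names(y) <- vocab$elabels
  list(label = vocab$elabels[which.max(y)], distribution = y)
}

#' Greedy BILOU decode of a sentence
#'
#' Left-to-right decoding starting from the START symbol; each step
#' conditions on the previously *predicted* label. Deterministic given
#' the model and states.
#'
#' @param model a `bionerel_model`.
#' @param states encoder output from [encode_sentence()]; computed when
#'   missing.
#' @param sent the `annotated_sentence` (needed when `states` missing).
#' @return character vector of predicted BILOU labels.
#' @export
tag_sentence <- function(model, sent, states = NULL) {
  if (is.null(states)) states <- encoder_forward(model, sent)
  n <- ncol(states$hf)
  labels <- character(n)
  prev <- "<START>"
  for (i in seq_len(n)) {
    labels[i] <- ner_step(model, states, i, prev)$label
    prev <- labels[i]
  }
  labels
}

# Forward + backward over all tagging examples of a sentence (one per
# token).  gold_labels supply the targets; prev labels are gold when
# teacher forcing, else the model's running argmax.  Returns loss,
# parameter gradients and gradients at the shared hidden states.
ner_grads <- function(model, states, gold_labels) {
  params <- model$params; vocab <- model$vocab; config <- model$config
  n <- length(gold_labels)
  targets <- elabel_id(vocab, gold_labels)
  H <- config$dim_hidden
  df <- config$dim_feat
  prev_ids <- integer(n)
  if (config$teacher_forcing) {
    prev_ids <- c(start_label_id(vocab), targets[-n])
    lab_block <- if (config$features$label)
      t(params$Elabel[prev_ids, , drop = FALSE]) else matrix(0, df, n)
    Z <- rbind(states$hf, states$hb, lab_block)
    Hm <- tanh(params$W2 %*% Z + params$b2)
    S <- params$W3 %*% Hm + params$b3
    Y <- softmax_cols(S)
  } else {
    Z <- matrix(0, 2L * H + df, n)
    Hm <- matrix(0, config$dim_ner_hidden, n)
    Y <- matrix(0, length(vocab$elabels), n)
    prev <- start_label_id(vocab)
    for (i in seq_len(n)) {
      prev_ids[i] <- prev
      Z[, i] <- ner_input(model, states, i, prev)
      Hm[, i] <- tanh(as.numeric(params$W2 %*% Z[, i]) + params$b2)
      Y[, i] <- softmax(as.numeric(params$W3 %*% Hm[, i]) + params$b3)
      prev <- which.max(Y[, i])
    }
  }
  probs <- Y[cbind(targets, seq_len(n))]
  loss <- -sum(log(pmax(probs, 1e-12)))
  dS <- Y
  dS[cbind(targets, seq_len(n))] <- dS[cbind(targets, seq_len(n))] - 1
  dW3 <- dS %*% t(Hm)
  db3 <- rowSums(dS)
  dH <- crossprod(params$W3, dS) * (1 - Hm^2)
  dW2 <- dH %*% t(Z)
  db2 <- rowSums(dH)
  dZ <- crossprod(params$W2, dH)
  g <- list(W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
  if (config$features$label) {
    dL <- t(dZ[(2L * H + 1L):(2L * H + df), , drop = FALSE])
    contrib <- rowsum(dL, group = prev_ids)
    g$Elabel <- matrix(0, nrow(params$Elabel), df)
    g$Elabel[as.integer(rownames(contrib)), ] <- contrib
  }
  list(loss = loss, n_examples = n, grads = g,
       dHf = dZ[seq_len(H), , drop = FALSE],
       dHb = dZ[(H + 1L):(2L * H), , drop = FALSE])
}
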