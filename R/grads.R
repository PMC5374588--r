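# Full-model gradients for one sentence, and the numerical gradient
# checker that guards the hand-written backpropagation.

# zero-filled gradient list matching every trainable parameter (word
# embeddings are frozen and excluded)
zero_grads <- function(params) {
  out <- lapply(params, function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  })
  out$Eword <- NULL
  out
}

#' Loss and gradients of the joint model on one sentence
#'
#' Generates the sentence's training examples -- one tagging example per
#' token (teacher-forced by default) and one relation example per
#' candidate entity pair built from the gold entities -- and returns the
#' summed cross-entropy loss together with analytic gradients for every
#' trainable parameter. In joint mode the relation examples propagate
#' into the shared encoder; in pipeline mode they do not.
#'
#' @param model a `bionerel_model`.
#' @param sent an `annotated_sentence` with gold annotations.
#' @param head which examples to include: `"both"`, `"ner"` or `"rel"`.
#' @param ner_mask optional logical/integer selection of tagging
#'   examples (token positions) to include.
#' @param rel_subset optional integer selection of relation candidates.
#' @return list with `loss`, `n_examples` and `grads` (named list).
#' @export
sentence_gradients <- function(model, sent, head = c("both", "ner", "rel"),
                               ner_mask = NULL, rel_subset = NULL) {
  head <- match.arg(head)
  config <- model$config
  states <- encoder_forward(model, sent)
  n <- states$cache$n
  H <- config$dim_hidden
  grads <- zero_grads(model$params)
  dHf <- matrix(0, H, n)
  dHb <- matrix(0, H, n)
  loss <- 0
  n_examples <- 0L
  touched_encoder <- FALSE

  if (head %in% c("both", "ner")) {
    gold_labels <- encode_bilou(n, sent$entities)
    ng <- ner_grads_masked(model, states, gold_labels, ner_mask)
    loss <- loss + ng$loss
    n_examples <- n_examples + ng$n_examples
    grads <- add_grads(grads, ng$grads)
    dHf <- dHf + ng$dHf
    dHb <- dHb + ng$dHb
    touched_encoder <- TRUE
  }
  if (head %in% c("both", "rel")) {
    cands <- generate_candidates(sent, model$vocab$task)
    if (!is.null(rel_subset)) cands <- cands[rel_subset]
    if (length(cands) > 0L) {
      rg <- rel_grads(model, states, sent, cands)
      loss <- loss + rg$loss
      n_examples <- n_examples + rg$n_examples
      grads <- add_grads(grads, rg$grads)
      if (config$mode == "joint") {
        dHf <- dHf + rg$dHf
        dHb <- dHb + rg$dHb
        touched_encoder <- TRUE
      }
    }
  }
  if (touched_encoder)
    grads <- encoder_backward(model, states, dHf, dHb, grads)
  list(loss = loss, n_examples = n_examples, grads = grads)
}

# ner_grads with an optional selection of token positions
ner_grads_masked <- function(model, states, gold_labels, mask = NULL) {
  if (is.null(mask)) return(ner_grads(model, states, gold_labels))
  sel <- seq_along(gold_labels)[mask]
  ner_grads_subset(model, states, gold_labels, sel)
}

# teacher-forced tagging gradients restricted to token positions `sel`
ner_grads_subset <- function(model, states, gold_labels, sel) {
  params <- model$params; vocab <- model$vocab; config <- model$config
  n <- length(gold_labels)
  targets <- elabel_id(vocab, gold_labels)
  prev_ids <- c(start_label_id(vocab), targets[-n])
  H <- config$dim_hidden; df <- config$dim_feat
  lab_block <- if (config$features$label)
    t(params$Elabel[prev_ids, , drop = FALSE]) else matrix(0, df, n)
  Z <- rbind(states$hf, states$hb, lab_block)[, sel, drop = FALSE]
  Hm <- tanh(params$W2 %*% Z + params$b2)
  Y <- softmax_cols(params$W3 %*% Hm + params$b3)
  tg <- targets[sel]
  probs <- Y[cbind(tg, seq_along(sel))]
  loss <- -sum(log(pmax(probs, 1e-12)))
  dS <- Y
  dS[cbind(tg, seq_along(sel))] <- dS[cbind(tg, seq_along(sel))] - 1
  dH <- crossprod(params$W3, dS) * (1 - Hm^2)
  dZ <- crossprod(params$W2, dH)
  g <- list(W2 = dH %*% t(Z), b2 = rowSums(dH),
            W3 = dS %*% t(Hm), b3 = rowSums(dS))
  if (config$features$label) {
    dL <- t(dZ[(2L * H + 1L):(2L * H + df), , drop = FALSE])
    contrib <- rowsum(dL, group = prev_ids[sel])
    g$Elabel <- matrix(0, nrow(params$Elabel), df)
    g$Elabel[as.integer(rownames(contrib)), ] <- contrib
  }
  dHf <- matrix(0, H, n); dHb <- matrix(0, H, n)
  dHf[, sel] <- dZ[seq_len(H), , drop = FALSE]
  dHb[, sel] <- dZ[(H + 1L):(2L * H), , drop = FALSE]
  list(loss = loss, n_examples = length(sel), grads = g, dHf = dHf, dHb = dHb)
}

#' Numerical gradient check of the full model
#'
#' Compares the analytic gradients of [sentence_gradients()] against
#' central finite differences for every trainable parameter entry.
#' Relative error is `|a - n| / max(|a| + |n|, 1e-4)`, which reduces to
#' an absolute comparison for near-zero gradients.
#'
#' @param model a `bionerel_model` (use toy dimensions; cost is two
#'   forward passes per parameter entry).
#' @param sent an `annotated_sentence` with gold annotations.
#' @param head as in [sentence_gradients()].
#' @param eps finite-difference step.
#' @return list with `max_rel_err` and a per-parameter summary
#'   data.frame.
#' @export
gradient_check <- function(model, sent, head = "both", eps = 3e-5) {
  ana <- sentence_gradients(model, sent, head = head)$grads
  rows <- list()
  max_err <- 0
  for (nm in names(ana)) {
    p <- model$params[[nm]]
    a <- ana[[nm]]
    num <- array(0, dim = if (is.matrix(p)) dim(p) else length(p))
    for (k in seq_along(p)) {
      m2 <- model
      m2$params[[nm]][k] <- p[k] + eps
      up <- sentence_gradients(m2, sent, head = head)$loss
      m2$params[[nm]][k] <- p[k] - eps
      dn <- sentence_gradients(m2, sent, head = head)$loss
      num[k] <- (up - dn) / (2 * eps)
    }
    rel <- abs(a - num) / pmax(abs(a) + abs(num), 1e-4)
    rows[[nm]] <- data.frame(param = nm, n = length(p),
                             max_rel_err = max(rel),
                             stringsAsFactors = FALSE)
    max_err <- max(max_err, max(rel))
  }
  list(max_rel_err = max_err, by_param = do.call(rbind, rows))
}
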