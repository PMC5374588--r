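# Online joint training with AdaGrad.

#' Cross-entropy loss of one training example
#'
#' `-log(prob)` for the gold label's predicted probability, plus the
#' global L2 term `lambda/2 * ||theta||^2` when supplied. Probabilities
#' at or below zero are clamped to `1e-12` with a warning.
#'
#' @param gold_label_prob predicted probability of the gold label.
#' @param params_norm_sq squared L2 norm of all parameters.
#' @param lambda regularization strength.
#' @return the loss value.
#' @export
example_loss <- function(gold_label_prob, params_norm_sq = 0, lambda = 0) {
  if (gold_label_prob <= 0) {
    warning("non-positive probability clamped to 1e-12")
    gold_label_prob <- 1e-12
  }
  -log(gold_label_prob) + lambda / 2 * params_norm_sq
}

#' One AdaGrad update
#'
#' Accumulates the squared gradient and scales the step:
#' `acc <- acc + g^2; param <- param - alpha * g / (sqrt(acc) + epsilon)`.
#'
#' @param param numeric vector/matrix of parameters.
#' @param grad gradient of the same shape.
#' @param accum squared-gradient accumulator of the same shape.
#' @param alpha learning rate.
#' @param epsilon stabilizer.
#' @return list with updated `param` and `accum`.
#' @export
adagrad_update <- function(param, grad, accum, alpha = 0.03, epsilon = 1e-8) {
  stopifnot(length(param) == length(grad), length(param) == length(accum))
  accum <- accum + grad^2
  list(param = param - alpha * grad / (sqrt(accum) + epsilon),
       accum = accum)
}

# apply one AdaGrad step for every gradient in `grads`, adding the L2
# weight-decay term lambda * theta to each gradient first
apply_updates <- function(model, grads) {
  cfg <- model$config
  if (is.null(model$adagrad))
    model$adagrad <- lapply(grads, function(g) g * 0)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (cfg$lambda > 0) g <- g + cfg$lambda * model$params[[nm]]
    acc <- model$adagrad[[nm]] + g^2
    model$params[[nm]] <- model$params[[nm]] -
      cfg$alpha * g / (sqrt(acc) + cfg$epsilon)
    model$adagrad[[nm]] <- acc
  }
  model
}

#' One online training pass over a corpus
#'
#' For each sentence, the two submodels are trained alternately: first
#' the tagging examples (one per token), then the relation examples (one
#' per candidate pair built from gold entities). With
#' `update = "sentence"` each group produces one AdaGrad update, with a
#' fresh shared encoder pass between the groups; with
#' `update = "example"` every single example triggers its own update and
#' encoder recomputation.
#'
#' @param model a `bionerel_model`.
#' @param corpus list of `annotated_sentence` (already preprocessed).
#' @param order optional permutation of sentence indices.
#' @return list with the updated `model`, total `loss` and the number of
#'   examples seen.
#' @export
train_epoch <- function(model, corpus, order = seq_along(corpus)) {
  if (length(corpus) == 0L) stop("cannot train on an empty corpus")
  total_loss <- 0
  total_n <- 0L
  for (si in order) {
    sent <- corpus[[si]]
    if (model$config$update == "sentence") {
      g <- sentence_gradients(model, sent, head = "ner")
      model <- apply_updates(model, g$grads)
      total_loss <- total_loss + g$loss; total_n <- total_n + g$n_examples
      g <- sentence_gradients(model, sent, head = "rel")
      if (g$n_examples > 0L) {
        model <- apply_updates(model, g$grads)
        total_loss <- total_loss + g$loss; total_n <- total_n + g$n_examples
      }
    } else {
      for (i in seq_len(nrow(sent$tokens))) {
        g <- sentence_gradients(model, sent, head = "ner", ner_mask = i)
        model <- apply_updates(model, g$grads)
        total_loss <- total_loss + g$loss; total_n <- total_n + 1L
      }
      n_cand <- length(generate_candidates(sent, model$vocab$task))
      for (j in seq_len(n_cand)) {
        g <- sentence_gradients(model, sent, head = "rel", rel_subset = j)
        model <- apply_updates(model, g$grads)
        total_loss <- total_loss + g$loss; total_n <- total_n + 1L
      }
    }
  }
  list(model = model, loss = total_loss, n_examples = total_n)
}

#' Train a joint (or pipeline) model
#'
#' Builds the vocabulary, initializes parameters under `config$seed`,
#' and runs `config$epochs` online passes with per-epoch reshuffling.
#' When `config$early_stop_f1` is set, entity and relation F1 are
#' monitored after each epoch (on `monitor`, defaulting to the training
#' corpus) and training stops once both reach the threshold.
#'
#' @param corpus list of `annotated_sentence`.
#' @param config a `bionerel_config`.
#' @param task `"ade"` or `"bb"`.
#' @param monitor optional corpus for early-stop monitoring.
#' @param word_vectors optional pre-trained word-vector matrix.
#' @param verbose print per-epoch losses?
#' @return trained `bionerel_model` with a `history` data.frame
#'   (epoch, mean loss, monitored F1s).
#' @export
train_model <- function(corpus, config = model_config(),
                        task = c("ade", "bb"), monitor = NULL,
                        word_vectors = NULL, verbose = FALSE) {
  task <- match.arg(task)
  vocab <- build_vocab(corpus, task)
  set.seed(config$seed)
  model <- init_model(vocab, config, word_vectors)
  if (is.null(monitor)) monitor <- corpus
  hist <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                     entity_f1 = numeric(0), relation_f1 = numeric(0))
  for (ep in seq_len(config$epochs)) {
    order <- sample(length(corpus))
    res <- train_epoch(model, corpus, order)
    model <- res$model
    ef1 <- rf1 <- NA_real_
    if (!is.null(config$early_stop_f1)) {
      sc <- score_corpus(monitor, predict_corpus(model, monitor))
      ef1 <- sc$entity["f1"]; rf1 <- sc$relation["f1"]
    }
    hist <- rbind(hist, data.frame(epoch = ep,
                                   mean_loss = res$loss / res$n_examples,
                                   entity_f1 = ef1, relation_f1 = rf1))
    if (verbose)
      message(sprintf("epoch %d: mean loss %.4f", ep,
                      res$loss / res$n_examples))
    if (!is.null(config$early_stop_f1) &&
        !is.na(ef1) && !is.na(rf1) &&
        ef1 >= config$early_stop_f1 && rf1 >= config$early_stop_f1) break
  }
  model$history <- hist
  model
}

#' Derive the pipeline ablation from a joint model
#'
#' Replaces the relation head's inputs -- the shared hidden states -- by
#' plain word embeddings, so the two submodels share no parameters and
#' relation losses can no longer reach the encoder. The path LSTMs and
#' the relation hidden layer are re-initialized at their (possibly
#' different) pipeline dimensions; all other parameters are carried
#' over.
#'
#' @param model a joint `bionerel_model`.
#' @return a `bionerel_model` with `config$mode == "pipeline"`.
#' @export
build_pipeline_model <- function(model) {
  config <- model$config
  config$mode <- "pipeline"
  sdp_in <- sdp_input_dim(config)
  rel_in <- 4L * config$dim_sdp_hidden + 2L * entity_repr_dim(config)
  p <- model$params
  if (ncol(p$sdpf.W) != sdp_in) {
    sf <- lstm_params(sdp_in, config$dim_sdp_hidden)
    sb <- lstm_params(sdp_in, config$dim_sdp_hidden)
    p$sdpf.W <- sf$W; p$sdpf.U <- sf$U; p$sdpf.b <- sf$b
    p$sdpb.W <- sb$W; p$sdpb.U <- sb$U; p$sdpb.b <- sb$b
  }
  if (ncol(p$W4) != rel_in) {
    p$W4 <- init_glorot(config$dim_rel_hidden, rel_in)
    p$b4 <- numeric(config$dim_rel_hidden)
  }
  structure(list(vocab = model$vocab, config = config, params = p,
                 adagrad = NULL, history = NULL),
            class = "bionerel_model")
}

#' Predict entities and relations for one sentence
#'
#' Greedy BILOU decoding (with repair), then relation classification of
#' every type-compatible pair of *predicted* mentions; pairs whose
#' argmax label is `NONE` are discarded.
#'
#' @param model a trained `bionerel_model`.
#' @param sent an `annotated_sentence` (gold annotations are ignored).
#' @return an `annotated_sentence` carrying the predicted entities and
#'   relations.
#' @export
predict_sentence <- function(model, sent) {
  states <- encoder_forward(model, sent)
  labels <- tag_sentence(model, sent, states)
  ents <- decode_bilou(labels)
  rel <- empty_relations()
  if (nrow(ents) >= 2L) {
    cands <- generate_candidates(sent, model$vocab$task, entities = ents)
    for (cand in cands) {
      y <- classify_pair(model, states, sent, cand)
      lab <- names(y)[which.max(y)]
      if (lab != "NONE")
        rel <- rbind(rel, data.frame(arg1 = cand$ia, arg2 = cand$ib,
                                     type = lab, stringsAsFactors = FALSE))
    }
  }
  annotated_sentence(tokens = sent$tokens, heads = sent$heads,
                     deprels = sent$deprels, entities = ents,
                     relations = rel, validate = FALSE)
}

#' @rdname predict_sentence
#' @param corpus list of sentences.
#' @export
predict_corpus <- function(model, corpus) {
  lapply(corpus, predict_sentence, model = model)
}

#' Save / load a trained model
#'
#' The checkpoint is an RDS archive of the parameter arrays, vocabulary
#' and configuration; the loader re-validates the dimension invariants.
#'
#' @param model a `bionerel_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bionerel_model"))
  config <- model$config
  p <- model$params
  win <- (2L * config$char_window + 1L) * config$dim_char
  stopifnot(
    ncol(p$W1) == win,
    ncol(p$W2) == 2L * config$dim_hidden + config$dim_feat,
    ncol(p$lstmf.W) == config$dim_word + config$dim_feat + config$dim_char_repr,
    ncol(p$sdpf.W) == sdp_input_dim(config),
    ncol(p$W4) == 4L * config$dim_sdp_hidden + 2L * entity_repr_dim(config))
  model
}
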