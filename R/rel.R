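# Relation head: a second bidirectional LSTM along the shortest
# dependency path between two entity anchors, stacked on the shared
# encoder, plus mean-pooled entity representations.

#' Mean-pooled representation of an entity mention
#'
#' In joint mode, the mean over the mention's tokens of the concatenated
#' forward/backward shared hidden states (dimension `2 * dim_hidden`); in
#' pipeline mode, the mean of the word embeddings.
#'
#' @param model a `bionerel_model`.
#' @param states encoder output from [encode_sentence()].
#' @param entity one-row entity data.frame (or list) with `start`, `end`.
#' @return numeric vector.
#' @export
entity_representation <- function(model, states, entity) {
  span <- entity$start:entity$end
  if (length(span) < 1L) stop("empty entity span")
  if (model$config$mode == "joint") {
    block <- rbind(states$hf[, span, drop = FALSE],
                   states$hb[, span, drop = FALSE])
  } else {
    block <- t(model$params$Eword[states$cache$wid[span], , drop = FALSE])
  }
  rowMeans(block)
}

# per-token inputs of the dependency-path LSTM for a path (vector of
# token indices): [hf_i, hb_i, emb(d_i)] in joint mode, word embedding
# in place of the hidden states in pipeline mode
sdp_inputs <- function(model, states, sent, path) {
  config <- model$config
  dep <- if (config$features$dep) {
    ids <- dep_ids(model$vocab, sent$deprels[path])
    t(model$params$Edep[ids, , drop = FALSE])
  } else matrix(0, config$dim_feat, length(path))
  base <- if (config$mode == "joint") {
    rbind(states$hf[, path, drop = FALSE], states$hb[, path, drop = FALSE])
  } else {
    t(model$params$Eword[states$cache$wid[path], , drop = FALSE])
  }
  rbind(base, dep)
}

#' Encode a shortest dependency path
#'
#' Runs the path LSTM over the four directed sequences of the path: the
#' two bottom-up climbs (anchor to LCA, forward parameter set) and the
#' two top-down descents (LCA to anchor, backward parameter set),
#' returning the four final hidden states.
#'
#' @param model a `bionerel_model`.
#' @param states encoder output.
#' @param sent the sentence (supplies dependency types).
#' @param sdp result of [shortest_dep_path()].
#' @return list with vectors `up_a`, `up_b`, `down_a`, `down_b`.
#' @export
sdp_encode <- function(model, states, sent, sdp) {
  p <- model$params
  Xa <- sdp_inputs(model, states, sent, sdp$up_a)
  Xb <- sdp_inputs(model, states, sent, sdp$up_b)
  last <- function(run) run$H[, ncol(run$H)]
  list(up_a = last(lstm_forward(Xa, p$sdpf.W, p$sdpf.U, p$sdpf.b)),
       up_b = last(lstm_forward(Xb, p$sdpf.W, p$sdpf.U, p$sdpf.b)),
       down_a = last(lstm_forward(Xa[, rev(seq_len(ncol(Xa))), drop = FALSE],
                                  p$sdpb.W, p$sdpb.U, p$sdpb.b)),
       down_b = last(lstm_forward(Xb[, rev(seq_len(ncol(Xb))), drop = FALSE],
                                  p$sdpb.W, p$sdpb.U, p$sdpb.b)))
}

# full forward pass of the relation head for one candidate; returns the
# probability vector and every intermediate needed for backprop
rel_forward <- function(model, states, sent, cand) {
  p <- model$params
  Xa <- sdp_inputs(model, states, sent, cand$sdp$up_a)
  Xb <- sdp_inputs(model, states, sent, cand$sdp$up_b)
  fa <- lstm_forward(Xa, p$sdpf.W, p$sdpf.U, p$sdpf.b)
  fb <- lstm_forward(Xb, p$sdpf.W, p$sdpf.U, p$sdpf.b)
  da <- lstm_forward(Xa[, rev(seq_len(ncol(Xa))), drop = FALSE],
                     p$sdpb.W, p$sdpb.U, p$sdpb.b)
  db_ <- lstm_forward(Xb[, rev(seq_len(ncol(Xb))), drop = FALSE],
                      p$sdpb.W, p$sdpb.U, p$sdpb.b)
  last <- function(run) run$H[, ncol(run$H)]
  if (model$config$features$entity_repr) {
    ra <- entity_representation(model, states, cand$e_a)
    rb <- entity_representation(model, states, cand$e_b)
  } else {
    ra <- numeric(entity_repr_dim(model$config))
    rb <- numeric(entity_repr_dim(model$config))
  }
  v <- c(last(fa), last(fb), last(da), last(db_), ra, rb)
  h <- tanh(as.numeric(p$W4 %*% v) + p$b4)
  y <- softmax(as.numeric(p$W5 %*% h) + p$b5)
  names(y) <- model$vocab$rlabels
  list(y = y, cache = list(Xa = Xa, Xb = Xb, fa = fa, fb = fb,
                           da = da, db_ = db_, v = v, h = h))
}

#' Classify one candidate entity pair
#'
#' `softmax(W5 tanh(W4 [up_a, up_b, down_a, down_b, r_a, r_b] + b4) + b5)`
#' over the relation-label set (task types plus `NONE`).
#'
#' @param model a `bionerel_model`.
#' @param states encoder output.
#' @param sent the sentence.
#' @param cand one element of [generate_candidates()].
#' @return named probability vector over relation labels.
#' @export
classify_pair <- function(model, states, sent, cand) {
  rel_forward(model, states, sent, cand)$y
}

#' Enumerate candidate entity pairs of a sentence
#'
#' All type-compatible pairs: Drug--Disease for the ADE schema,
#' Bacteria--Habitat and Bacteria--Geographical for the Lives_In schema
#' (first argument fixed by type, so predicted relations are directional
#' by construction). Each candidate carries the shortest dependency path
#' between the two entity anchors (last tokens). Pairs whose anchors
#' coincide are skipped with a warning.
#'
#' @param sent an `annotated_sentence`.
#' @param task `"ade"` or `"bb"`.
#' @param entities entity data.frame; defaults to the sentence's gold
#'   entities (pass predicted mentions at inference time).
#' @return list of candidates, each a list with `e_a`, `e_b` (one-row
#'   entity frames), `ia`, `ib` (row indices into `entities`), `sdp`, and
#'   `gold` (the gold relation type or `"NONE"`).
#' @export
generate_candidates <- function(sent, task = c("ade", "bb"),
                                entities = sent$entities) {
  task <- match.arg(task)
  first_types <- if (task == "ade") "Drug" else "Bacteria"
  second_types <- if (task == "ade") "Disease" else c("Habitat", "Geographical")
  ia_all <- which(entities$type %in% first_types)
  ib_all <- which(entities$type %in% second_types)
  gold_key <- character(0)
  if (nrow(sent$relations) > 0L) {
    ge <- sent$entities
    gold_key <- paste(ge$start[sent$relations$arg1], ge$end[sent$relations$arg1],
                      ge$start[sent$relations$arg2], ge$end[sent$relations$arg2])
    names(gold_key) <- sent$relations$type
  }
  out <- list()
  for (ia in ia_all) for (ib in ib_all) {
    a <- entity_anchor(entities[ia, ])
    b <- entity_anchor(entities[ib, ])
    if (a == b) {
      warning("skipping candidate pair with coinciding anchors at token ", a)
      next
    }
    key <- paste(entities$start[ia], entities$end[ia],
                 entities$start[ib], entities$end[ib])
    hit <- match(key, gold_key)
    out[[length(out) + 1L]] <- list(
      e_a = entities[ia, ], e_b = entities[ib, ], ia = ia, ib = ib,
      sdp = shortest_dep_path(sent$heads, a, b),
      gold = if (is.na(hit)) "NONE" else names(gold_key)[hit])
  }
  out
}

# Forward + backward over a set of relation candidates.  Returns loss,
# parameter gradients, and (joint mode) gradients at the shared hidden
# states.
rel_grads <- function(model, states, sent, cands) {
  params <- model$params; config <- model$config; vocab <- model$vocab
  H <- config$dim_hidden
  Hs <- config$dim_sdp_hidden
  de <- entity_repr_dim(config)
  n <- states$cache$n
  g <- list(W4 = matrix(0, nrow(params$W4), ncol(params$W4)),
            b4 = numeric(length(params$b4)),
            W5 = matrix(0, nrow(params$W5), ncol(params$W5)),
            b5 = numeric(length(params$b5)),
            sdpf.W = matrix(0, nrow(params$sdpf.W), ncol(params$sdpf.W)),
            sdpf.U = matrix(0, nrow(params$sdpf.U), ncol(params$sdpf.U)),
            sdpf.b = numeric(length(params$sdpf.b)),
            sdpb.W = matrix(0, nrow(params$sdpb.W), ncol(params$sdpb.W)),
            sdpb.U = matrix(0, nrow(params$sdpb.U), ncol(params$sdpb.U)),
            sdpb.b = numeric(length(params$sdpb.b)))
  if (config$features$dep)
    g$Edep <- matrix(0, nrow(params$Edep), ncol(params$Edep))
  dHf <- matrix(0, H, n)
  dHb <- matrix(0, H, n)
  loss <- 0
  for (cand in cands) {
    fw <- rel_forward(model, states, sent, cand)
    cache <- fw$cache
    target <- rlabel_id(vocab, cand$gold)
    loss <- loss - log(max(fw$y[target], 1e-12))
    ds <- fw$y
    ds[target] <- ds[target] - 1
    g$W5 <- g$W5 + tcrossprod(ds, cache$h)
    g$b5 <- g$b5 + ds
    dh <- as.numeric(crossprod(params$W5, ds)) * (1 - cache$h^2)
    g$W4 <- g$W4 + tcrossprod(dh, cache$v)
    g$b4 <- g$b4 + dh
    dv <- as.numeric(crossprod(params$W4, dh))
    d_ua <- dv[seq_len(Hs)]
    d_ub <- dv[Hs + seq_len(Hs)]
    d_da <- dv[2L * Hs + seq_len(Hs)]
    d_db <- dv[3L * Hs + seq_len(Hs)]
    d_ra <- dv[4L * Hs + seq_len(de)]
    d_rb <- dv[4L * Hs + de + seq_len(de)]

    la <- ncol(cache$Xa); lb <- ncol(cache$Xb)
    mk_dH <- function(len, dlast) {
      m <- matrix(0, Hs, len); m[, len] <- dlast; m
    }
    bfa <- lstm_backward(params$sdpf.W, params$sdpf.U, cache$fa$cache,
                         mk_dH(la, d_ua))
    bfb <- lstm_backward(params$sdpf.W, params$sdpf.U, cache$fb$cache,
                         mk_dH(lb, d_ub))
    bda <- lstm_backward(params$sdpb.W, params$sdpb.U, cache$da$cache,
                         mk_dH(la, d_da))
    bdb <- lstm_backward(params$sdpb.W, params$sdpb.U, cache$db_$cache,
                         mk_dH(lb, d_db))
    g$sdpf.W <- g$sdpf.W + bfa$dW + bfb$dW
    g$sdpf.U <- g$sdpf.U + bfa$dU + bfb$dU
    g$sdpf.b <- g$sdpf.b + bfa$db + bfb$db
    g$sdpb.W <- g$sdpb.W + bda$dW + bdb$dW
    g$sdpb.U <- g$sdpb.U + bda$dU + bdb$dU
    g$sdpb.b <- g$sdpb.b + bda$db + bdb$db

    dXa <- bfa$dX + bda$dX[, rev(seq_len(la)), drop = FALSE]
    dXb <- bfb$dX + bdb$dX[, rev(seq_len(lb)), drop = FALSE]
    base_dim <- if (config$mode == "joint") 2L * H else config$dim_word
    scatter_path <- function(dX, path) {
      if (config$mode == "joint") {
        for (k in seq_along(path)) {
          dHf[, path[k]] <<- dHf[, path[k]] + dX[seq_len(H), k]
          dHb[, path[k]] <<- dHb[, path[k]] + dX[H + seq_len(H), k]
        }
      }
      if (config$features$dep) {
        ids <- dep_ids(vocab, sent$deprels[path])
        dD <- dX[(base_dim + 1L):(base_dim + config$dim_feat), , drop = FALSE]
        for (k in seq_along(path))
          g$Edep[ids[k], ] <<- g$Edep[ids[k], ] + dD[, k]
      }
    }
    scatter_path(dXa, cand$sdp$up_a)
    scatter_path(dXb, cand$sdp$up_b)

    if (config$features$entity_repr && config$mode == "joint") {
      spread <- function(ent, d) {
        span <- ent$start:ent$end
        w <- 1 / length(span)
        for (k in span) {
          dHf[, k] <<- dHf[, k] + w * d[seq_len(H)]
          dHb[, k] <<- dHb[, k] + w * d[H + seq_len(H)]
        }
      }
      spread(cand$e_a, d_ra)
      spread(cand$e_b, d_rb)
    }
  }
  list(loss = loss, n_examples = length(cands), grads = g,
       dHf = dHf, dHb = dHb)
}
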