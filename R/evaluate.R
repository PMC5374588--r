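# Strict-match scoring, cross-validation, error taxonomy and baselines.

entity_keys <- function(entities) {
  if (is.null(entities) || nrow(entities) == 0L) return(character(0))
  paste(entities$start, entities$end, entities$type)
}

# relation keys with arguments resolved to spans and types
relation_keys <- function(sent) {
  rel <- sent$relations
  if (is.null(rel) || nrow(rel) == 0L) return(character(0))
  e <- sent$entities
  paste(e$start[rel$arg1], e$end[rel$arg1], e$type[rel$arg1],
        e$start[rel$arg2], e$end[rel$arg2], e$type[rel$arg2], rel$type)
}

# multiset tp/fp/fn between two key vectors
match_keys <- function(gold, pred) {
  tp <- 0L
  g <- gold
  for (k in pred) {
    hit <- match(k, g)
    if (!is.na(hit)) { tp <- tp + 1L; g <- g[-hit] }
  }
  c(tp = tp, fp = length(pred) - tp, fn = length(gold) - tp)
}

#' Strict matching of entity mentions
#'
#' A predicted mention is a true positive iff its token span and type
#' both match a gold mention, under one-to-one pairing.
#'
#' @param gold,pred entity data.frames (`start`, `end`, `type`) for the
#'   same sentence.
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
match_entities <- function(gold, pred) {
  match_keys(entity_keys(gold), entity_keys(pred))
}

#' Strict matching of relations
#'
#' A predicted relation is a true positive iff its type is correct and
#' the spans and types of both argument mentions match those of a gold
#' relation.
#'
#' @param gold_sent,pred_sent `annotated_sentence` objects over the same
#'   tokens (entities resolve the relation arguments).
#' @return named integer vector `c(tp, fp, fn)`.
#' @export
match_relations <- function(gold_sent, pred_sent) {
  match_keys(relation_keys(gold_sent), relation_keys(pred_sent))
}

#' Precision, recall and F1 from match counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; a zero
#' denominator yields 0 by convention.
#'
#' @param counts named vector with `tp`, `fp`, `fn`.
#' @return named numeric vector `c(precision, recall, f1)` on the 0--1
#'   scale.
#' @export
prf <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' F1 from a precision/recall pair
#'
#' Scale-agnostic harmonic mean: works on proportions or percentages.
#'
#' @param p,r precision and recall.
#' @return F1 on the same scale.
#' @export
f1_score <- function(p, r) {
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Score a predicted corpus against gold
#'
#' @param gold,pred parallel lists of `annotated_sentence`.
#' @return list with `entity` and `relation` precision/recall/F1 vectors
#'   and the raw `counts`.
#' @export
score_corpus <- function(gold, pred) {
  stopifnot(length(gold) == length(pred))
  ec <- c(tp = 0L, fp = 0L, fn = 0L)
  rc <- c(tp = 0L, fp = 0L, fn = 0L)
  for (i in seq_along(gold)) {
    ec <- ec + match_entities(gold[[i]]$entities, pred[[i]]$entities)
    rc <- rc + match_relations(gold[[i]], pred[[i]])
  }
  list(entity = prf(ec), relation = prf(rc),
       counts = list(entity = ec, relation = rc))
}

#' Disjoint fold assignment for cross-validation
#'
#' @param n corpus size.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return integer vector of fold ids (1..k) per sentence.
#' @export
make_folds <- function(n, k = 10L, seed = 1L) {
  if (k < 2L) stop("cross-validation needs at least 2 folds")
  if (n < k) stop("fewer sentences than folds")
  set.seed(seed)
  ids <- rep(seq_len(k), length.out = n)
  ids[sample(n)]
}

#' K-fold cross-validation of the joint model
#'
#' Per fold: the fold is the test set, the next fold the development
#' set, the remaining ~80% the training set. Models are trained with
#' [train_model()] and scored with strict matching; final scores are the
#' unweighted (macro) means of per-fold precision, recall and F1.
#'
#' @param corpus list of `annotated_sentence`.
#' @param config a `bionerel_config`.
#' @param task `"ade"` or `"bb"`.
#' @param k number of folds.
#' @return list with `entity`, `relation` (macro-averaged vectors) and
#'   `folds` (per-fold data.frame).
#' @export
cross_validate <- function(corpus, config = model_config(),
                           task = c("ade", "bb"), k = 10L) {
  task <- match.arg(task)
  folds <- make_folds(length(corpus), k, config$seed)
  per <- data.frame()
  for (fold in seq_len(k)) {
    dev_fold <- fold %% k + 1L
    test_idx <- which(folds == fold)
    dev_idx <- which(folds == dev_fold)
    train_idx <- setdiff(seq_along(corpus), c(test_idx, dev_idx))
    model <- train_model(corpus[train_idx], config, task,
                         monitor = corpus[dev_idx])
    sc <- score_corpus(corpus[test_idx],
                       predict_corpus(model, corpus[test_idx]))
    per <- rbind(per, data.frame(
      fold = fold,
      entity_p = sc$entity["precision"], entity_r = sc$entity["recall"],
      entity_f1 = sc$entity["f1"],
      relation_p = sc$relation["precision"],
      relation_r = sc$relation["recall"],
      relation_f1 = sc$relation["f1"]))
  }
  rownames(per) <- NULL
  list(entity = c(precision = mean(per$entity_p), recall = mean(per$entity_r),
                  f1 = mean(per$entity_f1)),
       relation = c(precision = mean(per$relation_p),
                    recall = mean(per$relation_r),
                    f1 = mean(per$relation_f1)),
       folds = per)
}

#' Error taxonomy for entities and relations
#'
#' Attributes every false positive and false negative to one category.
#' Entities: an exact-span prediction with the wrong type is an
#' "incorrect types" error; every other mismatch (shifted span with the
#' same type, partial overlap, no overlap) is "incorrect boundaries".
#' Relations: a false positive whose two argument mentions both match
#' gold mentions is "entities correct, relations wrong", otherwise
#' "entities incorrectly recognized"; a false negative whose two
#' argument mentions were both predicted is "entities found, relations
#' not found", otherwise (at least one argument missing) "entities not
#' found".
#'
#' @param gold,pred parallel lists of `annotated_sentence`.
#' @return list of two data.frames (`entity`, `relation`) with columns
#'   `class` (FP/FN), `category`, `count`, `pct`; percentages sum to 100
#'   within each table.
#' @export
error_taxonomy <- function(gold, pred) {
  stopifnot(length(gold) == length(pred))
  ent <- c(fp_boundary = 0L, fp_type = 0L, fn_boundary = 0L, fn_type = 0L)
  rel <- c(fp_entities = 0L, fp_relation = 0L,
           fn_entities = 0L, fn_relation = 0L)
  for (i in seq_along(gold)) {
    ge <- gold[[i]]$entities; pe <- pred[[i]]$entities
    gk <- entity_keys(ge); pk <- entity_keys(pe)
    for (r in seq_len(nrow(pe))) {
      if (pk[r] %in% gk) next
      exact_wrong_type <- any(ge$start == pe$start[r] & ge$end == pe$end[r] &
                              ge$type != pe$type[r])
      if (exact_wrong_type) ent["fp_type"] <- ent["fp_type"] + 1L
      else ent["fp_boundary"] <- ent["fp_boundary"] + 1L
    }
    for (r in seq_len(nrow(ge))) {
      if (gk[r] %in% pk) next
      exact_wrong_type <- any(pe$start == ge$start[r] & pe$end == ge$end[r] &
                              pe$type != ge$type[r])
      if (exact_wrong_type) ent["fn_type"] <- ent["fn_type"] + 1L
      else ent["fn_boundary"] <- ent["fn_boundary"] + 1L
    }
    grk <- relation_keys(gold[[i]]); prk <- relation_keys(pred[[i]])
    pr <- pred[[i]]$relations
    for (r in seq_len(nrow(pr))) {
      if (prk[r] %in% grk) next
      args_ok <- all(entity_keys(pe[c(pr$arg1[r], pr$arg2[r]), ]) %in% gk)
      if (args_ok) rel["fp_relation"] <- rel["fp_relation"] + 1L
      else rel["fp_entities"] <- rel["fp_entities"] + 1L
    }
    gr <- gold[[i]]$relations
    for (r in seq_len(nrow(gr))) {
      if (grk[r] %in% prk) next
      args_found <- all(entity_keys(ge[c(gr$arg1[r], gr$arg2[r]), ]) %in% pk)
      if (args_found) rel["fn_relation"] <- rel["fn_relation"] + 1L
      else rel["fn_entities"] <- rel["fn_entities"] + 1L
    }
  }
  tab <- function(counts, classes, categories) {
    total <- sum(counts)
    data.frame(class = classes, category = categories,
               count = as.integer(counts),
               pct = if (total > 0) 100 * counts / total else rep(0, 4),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(entity = tab(ent, c("FP", "FP", "FN", "FN"),
                    c("incorrect boundaries", "incorrect types",
                      "incorrect boundaries", "incorrect types")),
       relation = tab(rel, c("FP", "FP", "FN", "FN"),
                      c("entities incorrectly recognized",
                        "entities correct, relations wrong",
                        "entities not found",
                        "entities found, relations not found")))
}

#' Co-occurrence baseline
#'
#' Given gold entity mentions, predicts the task relation for every
#' type-compatible pair inside each sentence. Its recall on
#' intra-sentence gold relations is 100% by construction.
#'
#' @param corpus list of `annotated_sentence` with gold entities.
#' @param task `"ade"` or `"bb"`.
#' @return list of predicted `annotated_sentence`.
#' @export
cooccurrence_baseline <- function(corpus, task = c("ade", "bb")) {
  task <- match.arg(task)
  rtype <- if (task == "ade") "ADE" else "Lives_In"
  lapply(corpus, function(sent) {
    cands <- generate_candidates(sent, task)
    rel <- empty_relations()
    for (cand in cands)
      rel <- rbind(rel, data.frame(arg1 = cand$ia, arg2 = cand$ib,
                                   type = rtype, stringsAsFactors = FALSE))
    annotated_sentence(tokens = sent$tokens, heads = sent$heads,
                       deprels = sent$deprels, entities = sent$entities,
                       relations = rel, validate = FALSE)
  })
}

#' Per-category relation scores
#'
#' Partitions gold and predicted relations by a category key (default:
#' the type of the second argument, i.e. the location entity in the
#' Lives_In schema) and applies strict matching within each category.
#'
#' @param gold,pred parallel lists of `annotated_sentence`.
#' @param key function(sentence, relation_row) returning a category
#'   string.
#' @return data.frame with one row per category: counts and
#'   precision/recall/F1.
#' @export
breakdown_by_category <- function(gold, pred,
                                  key = function(sent, rel)
                                    sent$entities$type[rel$arg2]) {
  stopifnot(length(gold) == length(pred))
  acc <- list()
  bump <- function(cat, what) {
    if (is.na(cat) || !nzchar(cat)) stop("unknown relation category")
    if (is.null(acc[[cat]])) acc[[cat]] <<- c(tp = 0L, fp = 0L, fn = 0L)
    acc[[cat]][what] <<- acc[[cat]][what] + 1L
  }
  for (i in seq_along(gold)) {
    gk <- relation_keys(gold[[i]]); pk <- relation_keys(pred[[i]])
    gcat <- character(0); pcat <- character(0)
    gr <- gold[[i]]$relations; pr <- pred[[i]]$relations
    if (nrow(gr) > 0L)
      gcat <- vapply(seq_len(nrow(gr)),
                     function(r) key(gold[[i]], gr[r, ]), "")
    if (nrow(pr) > 0L)
      pcat <- vapply(seq_len(nrow(pr)),
                     function(r) key(pred[[i]], pr[r, ]), "")
    unmatched_gold <- rep(TRUE, length(gk))
    for (r in seq_along(pk)) {
      hit <- match(pk[r], gk[unmatched_gold])
      if (!is.na(hit)) {
        idx <- which(unmatched_gold)[hit]
        unmatched_gold[idx] <- FALSE
        bump(pcat[r], "tp")
      } else bump(pcat[r], "fp")
    }
    for (r in which(unmatched_gold)) bump(gcat[r], "fn")
  }
  cats <- sort(names(acc))
  out <- do.call(rbind, lapply(cats, function(cat) {
    s <- prf(acc[[cat]])
    data.frame(category = cat, tp = acc[[cat]]["tp"], fp = acc[[cat]]["fp"],
               fn = acc[[cat]]["fn"], precision = s["precision"],
               recall = s["recall"], f1 = s["f1"], row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  out
}
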