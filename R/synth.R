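# Deterministic template-based corpus generator.  Templates carry
# hand-authored projective parses (the trigger verb as root), so the
# whole stack is exercisable without an external parser.

ade_lexicon <- function() {
  list(
    Drug = list(
      single = c("methimazole", "gliclazide", "lithium", "ibuprofen",
                 "warfarin", "heparin", "metformin", "cisplatin",
                 "naproxen", "amiodarone", "clozapine", "tamoxifen"),
      multi = list(c("valproic", "acid"), c("fusidic", "acid"),
                   c("acetylsalicylic", "acid"))),
    Disease = list(
      single = c("agranulocytosis", "thyrotoxicosis", "nephritis",
                 "hepatitis", "anemia", "pancytopenia", "hypoglycemia",
                 "seizures", "neutropenia", "rhabdomyolysis"),
      multi = list(c("acute", "hepatitis"), c("renal", "failure"),
                   c("liver", "injury"), c("skin", "rash"),
                   c("aplastic", "anemia"))))
}

bb_lexicon <- function() {
  list(
    Bacteria = list(
      single = c("helicobacter", "campylobacter", "salmonella", "listeria",
                 "shigella", "vibrio", "legionella", "clostridium"),
      multi = list(c("helicobacter", "pylori"), c("bacillus", "subtilis"),
                   c("listeria", "monocytogenes"))),
    Habitat = list(
      single = c("soil", "water", "sediment", "milk", "cheese", "sputum"),
      multi = list(c("human", "gut"), c("dairy", "products"),
                   c("chicken", "skin"), c("gastric", "mucosa"))),
    Geographical = list(
      single = c("france", "japan", "germany", "brazil", "canada", "spain"),
      multi = list()))
}

#' Specification of a synthetic corpus
#'
#' Defines the entity lexicons, sentence templates and sampling rates of
#' the generator. Each template is a sentence skeleton with a trigger
#' word as the parse root and slots for one type-compatible entity pair;
#' relation templates make the pair a gold relation, distractor
#' templates (negated or treatment contexts) do not, so with
#' `noise_rate = 0` the relation label is a deterministic function of
#' the trigger words and the corpus is separable.
#'
#' @param task `"ade"` or `"bb"`.
#' @param distractor_frac fraction of sentences drawn from distractor
#'   templates (compatible pair, no gold relation).
#' @param multi_token_frac probability that an entity slot is filled
#'   with a multi-token lexicon entry (exercises B/I/L labels and
#'   mention-span averaging).
#' @param noise_rate probability that each filler (non-entity,
#'   non-trigger) token is substituted by a label-irrelevant adverb.
#' @param geo_frac for the Lives_In schema, probability that the
#'   location slot is Geographical rather than Habitat.
#' @param seed generator seed.
#' @return list of class `template_spec`.
#' @export
template_spec <- function(task = c("ade", "bb"), distractor_frac = 0.3,
                          multi_token_frac = 0.3, noise_rate = 0,
                          geo_frac = 0.25, seed = 1L) {
  task <- match.arg(task)
  stopifnot(distractor_frac >= 0, distractor_frac <= 1,
            multi_token_frac >= 0, multi_token_frac <= 1,
            noise_rate >= 0, noise_rate <= 1)
  lex <- if (task == "ade") ade_lexicon() else bb_lexicon()
  if (any(vapply(lex, function(l) length(l$single) + length(l$multi), 0L) == 0L))
    stop("empty entity lexicon")
  structure(list(task = task, lexicon = lex,
                 distractor_frac = distractor_frac,
                 multi_token_frac = multi_token_frac,
                 noise_rate = noise_rate, geo_frac = geo_frac,
                 seed = as.integer(seed)),
            class = "template_spec")
}

# draw one entity of `type`: a character vector of tokens
draw_entity <- function(spec, type) {
  lex <- spec$lexicon[[type]]
  use_multi <- length(lex$multi) > 0L && runif(1) < spec$multi_token_frac
  if (use_multi) lex$multi[[sample.int(length(lex$multi), 1L)]]
  else lex$single[sample.int(length(lex$single), 1L)]
}

# assemble a sentence from parts: `parts` is a list of lists with fields
# tokens, pos, deprel (per token), head_mode; entity parts carry a type.
# Internal entity tokens attach to the entity-final token as "compound".
assemble_sentence <- function(parts, root_part, attach, relations,
                              fillable_parts = integer(0),
                              noise_rate = 0) {
  words <- character(0); pos <- character(0)
  heads <- integer(0); deprels <- character(0)
  part_last <- integer(length(parts))   # index of each part's head token
  offset <- 0L
  ent_rows <- empty_entities()
  fillable <- integer(0)
  for (pi in seq_along(parts)) {
    p <- parts[[pi]]
    k <- length(p$tokens)
    idx <- offset + seq_len(k)
    words <- c(words, p$tokens)
    if (!is.null(p$type)) {
      pos <- c(pos, rep("NN", k))
      heads <- c(heads, rep(NA_integer_, k))
      if (k > 1L) heads[idx[-k]] <- idx[k]   # internal tokens -> final token
      deprels <- c(deprels, c(rep("compound", k - 1L), p$deprel))
      ent_rows <- rbind(ent_rows,
                        data.frame(start = idx[1], end = idx[k],
                                   type = p$type, stringsAsFactors = FALSE))
    } else {
      pos <- c(pos, p$pos)
      heads <- c(heads, rep(NA_integer_, k))
      deprels <- c(deprels, p$deprel)
      if (pi %in% fillable_parts) fillable <- c(fillable, idx)
    }
    part_last[pi] <- idx[k]
    offset <- offset + k
  }
  # wire part-level attachments (entity-final / single tokens only)
  for (pi in seq_along(parts)) {
    tgt <- attach[pi]
    heads[part_last[pi]] <- if (pi == root_part) 0L else part_last[tgt]
    p <- parts[[pi]]
    if (is.null(p$type) && length(p$tokens) > 1L) {
      # multi-token fixed parts: chain every earlier token to the last
      idx <- (part_last[pi] - length(p$tokens) + 1L):part_last[pi]
      heads[idx[-length(idx)]] <- idx[length(idx)]
    }
  }
  if (noise_rate > 0 && length(fillable) > 0L) {
    pool <- c("reportedly", "recently", "perhaps", "notably", "apparently")
    for (i in fillable) {
      if (runif(1) < noise_rate) {
        words[i] <- pool[sample.int(length(pool), 1L)]
        pos[i] <- "RB"
      }
    }
  }
  ents <- ent_rows
  rel <- if (nrow(relations) > 0L) relations else empty_relations()
  annotated_sentence(
    tokens = data.frame(surface = words, norm = normalize_token(words),
                        pos = pos, stringsAsFactors = FALSE),
    heads = heads, deprels = deprels, entities = ents, relations = rel)
}

tok <- function(tokens, pos, deprel) {
  list(tokens = tokens, pos = pos, deprel = deprel)
}
ent <- function(tokens, type, deprel) {
  list(tokens = tokens, type = type, deprel = deprel)
}

rel_pair <- function(type) {
  data.frame(arg1 = 1L, arg2 = 2L, type = type, stringsAsFactors = FALSE)
}

# ADE templates -------------------------------------------------------
ade_templates <- function(spec) {
  list(
    # "<drug> - induced <disease> ."  (relation; root "induced")
    function(a, b) assemble_sentence(
      parts = list(ent(a, "Drug", "nsubj"), tok("-", "HYPH", "punct"),
                   tok("induced", "VBN", "root"), ent(b, "Disease", "dobj"),
                   tok(".", ".", "punct")),
      root_part = 3L, attach = c(3L, 3L, 0L, 3L, 3L),
      relations = rel_pair("ADE"), noise_rate = spec$noise_rate),
    # "the patient developed <disease> after taking <drug> ."
    function(a, b) assemble_sentence(
      parts = list(tok("the", "DT", "det"), tok("patient", "NN", "nsubj"),
                   tok("developed", "VBD", "root"), ent(b, "Disease", "dobj"),
                   tok("after", "IN", "mark"), tok("taking", "VBG", "advcl"),
                   ent(a, "Drug", "dobj"), tok(".", ".", "punct")),
      root_part = 3L, attach = c(2L, 3L, 0L, 3L, 6L, 3L, 6L, 3L),
      relations = data.frame(arg1 = 2L, arg2 = 1L, type = "ADE",
                             stringsAsFactors = FALSE),
      fillable_parts = c(1L, 2L, 5L), noise_rate = spec$noise_rate),
    # distractor: "<drug> was given for <disease> ."  (treatment, no ADE)
    function(a, b) assemble_sentence(
      parts = list(ent(a, "Drug", "nsubjpass"), tok("was", "VBD", "auxpass"),
                   tok("given", "VBN", "root"), tok("for", "IN", "case"),
                   ent(b, "Disease", "nmod"), tok(".", ".", "punct")),
      root_part = 3L, attach = c(3L, 3L, 0L, 5L, 3L, 3L),
      relations = empty_relations(),
      fillable_parts = c(2L, 4L), noise_rate = spec$noise_rate)
  )
}

# Lives_In templates --------------------------------------------------
bb_templates <- function(spec) {
  list(
    # "<bacteria> was isolated from <loc> ."
    function(a, b, loc_type) assemble_sentence(
      parts = list(ent(a, "Bacteria", "nsubjpass"),
                   tok("was", "VBD", "auxpass"),
                   tok("isolated", "VBN", "root"), tok("from", "IN", "case"),
                   ent(b, loc_type, "nmod"), tok(".", ".", "punct")),
      root_part = 3L, attach = c(3L, 3L, 0L, 5L, 3L, 3L),
      relations = rel_pair("Lives_In"),
      fillable_parts = c(2L, 4L), noise_rate = spec$noise_rate),
    # "<bacteria> lives in <loc> ."
    function(a, b, loc_type) assemble_sentence(
      parts = list(ent(a, "Bacteria", "nsubj"), tok("lives", "VBZ", "root"),
                   tok("in", "IN", "case"), ent(b, loc_type, "nmod"),
                   tok(".", ".", "punct")),
      root_part = 2L, attach = c(2L, 0L, 4L, 2L, 2L),
      relations = rel_pair("Lives_In"),
      fillable_parts = 3L, noise_rate = spec$noise_rate),
    # distractor: "<bacteria> was not detected in <loc> ."
    function(a, b, loc_type) assemble_sentence(
      parts = list(ent(a, "Bacteria", "nsubjpass"),
                   tok("was", "VBD", "auxpass"), tok("not", "RB", "neg"),
                   tok("detected", "VBN", "root"), tok("in", "IN", "case"),
                   ent(b, loc_type, "nmod"), tok(".", ".", "punct")),
      root_part = 4L, attach = c(4L, 4L, 4L, 0L, 6L, 4L, 4L),
      relations = empty_relations(),
      fillable_parts = c(2L, 5L), noise_rate = spec$noise_rate)
  )
}

#' Generate a synthetic annotated corpus
#'
#' Deterministic under `spec$seed`. Each sentence instantiates one
#' template with a freshly drawn type-compatible entity pair; with
#' probability `distractor_frac` the template is a distractor (no gold
#' relation). When `dir` is given, the corpus is also written in all
#' three dialects via [write_corpus()], and the written files round-trip
#' through the readers.
#'
#' @param spec a [template_spec()].
#' @param n number of sentences (>= 1).
#' @param dir optional output directory.
#' @return list of `annotated_sentence`; when `dir` is given, the file
#'   paths are attached as attribute `files`.
#' @export
generate_corpus <- function(spec, n, dir = NULL) {
  stopifnot(inherits(spec, "template_spec"), n >= 1L)
  set.seed(spec$seed)
  tmpl <- if (spec$task == "ade") ade_templates(spec) else bb_templates(spec)
  n_rel <- length(tmpl) - 1L     # last template is the distractor
  out <- vector("list", n)
  for (i in seq_len(n)) {
    is_distractor <- runif(1) < spec$distractor_frac
    ti <- if (is_distractor) length(tmpl) else sample.int(n_rel, 1L)
    if (spec$task == "ade") {
      a <- draw_entity(spec, "Drug")
      b <- draw_entity(spec, "Disease")
      out[[i]] <- tmpl[[ti]](a, b)
    } else {
      loc_type <- if (runif(1) < spec$geo_frac) "Geographical" else "Habitat"
      a <- draw_entity(spec, "Bacteria")
      b <- draw_entity(spec, loc_type)
      out[[i]] <- tmpl[[ti]](a, b, loc_type)
    }
  }
  if (!is.null(dir)) attr(out, "files") <- write_corpus(out, dir)
  out
}

#' Plant counted errors into predictions
#'
#' Starting from a perfect copy of the gold annotations, injects exactly
#' the requested numbers of categorized errors, for exercising the
#' scoring and error-taxonomy code. Plan fields (all default 0):
#' * `entity_boundary` -- shift a relation-free mention's boundary by one
#'   token (one boundary FP plus one boundary FN);
#' * `entity_type` -- flip a relation-free mention's type (one type FP
#'   plus one type FN);
#' * `entity_miss` -- delete a relation-free mention (one boundary FN);
#' * `entity_spurious` -- add a mention over an uncovered token (one
#'   boundary FP);
#' * `relation_wrong` -- add a relation between two correctly predicted
#'   mentions of a distractor sentence (FP, "entities correct");
#' * `relation_miss` -- delete a gold relation, keeping its argument
#'   mentions (FN, "entities found");
#' * `relation_arg_lost` -- delete a mention that is a relation argument
#'   together with its relation (one boundary entity FN plus one
#'   relation FN, "entities not found").
#'
#' @param corpus gold corpus from [generate_corpus()].
#' @param plan named list/vector of error counts.
#' @return list of predicted `annotated_sentence` with attribute
#'   `planted` (the realized counts).
#' @export
plant_errors <- function(corpus, plan = list()) {
  fields <- c("entity_boundary", "entity_type", "entity_miss",
              "entity_spurious", "relation_wrong", "relation_miss",
              "relation_arg_lost")
  todo <- stats::setNames(rep(0L, length(fields)), fields)
  bad <- setdiff(names(plan), fields)
  if (length(bad) > 0L) stop("unknown plan fields: ", paste(bad, collapse = ", "))
  todo[names(plan)] <- as.integer(unlist(plan))
  if (any(todo < 0L)) stop("error counts must be non-negative")
  pred <- lapply(corpus, function(s) {
    annotated_sentence(tokens = s$tokens, heads = s$heads,
                       deprels = s$deprels, entities = s$entities,
                       relations = s$relations, validate = FALSE)
  })
  planted <- todo * 0L

  drop_entity <- function(sent, row) {
    keep <- setdiff(seq_len(nrow(sent$entities)), row)
    remap <- match(seq_len(nrow(sent$entities)), keep)
    rel <- sent$relations
    rel <- rel[!is.na(remap[rel$arg1]) & !is.na(remap[rel$arg2]), , drop = FALSE]
    rel$arg1 <- remap[rel$arg1]; rel$arg2 <- remap[rel$arg2]
    sent$entities <- sent$entities[keep, , drop = FALSE]
    rownames(sent$entities) <- NULL
    sent$relations <- rel
    sent
  }

  for (si in seq_along(pred)) {
    if (all(todo == planted)) break
    s <- pred[[si]]
    n <- nrow(s$tokens)
    gold_keys <- entity_keys(corpus[[si]]$entities)   # sentence-local
    in_rel <- unique(c(s$relations$arg1, s$relations$arg2))
    free <- setdiff(seq_len(nrow(s$entities)), in_rel)

    if (planted["entity_boundary"] < todo["entity_boundary"] && length(free) > 0L) {
      r <- free[1]
      new_end <- s$entities$end[r] + 1L
      covered <- unlist(mapply(seq, s$entities$start, s$entities$end,
                               SIMPLIFY = FALSE))
      if (new_end <= n && !(new_end %in% covered)) {
        key <- paste(s$entities$start[r], new_end, s$entities$type[r])
        if (!(key %in% gold_keys)) {
          s$entities$end[r] <- new_end
          planted["entity_boundary"] <- planted["entity_boundary"] + 1L
          free <- free[-1]
        }
      }
    }
    if (planted["entity_type"] < todo["entity_type"] && length(free) > 0L) {
      r <- free[1]
      types <- unique(unlist(lapply(corpus, function(x) x$entities$type)))
      other <- setdiff(types, s$entities$type[r])
      if (length(other) > 0L) {
        s$entities$type[r] <- other[1]
        planted["entity_type"] <- planted["entity_type"] + 1L
        free <- free[-1]
      }
    }
    if (planted["entity_miss"] < todo["entity_miss"] && length(free) > 0L) {
      r <- free[1]
      s <- drop_entity(s, r)
      planted["entity_miss"] <- planted["entity_miss"] + 1L
      in_rel <- unique(c(s$relations$arg1, s$relations$arg2))
      free <- setdiff(seq_len(nrow(s$entities)), in_rel)
    }
    if (planted["entity_spurious"] < todo["entity_spurious"]) {
      covered <- unlist(mapply(seq, s$entities$start, s$entities$end,
                               SIMPLIFY = FALSE))
      open <- setdiff(seq_len(n), covered)
      if (length(open) > 0L) {
        ty <- corpus[[si]]$entities$type[1]
        if (is.na(ty)) ty <- "Drug"
        key <- paste(open[1], open[1], ty)
        if (!(key %in% gold_keys)) {
          s$entities <- rbind(s$entities,
                              data.frame(start = open[1], end = open[1],
                                         type = ty, stringsAsFactors = FALSE))
          planted["entity_spurious"] <- planted["entity_spurious"] + 1L
        }
      }
    }
    if (planted["relation_wrong"] < todo["relation_wrong"] &&
        nrow(corpus[[si]]$relations) == 0L && nrow(s$entities) >= 2L &&
        identical(s$entities, corpus[[si]]$entities)) {
      rtype <- if (any(s$entities$type == "Drug")) "ADE" else "Lives_In"
      s$relations <- rbind(s$relations,
                           data.frame(arg1 = 1L, arg2 = 2L, type = rtype,
                                      stringsAsFactors = FALSE))
      planted["relation_wrong"] <- planted["relation_wrong"] + 1L
    }
    if (planted["relation_miss"] < todo["relation_miss"] &&
        nrow(s$relations) > 0L && nrow(corpus[[si]]$relations) > 0L &&
        identical(s$entities, corpus[[si]]$entities)) {
      s$relations <- s$relations[-1, , drop = FALSE]
      planted["relation_miss"] <- planted["relation_miss"] + 1L
    }
    if (planted["relation_arg_lost"] < todo["relation_arg_lost"] &&
        nrow(s$relations) > 0L) {
      r <- s$relations$arg1[1]
      s <- drop_entity(s, r)
      planted["relation_arg_lost"] <- planted["relation_arg_lost"] + 1L
    }
    pred[[si]] <- s
  }
  if (!all(planted == todo))
    stop("could not realize the full error plan; shortfall in: ",
         paste(names(todo)[planted < todo], collapse = ", "))
  attr(pred, "planted") <- planted
  pred
}
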