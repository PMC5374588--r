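test_that("strict entity matching handles the boundary cases", {
  g <- data.frame(start = c(1L, 4L), end = c(1L, 5L),
                  type = c("Drug", "Disease"), stringsAsFactors = FALSE)
  expect_equal(match_entities(g, g), c(tp = 2L, fp = 0L, fn = 0L))
  off <- g; off$end[2] <- 6L        # boundary off by one token
  expect_equal(match_entities(g, off), c(tp = 1L, fp = 1L, fn = 1L))
  expect_equal(match_entities(g, empty_entities()),
               c(tp = 0L, fp = 0L, fn = 2L))
})

test_that("entity matching equals the exhaustive matching oracle", {
  set.seed(44)
  types <- c("Drug", "Disease")
  rand_set <- function() {
    k <- sample(0:5, 1)
    if (k == 0L) return(empty_entities())
    d <- data.frame(start = sample(1:6, k, replace = TRUE),
                    end = NA_integer_,
                    type = sample(types, k, replace = TRUE),
                    stringsAsFactors = FALSE)
    d$end <- d$start + sample(0:1, k, replace = TRUE)
    d
  }
  for (i in 1:50) {
    g <- rand_set(); p <- rand_set()
    expect_equal(match_entities(g, p), oracle_match(g, p))
  }
})

test_that("strict relation matching requires type and both arguments", {
  s <- fig_sentence()
  expect_equal(match_relations(s, s), c(tp = 1L, fp = 0L, fn = 0L))
  wrong_type <- s
  wrong_type$relations$type <- "OTHER"
  expect_equal(match_relations(s, wrong_type), c(tp = 0L, fp = 1L, fn = 1L))
  bad_arg <- s
  bad_arg$entities$end[2] <- 4L     # argument boundary error
  expect_equal(match_relations(s, bad_arg), c(tp = 0L, fp = 1L, fn = 1L))
  # constructed 3-relation document with one argument boundary error
  g3 <- annotated_sentence(
    tokens = data.frame(surface = letters[1:7], pos = rep("NN", 7),
                        stringsAsFactors = FALSE),
    heads = c(2L, 0L, 2L, 2L, 2L, 2L, 2L),
    deprels = c("nsubj", "root", rep("dobj", 5)),
    entities = data.frame(start = c(1L, 3L, 4L, 5L), end = c(1L, 3L, 4L, 5L),
                          type = c("Drug", "Disease", "Disease", "Disease"),
                          stringsAsFactors = FALSE),
    relations = data.frame(arg1 = 1L, arg2 = 2:4, type = "ADE",
                           stringsAsFactors = FALSE))
  p3 <- g3
  p3$entities$start[2] <- 2L        # one argument mention shifted
  expect_equal(match_relations(g3, p3), c(tp = 2L, fp = 1L, fn = 1L))
})

test_that("precision/recall/F1 follow the defining formulas", {
  expect_equal(prf(c(tp = 1, fp = 1, fn = 1)),
               c(precision = 0.5, recall = 0.5, f1 = 0.5))
  expect_equal(prf(c(tp = 0, fp = 0, fn = 0)),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(unname(prf(c(tp = 3, fp = 1, fn = 2))[1:2]), c(0.75, 0.6))
  # swapping gold and prediction swaps precision and recall
  g <- data.frame(start = 1:3, end = 1:3, type = "Drug",
                  stringsAsFactors = FALSE)
  p <- g[1:2, ]
  a <- prf(match_entities(g, p)); b <- prf(match_entities(p, g))
  expect_equal(a[["precision"]], b[["recall"]])
  expect_equal(a[["recall"]], b[["precision"]])
})

test_that("published result tables are internally F1-consistent", {
  # every printed (P, R, F1) triple; recomputing F1 from the printed P and
  # R agrees with the printed F1 to one unit in the last printed digit
  triples <- rbind(
    # ADE task comparison (entity, relation)
    c(42.1, 76.3, 54.3), c(79.5, 79.6, 79.5), c(64.0, 62.9, 63.4),
    c(82.7, 86.7, 84.6), c(67.5, 75.8, 71.4),
    # Lives_In task comparison
    c(19.3, 19.1, 19.2), c(33.1, 13.3, 19.0), c(49.8, 19.9, 28.4),
    # annotator agreement
    c(95.5, 62.1, 75.3), c(95.2, 31.1, 46.8),
    # entity-feature contributions
    c(80.1, 83.6, 81.8), c(80.2, 84.0, 82.1), c(80.5, 84.7, 82.5),
    c(82.5, 85.5, 84.0), c(82.4, 86.4, 84.3),
    c(67.1, 56.7, 61.4), c(66.4, 59.4, 62.7), c(69.4, 60.8, 64.8),
    c(66.1, 59.5, 62.6), c(68.0, 63.4, 65.6),
    # relation-feature contributions
    c(62.7, 69.9, 66.1), c(63.3, 71.0, 66.9), c(63.4, 71.2, 67.1),
    c(67.3, 75.7, 71.3),
    c(34.5, 20.4, 25.6), c(42.0, 19.9, 27.0), c(34.1, 24.7, 28.6),
    c(42.7, 25.2, 31.7),
    # joint vs pipeline
    c(79.6, 83.5, 81.5), c(62.5, 69.9, 66.0), c(80.1, 83.6, 81.8),
    c(62.7, 69.9, 66.1),
    c(67.2, 52.0, 58.6), c(26.6, 17.7, 21.2), c(67.1, 56.7, 61.4),
    c(34.5, 20.4, 25.6),
    # co-occurrence / gold-mention baselines
    c(97.3, 100.0, 98.6), c(97.5, 99.9, 98.7), c(34.9, 72.5, 47.1),
    c(58.7, 43.6, 50.0))
  recomputed <- f1_score(triples[, 1], triples[, 2])
  expect_true(all(abs(recomputed - triples[, 3]) <= 0.1))
})

test_that("fold assignment is disjoint, covering and deterministic", {
  f1 <- make_folds(100, 10, seed = 3)
  f2 <- make_folds(100, 10, seed = 3)
  expect_identical(f1, f2)
  expect_equal(as.vector(table(f1)), rep(10L, 10))
  expect_error(make_folds(100, 1), "2 folds")
  # macro average of identical fold scores is that score
  expect_equal(mean(rep(0.37, 10)), 0.37)
})

test_that("cross-validation trains per fold and macro-averages", {
  corp <- generate_corpus(template_spec("ade", seed = 61), 40)
  cfg <- toy_config(epochs = 1L, seed = 2L)
  cv <- cross_validate(corp, cfg, "ade", k = 4L)
  expect_equal(nrow(cv$folds), 4L)
  expect_equal(cv$entity[["f1"]], mean(cv$folds$entity_f1))
  expect_equal(cv$relation[["precision"]], mean(cv$folds$relation_p))
  expect_true(all(cv$folds$entity_f1 >= 0 & cv$folds$entity_f1 <= 1))
})

test_that("error taxonomy attributes planted errors exactly", {
  corp <- generate_corpus(template_spec("ade", seed = 71), 60)
  plan <- list(entity_boundary = 5L, entity_type = 3L, entity_miss = 2L,
               entity_spurious = 4L, relation_wrong = 3L,
               relation_miss = 2L, relation_arg_lost = 2L)
  pred <- plant_errors(corp, plan)
  expect_equal(unname(attr(pred, "planted")), unname(unlist(plan)[
    names(attr(pred, "planted"))]))
  rep <- error_taxonomy(corp, pred)
  ent <- rep$entity; rel <- rep$relation
  get <- function(tab, cls, cat) tab$count[tab$class == cls & tab$category == cat]
  expect_equal(get(ent, "FP", "incorrect boundaries"), 5L + 4L)
  expect_equal(get(ent, "FP", "incorrect types"), 3L)
  expect_equal(get(ent, "FN", "incorrect boundaries"), 5L + 2L + 2L)
  expect_equal(get(ent, "FN", "incorrect types"), 3L)
  expect_equal(get(rel, "FP", "entities correct, relations wrong"), 3L)
  expect_equal(get(rel, "FP", "entities incorrectly recognized"), 0L)
  expect_equal(get(rel, "FN", "entities found, relations not found"), 2L)
  expect_equal(get(rel, "FN", "entities not found"), 2L)
  # percentages sum to 100 within each table
  expect_equal(sum(ent$pct), 100, tolerance = 0.1)
  expect_equal(sum(rel$pct), 100, tolerance = 0.1)
  # zero plan: perfect predictions
  perfect <- plant_errors(corp, list())
  sc <- score_corpus(corp, perfect)
  expect_equal(unname(sc$entity), c(1, 1, 1))
  expect_equal(unname(sc$relation), c(1, 1, 1))
  # category counts tie out with the raw confusion counts
  sc2 <- score_corpus(corp, pred)
  expect_equal(sum(ent$count),
               sc2$counts$entity[["fp"]] + sc2$counts$entity[["fn"]])
  expect_equal(sum(rel$count),
               sc2$counts$relation[["fp"]] + sc2$counts$relation[["fn"]])
})

test_that("co-occurrence baseline has perfect recall, diluted precision", {
  # distractor-free corpus: every compatible pair is a gold relation
  corp0 <- generate_corpus(template_spec("ade", distractor_frac = 0,
                                         seed = 81), 30)
  sc0 <- score_corpus(corp0, cooccurrence_baseline(corp0, "ade"))
  expect_equal(unname(sc0$relation), c(1, 1, 1))
  # one gold relation among 4 compatible pairs: R = 1, P = 0.25
  s <- annotated_sentence(
    tokens = data.frame(surface = c("d1", "d2", "caused", "x", "y"),
                        pos = rep("NN", 5), stringsAsFactors = FALSE),
    heads = c(3L, 1L, 0L, 3L, 4L),
    deprels = c("nsubj", "conj", "root", "dobj", "conj"),
    entities = data.frame(start = c(1L, 2L, 4L, 5L), end = c(1L, 2L, 4L, 5L),
                          type = c("Drug", "Drug", "Disease", "Disease"),
                          stringsAsFactors = FALSE),
    relations = data.frame(arg1 = 1L, arg2 = 3L, type = "ADE",
                           stringsAsFactors = FALSE))
  sc <- score_corpus(list(s), cooccurrence_baseline(list(s), "ade"))
  expect_equal(sc$relation[["recall"]], 1)
  expect_equal(sc$relation[["precision"]], 0.25)
  # recall dominates any classifier over the same gold-mention candidates
  corp <- generate_corpus(template_spec("ade", seed = 82), 20)
  sc_any <- score_corpus(corp, cooccurrence_baseline(corp, "ade"))
  expect_equal(sc_any$relation[["recall"]], 1)
})

test_that("per-category breakdown partitions the relation counts", {
  corp <- generate_corpus(template_spec("bb", seed = 91, geo_frac = 0.4), 40)
  pred <- plant_errors(corp, list(relation_miss = 3L))
  br <- breakdown_by_category(corp, pred)
  expect_true(all(br$category %in% c("Habitat", "Geographical")))
  overall <- score_corpus(corp, pred)$counts$relation
  expect_equal(sum(br$tp), overall[["tp"]])
  expect_equal(sum(br$fn), overall[["fn"]])
  # single-category case: overall F1 equals that category's F1
  hab <- corp[vapply(corp, function(s)
    nrow(s$relations) > 0 && all(s$entities$type[s$relations$arg2] == "Habitat"),
    TRUE)]
  br2 <- breakdown_by_category(hab, hab)
  expect_equal(br2$f1[br2$category == "Habitat"], 1)
  expect_equal(nrow(br2), 1L)
})
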