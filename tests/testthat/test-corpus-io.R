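test_that("tokenizer splits on whitespace and emits punctuation tokens", {
  expect_equal(tokenize("gliclazide-induced acute hepatitis")$surface,
               c("gliclazide", "-", "induced", "acute", "hepatitis"))
  expect_equal(tokenize("abc")$surface, "abc")
  expect_equal(tokenize("a,b")$surface, c("a", ",", "b"))
  expect_equal(tokenize("(THP-1) cells.")$surface,
               c("(", "THP", "-", "1", ")", "cells", "."))
  # offsets reconstruct the original text exactly
  txt <- "A woman, aged 42-45, was treated."
  tk <- tokenize(txt)
  expect_equal(substring(txt, tk$start, tk$end), tk$surface)
  expect_error(tokenize(""), "empty")
})

test_that("normalization lowercases and folds each digit to zero", {
  expect_equal(normalize_token("THP-1"), "thp-0")
  expect_equal(normalize_token("Gliclazide"), "gliclazide")
  expect_equal(normalize_token("1400"), "0000")
  expect_equal(normalize_token(c("A1", "b2C3")), c("a0", "b0c0"))
})

test_that("BILOU encoding follows the scheme definitions", {
  ents <- data.frame(start = c(1L, 4L), end = c(1L, 5L),
                     type = c("Drug", "Disease"), stringsAsFactors = FALSE)
  expect_equal(encode_bilou(5L, ents),
               c("U-Drug", "O", "O", "B-Disease", "L-Disease"))
  expect_equal(encode_bilou(4L, empty_entities()), rep("O", 4))
  ents3 <- data.frame(start = 2L, end = 4L, type = "Habitat",
                      stringsAsFactors = FALSE)
  expect_equal(encode_bilou(5L, ents3),
               c("O", "B-Habitat", "I-Habitat", "L-Habitat", "O"))
  over <- data.frame(start = c(1L, 2L), end = c(2L, 3L),
                     type = c("Drug", "Drug"), stringsAsFactors = FALSE)
  expect_error(encode_bilou(3L, over), "overlapping")
})

test_that("decoding the worked-example gold sequence yields three mentions", {
  labels <- c("O", "O", "O", "O", "O", "O", "U-Disease", "O", "U-Drug",
              "O", "U-Disease", "O")
  m <- decode_bilou(labels)
  expect_equal(nrow(m), 3L)
  expect_equal(m$type, c("Disease", "Drug", "Disease"))
  expect_equal(m$start, c(7L, 9L, 11L))
})

test_that("encode/decode round-trips on random synthetic sentences", {
  set.seed(202)
  for (task in c("ade", "bb")) {
    corp <- generate_corpus(template_spec(task, seed = 101), 50)
    for (s in corp) {
      lab <- encode_bilou(nrow(s$tokens), s$entities)
      expect_identical(canon_entities(decode_bilou(lab)),
                       canon_entities(s$entities))
    }
  }
})

test_that("repair rule matches the reference state machine on all short sequences", {
  labs <- bilou_labels(c("Drug", "Disease"))
  # all pairs
  for (l1 in labs) for (l2 in labs) {
    seq2 <- c(l1, l2)
    expect_identical(decode_bilou(seq2), reference_decode(seq2),
                     info = paste(seq2, collapse = " "))
  }
  # random longer sequences
  set.seed(7)
  for (k in 1:200) {
    seqk <- sample(labs, sample(3:8, 1), replace = TRUE)
    expect_identical(decode_bilou(seqk), reference_decode(seqk),
                     info = paste(seqk, collapse = " "))
  }
  # the documented example: I/L with no B becomes one two-token mention
  expect_equal(decode_bilou(c("I-Drug", "L-Drug")),
               data.frame(start = 1L, end = 2L, type = "Drug",
                          stringsAsFactors = FALSE))
})

test_that("decoded mentions never overlap, even for invalid sequences", {
  labs <- bilou_labels(c("Drug", "Disease"))
  set.seed(31)
  for (k in 1:100) {
    m <- decode_bilou(sample(labs, 10, replace = TRUE))
    if (nrow(m) >= 2L) {
      m <- m[order(m$start), ]
      expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    }
  }
})

test_that("nested filter keeps the longer mention", {
  ents <- data.frame(start = c(2L, 2L), end = c(4L, 2L),
                     type = c("Disease", "Drug"), stringsAsFactors = FALSE)
  out <- filter_nested_entities(ents)
  expect_equal(nrow(out), 1L)
  expect_equal(out$type, "Disease")
  expect_equal(attr(out, "n_dropped"), 1L)
})

test_that("standoff reader aligns, filters and counts drops", {
  txt <- "Helicobacter lives in soil.\nListeria was found."
  a1 <- paste(
    "T1\tBacteria 0 12\tHelicobacter",
    "T2\tHabitat 22 26\tsoil",
    "T3\tBacteria 28 36\tListeria",
    "T4\tHabitat 22 27\tsoil.",        # nests T2 (longer, survives)
    "T5\tHabitat 1 4\teli",            # mid-token, cannot align
    "T6\tHabitat 0 4;8 12\tdisc",      # discontinuous
    sep = "\n")
  a2 <- paste(
    "R1\tLives_In Arg1:T1 Arg2:T4",
    "R2\tLives_In Arg1:T3 Arg2:T4",    # cross-sentence
    sep = "\n")
  conll <- paste(
    "1\tHelicobacter\tNN\t2\tnsubj",
    "2\tlives\tVBZ\t0\troot",
    "3\tin\tIN\t4\tcase",
    "4\tsoil\tNN\t2\tnmod",
    "5\t.\t.\t2\tpunct",
    "",
    "1\tListeria\tNN\t3\tnsubjpass",
    "2\twas\tVBD\t3\tauxpass",
    "3\tfound\tVBN\t0\troot",
    "4\t.\t.\t3\tpunct",
    sep = "\n")
  corp <- read_standoff(txt, a1, a2, conll)
  drops <- attr(corp, "drop_counts")
  expect_length(corp, 2L)
  # first token of sentence 1 covers chars 0-12 -> token span [1,1]
  expect_equal(corp[[1]]$entities$start[corp[[1]]$entities$type == "Bacteria"], 1L)
  expect_equal(drops[["discontinuous"]], 1L)
  expect_equal(drops[["unaligned"]], 1L)
  expect_equal(drops[["nested"]], 1L)            # T2 inside T4
  expect_equal(drops[["cross_sentence_relation"]], 1L)
  # surviving relation points at the longer habitat span "soil."
  expect_equal(nrow(corp[[1]]$relations), 1L)
  hab <- corp[[1]]$entities[corp[[1]]$relations$arg2[1], ]
  expect_equal(c(hab$start, hab$end), c(4L, 5L))
})

test_that("record reader removes relations with nested gold annotations", {
  # drug "lithium" inside disease "lithium intoxication"
  line <- "lithium caused lithium intoxication|Drug,0,7;Disease,15,35|1,2,ADE"
  conll <- paste(
    "1\tlithium\tNN\t2\tnsubj",
    "2\tcaused\tVBD\t0\troot",
    "3\tlithium\tNN\t4\tcompound",
    "4\tintoxication\tNN\t2\tdobj",
    sep = "\n")
  corp <- read_ade(line, conll)
  expect_equal(nrow(corp[[1]]$entities), 2L)     # both drug and disease align
  # now the truly nested case: spans over the same tokens
  line2 <- "lithium intoxication occurred|Drug,0,7;Disease,0,20|1,2,ADE"
  conll2 <- paste(
    "1\tlithium\tNN\t2\tcompound",
    "2\tintoxication\tNN\t3\tnsubj",
    "3\toccurred\tVBD\t0\troot",
    sep = "\n")
  corp2 <- read_ade(line2, conll2)
  drops <- attr(corp2, "drop_counts")
  expect_equal(nrow(corp2[[1]]$entities), 1L)
  expect_equal(corp2[[1]]$entities$type, "Disease")  # longer survives
  expect_equal(nrow(corp2[[1]]$relations), 0L)
  expect_equal(drops[["nested"]], 1L)
  expect_equal(drops[["dangling_relation"]], 1L)
})

test_that("record reader handles the plain and empty cases", {
  line <- "warfarin caused rash|Drug,0,8;Disease,16,20|1,2,ADE"
  conll <- paste(
    "1\twarfarin\tNN\t2\tnsubj",
    "2\tcaused\tVBD\t0\troot",
    "3\trash\tNN\t2\tdobj",
    sep = "\n")
  corp <- read_ade(line, conll)
  expect_length(corp, 1L)
  expect_equal(nrow(corp[[1]]$entities), 2L)
  expect_equal(nrow(corp[[1]]$relations), 1L)
  empty <- read_ade(character(0), list())
  expect_length(empty, 0L)
  expect_equal(sum(attr(empty, "drop_counts")), 0L)
})

test_that("written corpora round-trip through both readers", {
  for (task in c("ade", "bb")) {
    corp <- generate_corpus(template_spec(task, seed = 55), 15)
    dir <- withr::local_tempdir()
    paths <- write_corpus(corp, dir)
    back <- read_standoff(paste(readLines(paths["txt"]), collapse = "\n"),
                          paste(readLines(paths["a1"]), collapse = "\n"),
                          paste(readLines(paths["a2"]), collapse = "\n"),
                          paste(readLines(paths["conll"]), collapse = "\n"))
    expect_length(back, length(corp))
    expect_equal(sum(attr(back, "drop_counts")), 0L)
    back2 <- read_ade(readLines(paths["ade"]),
                      paste(readLines(paths["conll"]), collapse = "\n"))
    for (i in seq_along(corp)) {
      expect_identical(canon_entities(back[[i]]$entities),
                       canon_entities(corp[[i]]$entities))
      expect_identical(canon_entities(back2[[i]]$entities),
                       canon_entities(corp[[i]]$entities))
      expect_equal(nrow(back[[i]]$relations), nrow(corp[[i]]$relations))
      expect_equal(nrow(back2[[i]]$relations), nrow(corp[[i]]$relations))
    }
  }
})

test_that("whole preprocessed corpora satisfy the structural invariants", {
  for (task in c("ade", "bb")) {
    corp <- generate_corpus(template_spec(task, seed = 77), 40)
    for (s in corp) {
      expect_silent(bionerel:::validate_sentence(s))
      expect_true(all(s$relations$arg1 != s$relations$arg2))
    }
  }
})

test_that("the shipped sample corpus parses in both dialects", {
  dir <- system.file("extdata", "ade_sample", package = "bionerel")
  corp <- read_ade(readLines(file.path(dir, "records.ade")),
                   paste(readLines(file.path(dir, "parses.conll")),
                         collapse = "\n"))
  expect_length(corp, 6L)
  expect_true(all(vapply(corp, function(s) nrow(s$entities), 0L) == 2L))
  so <- read_standoff(paste(readLines(file.path(dir, "doc.txt")),
                            collapse = "\n"),
                      paste(readLines(file.path(dir, "doc.a1")),
                            collapse = "\n"),
                      paste(readLines(file.path(dir, "doc.a2")),
                            collapse = "\n"),
                      paste(readLines(file.path(dir, "parses.conll")),
                            collapse = "\n"))
  for (i in seq_along(corp))
    expect_identical(canon_entities(so[[i]]$entities),
                     canon_entities(corp[[i]]$entities))
})
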