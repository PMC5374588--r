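corp <- generate_corpus(template_spec("ade", seed = 33), 10)
model <- toy_model(corp)
sent <- fig_sentence()
states <- encode_sentence(model, sent)

test_that("entity representation is the mean of shared states over the span", {
  # single-token mention: exactly the concatenated states of that token
  r <- entity_representation(model, states, list(start = 1L, end = 1L))
  expect_equal(r, c(states$hf[, 1], states$hb[, 1]))
  # multi-token mention: the arithmetic mean
  r2 <- entity_representation(model, states, list(start = 4L, end = 5L))
  expect_equal(r2, (c(states$hf[, 4], states$hb[, 4]) +
                      c(states$hf[, 5], states$hb[, 5])) / 2)
  # published dimensions: 2 * 100 = 200
  expect_equal(bionerel:::entity_repr_dim(model_config()), 200L)
  expect_length(r, 2L * model$config$dim_hidden)
})

test_that("relation hidden layer consumes the documented concatenation", {
  full <- model_config()
  expect_equal(4L * full$dim_sdp_hidden + 2L *
                 bionerel:::entity_repr_dim(full), 800L)
  # pipeline: word embedding (200) + dependency embedding (25) per step
  pip <- model_config(mode = "pipeline")
  expect_equal(bionerel:::sdp_input_dim(pip), 225L)
  expect_equal(bionerel:::sdp_input_dim(full), 225L)
})

test_that("path LSTM degenerates correctly and zeroes with zero params", {
  sdp <- shortest_dep_path(sent$heads, 1L, 5L)
  enc <- sdp_encode(model, states, sent, sdp)
  expect_length(enc$up_a, model$config$dim_sdp_hidden)
  # zero path LSTMs -> four zero vectors
  m0 <- model
  for (nm in c("sdpf.W", "sdpf.U", "sdpf.b", "sdpb.W", "sdpb.U", "sdpb.b"))
    m0$params[[nm]][] <- 0
  enc0 <- sdp_encode(m0, states, sent, sdp)
  expect_equal(unname(unlist(enc0)), rep(0, 4L * model$config$dim_sdp_hidden))
  # LCA = anchor on one side: that side is a single LSTM step from zero
  sdp2 <- shortest_dep_path(c(2L, 0L, 2L), 1L, 2L)
  s3 <- tiny_sentence()
  st3 <- encode_sentence(model, s3)
  enc2 <- sdp_encode(model, st3, s3, sdp2)
  x <- bionerel:::sdp_inputs(model, st3, s3, 2L)
  one <- bionerel:::lstm_forward(x, model$params$sdpf.W, model$params$sdpf.U,
                                 model$params$sdpf.b)
  expect_equal(enc2$up_b, one$H[, 1])
})

test_that("a two-node path matches a hand-unrolled LSTM", {
  s3 <- tiny_sentence()
  st3 <- encode_sentence(model, s3)
  X <- bionerel:::sdp_inputs(model, st3, s3, c(1L, 2L))
  p <- model$params
  H <- model$config$dim_sdp_hidden
  step <- function(x, h, c_) {
    z <- as.numeric(p$sdpf.W %*% x) + as.numeric(p$sdpf.U %*% h) + p$sdpf.b
    i <- 1 / (1 + exp(-z[1:H])); f <- 1 / (1 + exp(-z[H + 1:H]))
    o <- 1 / (1 + exp(-z[2 * H + 1:H])); g <- tanh(z[3 * H + 1:H])
    cn <- f * c_ + i * g
    list(h = o * tanh(cn), c = cn)
  }
  s1 <- step(X[, 1], numeric(H), numeric(H))
  s2 <- step(X[, 2], s1$h, s1$c)
  run <- bionerel:::lstm_forward(X, p$sdpf.W, p$sdpf.U, p$sdpf.b)
  expect_equal(run$H[, 2], s2$h)
})

test_that("pair classification returns a proper distribution", {
  cands <- generate_candidates(sent, "ade")
  expect_length(cands, 1L)
  y <- classify_pair(model, states, sent, cands[[1]])
  expect_equal(sum(y), 1, tolerance = 1e-9)
  expect_named(y, model$vocab$rlabels)
  m0 <- model
  m0$params$W5[] <- 0
  m0$params$b5[] <- 0
  y0 <- classify_pair(m0, states, sent, cands[[1]])
  expect_equal(unname(y0), rep(0.5, 2))   # uniform over {ADE, NONE}
})

test_that("candidate generation enumerates type-compatible pairs", {
  # 1 drug + 2 diseases -> 2 candidates
  s <- annotated_sentence(
    tokens = data.frame(surface = c("d", "caused", "x", "and", "y"),
                        pos = c("NN", "VBD", "NN", "CC", "NN"),
                        stringsAsFactors = FALSE),
    heads = c(2L, 0L, 2L, 5L, 3L),
    deprels = c("nsubj", "root", "dobj", "cc", "conj"),
    entities = data.frame(start = c(1L, 3L, 5L), end = c(1L, 3L, 5L),
                          type = c("Drug", "Disease", "Disease"),
                          stringsAsFactors = FALSE),
    relations = data.frame(arg1 = 1L, arg2 = 2L, type = "ADE",
                           stringsAsFactors = FALSE))
  cands <- generate_candidates(s, "ade")
  expect_length(cands, 2L)
  expect_equal(vapply(cands, function(cc) cc$gold, ""), c("ADE", "NONE"))
  # 2 bacteria + 1 habitat + 1 geographical -> 4 candidates (brute force:
  # bacteria x locations)
  sb <- annotated_sentence(
    tokens = data.frame(surface = c("b1", "and", "b2", "live", "in", "gut",
                                    "in", "france"),
                        pos = c("NN", "CC", "NN", "VBP", "IN", "NN", "IN",
                                "NN"), stringsAsFactors = FALSE),
    heads = c(4L, 3L, 1L, 0L, 6L, 4L, 8L, 4L),
    deprels = c("nsubj", "cc", "conj", "root", "case", "nmod", "case",
                "nmod"),
    entities = data.frame(start = c(1L, 3L, 6L, 8L), end = c(1L, 3L, 6L, 8L),
                          type = c("Bacteria", "Bacteria", "Habitat",
                                   "Geographical"), stringsAsFactors = FALSE))
  cb <- generate_candidates(sb, "bb")
  n_brute <- sum(outer(sb$entities$type %in% "Bacteria",
                       sb$entities$type %in% c("Habitat", "Geographical"),
                       "&"))
  expect_length(cb, n_brute)
  expect_length(cb, 4L)
  # 0 or 1 entity -> no candidates
  s1 <- s; s1$entities <- s1$entities[1, ]; s1$relations <- empty_relations()
  expect_length(generate_candidates(s1, "ade"), 0L)
})

test_that("relation output depends on the shared encoder (stacking contract)", {
  cands <- generate_candidates(sent, "ade")
  y1 <- classify_pair(model, states, sent, cands[[1]])
  m2 <- model
  m2$params$lstmf.W <- m2$params$lstmf.W + 0.05
  st2 <- encode_sentence(m2, sent)
  y2 <- classify_pair(m2, st2, sent, cands[[1]])
  expect_false(isTRUE(all.equal(y1, y2)))
})
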