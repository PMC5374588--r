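#' Model and training configuration
#'
#' Collects every tunable quantity of the joint model. The defaults are
#' the published operating point: AdaGrad learning rate `alpha = 0.03`,
#' L2 regularization `lambda = 1e-8`, 200-dimensional (frozen) word
#' embeddings, 25-dimensional POS/dependency/label/character embeddings,
#' character window `C = 3` with 25 convolution kernels, and
#' 100-dimensional hidden states throughout. `mode` selects the joint
#' model (relation head stacked on the shared encoder) or the pipeline
#' ablation (relation head reads word embeddings; no parameter sharing).
#' `features` switches individual input sources off for ablation
#' experiments; a disabled feature contributes a zero block of unchanged
#' dimension.
#'
#' @param dim_word word-embedding dimension.
#' @param dim_feat dimension of POS, dependency-type and label embeddings.
#' @param dim_char character-embedding dimension.
#' @param dim_char_repr number of character-CNN kernels (= dimension of
#'   the pooled character representation).
#' @param char_window half-width `C` of the character window; each window
#'   concatenates `2C + 1` character embeddings.
#' @param dim_hidden hidden dimension of each direction of the shared
#'   sentence LSTM.
#' @param dim_ner_hidden hidden-layer dimension of the tagger head.
#' @param dim_sdp_hidden hidden dimension of each direction of the
#'   dependency-path LSTM.
#' @param dim_rel_hidden hidden-layer dimension of the relation head.
#' @param alpha AdaGrad learning rate.
#' @param lambda L2 regularization strength, applied as per-update weight
#'   decay.
#' @param epsilon AdaGrad stabilizer.
#' @param epochs number of training epochs.
#' @param seed integer seed controlling initialization and shuffling.
#' @param mode `"joint"` or `"pipeline"`.
#' @param teacher_forcing condition each training tagging step on the
#'   gold previous label (`TRUE`, default) or on the model's own
#'   prediction.
#' @param update `"sentence"` (one update for a sentence's tagging
#'   examples, then one for its relation examples) or `"example"`
#'   (an update and a fresh encoder pass per example).
#' @param features named logical list with elements `char`, `pos`,
#'   `label`, `dep`, `entity_repr`.
#' @param early_stop_f1 optional: stop training once entity and relation
#'   F1 on the monitoring set both reach this value.
#' @return a list of class `bionerel_config`.
#' @export
model_config <- function(dim_word = 200L, dim_feat = 25L, dim_char = 25L,
                         dim_char_repr = 25L, char_window = 3L,
                         dim_hidden = 100L, dim_ner_hidden = 100L,
                         dim_sdp_hidden = 100L, dim_rel_hidden = 100L,
                         alpha = 0.03, lambda = 1e-8, epsilon = 1e-8,
                         epochs = 30L, seed = 1L,
                         mode = c("joint", "pipeline"),
                         teacher_forcing = TRUE,
                         update = c("sentence", "example"),
                         features = list(char = TRUE, pos = TRUE,
                                         label = TRUE, dep = TRUE,
                                         entity_repr = TRUE),
                         early_stop_f1 = NULL) {
  mode <- match.arg(mode)
  update <- match.arg(update)
  stopifnot(alpha > 0, lambda >= 0, char_window >= 1L)
  defaults <- list(char = TRUE, pos = TRUE, label = TRUE, dep = TRUE,
                   entity_repr = TRUE)
  defaults[names(features)] <- features
  structure(list(dim_word = dim_word, dim_feat = dim_feat,
                 dim_char = dim_char, dim_char_repr = dim_char_repr,
                 char_window = char_window, dim_hidden = dim_hidden,
                 dim_ner_hidden = dim_ner_hidden,
                 dim_sdp_hidden = dim_sdp_hidden,
                 dim_rel_hidden = dim_rel_hidden,
                 alpha = alpha, lambda = lambda, epsilon = epsilon,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 mode = mode, teacher_forcing = teacher_forcing,
                 update = update, features = defaults,
                 early_stop_f1 = early_stop_f1),
            class = "bionerel_config")
}

# input dimension of the dependency-path LSTM: shared hidden states in
# joint mode, plain word embeddings in pipeline mode (plus the
# dependency-type embedding either way)
sdp_input_dim <- function(config) {
  base <- if (config$mode == "joint") 2L * config$dim_hidden else config$dim_word
  base + config$dim_feat
}
# dimension of one entity representation
entity_repr_dim <- function(config) {
  if (config$mode == "joint") 2L * config$dim_hidden else config$dim_word
}

#' Initialize a joint model
#'
#' Allocates every embedding table and weight matrix. Feature embeddings
#' are drawn uniformly from (-0.01, 0.01); weight matrices and LSTM
#' parameters use a fan-scaled uniform initialization; biases start at
#' zero. Word embeddings are initialized randomly or from a pre-trained
#' table ([read_word2vec()]) and are frozen: training never updates them.
#'
#' @param vocab a `bionerel_vocab`.
#' @param config a `bionerel_config`.
#' @param word_vectors optional numeric matrix of pre-trained word
#'   vectors with rownames; rows matching `vocab$word` are copied in.
#' @return an object of class `bionerel_model`.
#' @export
init_model <- function(vocab, config = model_config(), word_vectors = NULL) {
  nw <- length(vocab$word) + 1L       # + UNK
  nc <- length(vocab$char) + 2L       # + UNK + PAD
  np <- length(vocab$pos) + 1L
  nd <- length(vocab$dep) + 1L
  nl <- length(vocab$elabels)
  nr <- length(vocab$rlabels)
  win <- (2L * config$char_window + 1L) * config$dim_char
  enc_in <- config$dim_word + config$dim_feat + config$dim_char_repr
  ner_in <- 2L * config$dim_hidden + config$dim_feat
  rel_in <- 4L * config$dim_sdp_hidden + 2L * entity_repr_dim(config)

  params <- list(
    Eword = init_uniform(nw, config$dim_word),
    Echar = init_uniform(nc, config$dim_char),
    Epos = init_uniform(np, config$dim_feat),
    Edep = init_uniform(nd, config$dim_feat),
    Elabel = init_uniform(nl + 1L, config$dim_feat),   # + START row
    W1 = init_glorot(config$dim_char_repr, win),
    b1 = numeric(config$dim_char_repr),
    W2 = init_glorot(config$dim_ner_hidden, ner_in),
    b2 = numeric(config$dim_ner_hidden),
    W3 = init_glorot(nl, config$dim_ner_hidden),
    b3 = numeric(nl),
    W4 = init_glorot(config$dim_rel_hidden, rel_in),
    b4 = numeric(config$dim_rel_hidden),
    W5 = init_glorot(nr, config$dim_rel_hidden),
    b5 = numeric(nr)
  )
  lf <- lstm_params(enc_in, config$dim_hidden)
  lb <- lstm_params(enc_in, config$dim_hidden)
  sf <- lstm_params(sdp_input_dim(config), config$dim_sdp_hidden)
  sb <- lstm_params(sdp_input_dim(config), config$dim_sdp_hidden)
  params$lstmf.W <- lf$W; params$lstmf.U <- lf$U; params$lstmf.b <- lf$b
  params$lstmb.W <- lb$W; params$lstmb.U <- lb$U; params$lstmb.b <- lb$b
  params$sdpf.W <- sf$W; params$sdpf.U <- sf$U; params$sdpf.b <- sf$b
  params$sdpb.W <- sb$W; params$sdpb.U <- sb$U; params$sdpb.b <- sb$b

  if (!is.null(word_vectors)) {
    hit <- intersect(rownames(word_vectors), vocab$word)
    if (length(hit) > 0L) {
      stopifnot(ncol(word_vectors) == config$dim_word)
      params$Eword[match(hit, vocab$word), ] <- word_vectors[hit, ]
    }
  }
  structure(list(vocab = vocab, config = config, params = params,
                 adagrad = NULL, history = NULL),
            class = "bionerel_model")
}

#' @export
print.bionerel_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat("<bionerel_model> mode=", x$config$mode, ", task=", x$vocab$task,
      ", ", format(np, big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Read word vectors in word2vec text format
#'
#' First line: `<n> <dim>`; then one word and `dim` numbers per line.
#'
#' @param path file path.
#' @return numeric matrix with one row per word, words as rownames.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed word2vec header: ", lines[1])
  rows <- strsplit(trimws(lines[-1]), "[ \t]+")
  rows <- rows[vapply(rows, length, 0L) > 1L]
  words <- vapply(rows, `[[`, "", 1L)
  mat <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(hdr[2])))
  rownames(mat) <- words
  mat
}
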