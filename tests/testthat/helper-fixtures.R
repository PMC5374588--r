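# Shared fixtures and independent reference implementations (oracles).

# toy model dimensions: every unit test that trains or differentiates
# uses these to stay fast
toy_config <- function(seed = 11L, ...) {
  model_config(dim_word = 8L, dim_feat = 3L, dim_char = 3L,
               dim_char_repr = 4L, char_window = 2L, dim_hidden = 5L,
               dim_ner_hidden = 6L, dim_sdp_hidden = 4L,
               dim_rel_hidden = 5L, seed = seed, ...)
}

toy_model <- function(corpus, task = "ade", cfg = toy_config()) {
  vocab <- build_vocab(corpus, task)
  set.seed(cfg$seed)
  init_model(vocab, cfg)
}

# the hyphenated drug-induced-disease sentence with its projective parse
# (root = "induced"); drug [1,1], disease [4,5], one ADE relation
fig_sentence <- function() {
  annotated_sentence(
    tokens = data.frame(
      surface = c("gliclazide", "-", "induced", "acute", "hepatitis"),
      pos = c("NN", "HYPH", "VBN", "JJ", "NN"), stringsAsFactors = FALSE),
    heads = c(3L, 3L, 0L, 5L, 3L),
    deprels = c("nsubj", "punct", "root", "amod", "dobj"),
    entities = data.frame(start = c(1L, 4L), end = c(1L, 5L),
                          type = c("Drug", "Disease"),
                          stringsAsFactors = FALSE),
    relations = data.frame(arg1 = 1L, arg2 = 2L, type = "ADE",
                           stringsAsFactors = FALSE))
}

# minimal 3-token sentence (drug - trigger - disease) for gradient checks
tiny_sentence <- function() {
  annotated_sentence(
    tokens = data.frame(surface = c("drugx", "induced", "rash"),
                        pos = c("NN", "VBN", "NN"), stringsAsFactors = FALSE),
    heads = c(2L, 0L, 2L),
    deprels = c("nsubj", "root", "dobj"),
    entities = data.frame(start = c(1L, 3L), end = c(1L, 3L),
                          type = c("Drug", "Disease"),
                          stringsAsFactors = FALSE),
    relations = data.frame(arg1 = 1L, arg2 = 2L, type = "ADE",
                           stringsAsFactors = FALSE))
}

# random rooted tree as a head vector (0 = root), uniformly random
# attachment of each node to an earlier one under a random relabeling
random_tree <- function(n) {
  heads_ord <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 0L))
  perm <- sample.int(n)                 # position -> label
  heads <- integer(n)
  for (i in seq_len(n)) {
    h <- heads_ord[i]
    heads[perm[i]] <- if (h == 0L) 0L else perm[h]
  }
  heads
}

# oracle: LCA via ancestor-set intersection with explicit depths
oracle_lca <- function(heads, u, v) {
  anc <- function(x) {
    out <- x
    while (heads[x] != 0L) { x <- heads[x]; out <- c(out, x) }
    out
  }
  au <- anc(u); av <- anc(v)
  common <- intersect(au, av)
  depth <- vapply(common, function(x) length(anc(x)), 0L)
  common[which.max(depth)]
}

# oracle: breadth-first shortest path on the undirected tree
oracle_bfs_path <- function(heads, a, b) {
  n <- length(heads)
  adj <- vector("list", n)
  for (i in seq_len(n)) if (heads[i] != 0L) {
    adj[[i]] <- c(adj[[i]], heads[i])
    adj[[heads[i]]] <- c(adj[[heads[i]]], i)
  }
  prev <- rep(NA_integer_, n)
  seen <- logical(n); seen[a] <- TRUE
  queue <- a
  while (length(queue) > 0L) {
    x <- queue[1]; queue <- queue[-1]
    if (x == b) break
    for (y in adj[[x]]) if (!seen[y]) {
      seen[y] <- TRUE; prev[y] <- x; queue <- c(queue, y)
    }
  }
  path <- b
  while (path[1] != a) path <- c(prev[path[1]], path)
  path
}

# independent reference implementation of the BILOU repair rule, written
# as a direct state machine over (tag, type) pairs
reference_decode <- function(labels) {
  mentions <- list()
  open <- NULL   # c(start, type)
  emit <- function(s, e, ty) mentions[[length(mentions) + 1L]] <<- list(s, e, ty)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    tag <- if (lab == "O") "O" else substring(lab, 1, 1)
    ty <- if (lab == "O") NA_character_ else substring(lab, 3)
    compatible <- !is.null(open) && identical(open[[2]], ty)
    if (tag == "I" && compatible) next
    if (tag == "L" && compatible) {
      emit(as.integer(open[[1]]), i, ty); open <- NULL; next
    }
    if (!is.null(open)) { emit(as.integer(open[[1]]), i - 1L, open[[2]]); open <- NULL }
    if (tag == "U") emit(i, i, ty)
    else if (tag %in% c("B", "I")) open <- list(i, ty)
    else if (tag == "L") emit(i, i, ty)
  }
  if (!is.null(open)) emit(as.integer(open[[1]]), length(labels), open[[2]])
  if (length(mentions) == 0L) return(empty_entities())
  data.frame(start = vapply(mentions, function(m) m[[1]], 0L),
             end = vapply(mentions, function(m) m[[2]], 0L),
             type = vapply(mentions, function(m) m[[3]], ""),
             stringsAsFactors = FALSE)
}

# oracle: maximum one-to-one exact matching by exhaustive assignment
oracle_match <- function(gold, pred) {
  gk <- paste(gold$start, gold$end, gold$type)
  pk <- paste(pred$start, pred$end, pred$type)
  rec <- function(pi, used) {
    if (pi > length(pk)) return(0L)
    best <- rec(pi + 1L, used)                 # leave this prediction unmatched
    for (g in seq_along(gk)) {
      if (!used[g] && pk[pi] == gk[g]) {
        used2 <- used; used2[g] <- TRUE
        best <- max(best, 1L + rec(pi + 1L, used2))
      }
    }
    best
  }
  tp <- rec(1L, rep(FALSE, length(gk)))
  c(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

# sorted canonical form of an entity frame, for set comparisons
canon_entities <- function(e) {
  e <- e[order(e$start, e$end, e$type), , drop = FALSE]
  rownames(e) <- NULL
  e
}
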