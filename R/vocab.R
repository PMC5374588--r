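#' Build vocabularies from a training corpus
#'
#' Collects the normalized word forms, characters, POS tags, dependency
#' types and entity types observed in `sentences`, and derives the BILOU
#' entity-label set and the relation-label set. Every lookup table gets
#' an UNK entry for unseen items; the character table additionally gets a
#' learned padding symbol used by the character CNN windows.
#'
#' @param sentences list of `annotated_sentence`.
#' @param task `"ade"` (Drug--Disease pairs, relation type `ADE`) or
#'   `"bb"` (Bacteria--Habitat/Geographical pairs, relation type
#'   `Lives_In`).
#' @return an object of class `bionerel_vocab`.
#' @export
build_vocab <- function(sentences, task = c("ade", "bb")) {
  task <- match.arg(task)
  norms <- unique(unlist(lapply(sentences, function(s) s$tokens$norm)))
  chars <- unique(unlist(strsplit(norms, "", fixed = TRUE)))
  pos <- unique(unlist(lapply(sentences, function(s) s$tokens$pos)))
  deps <- unique(unlist(lapply(sentences, function(s) s$deprels)))
  etypes <- if (task == "ade") c("Drug", "Disease")
            else c("Bacteria", "Habitat", "Geographical")
  seen <- unique(unlist(lapply(sentences, function(s) s$entities$type)))
  extra <- setdiff(seen, etypes)
  if (length(extra) > 0L)
    stop("entity types not in the ", task, " schema: ",
         paste(extra, collapse = ", "))
  structure(list(
    task = task,
    word = sort(norms), char = sort(chars), pos = sort(pos),
    dep = sort(deps), etypes = etypes,
    elabels = bilou_labels(etypes),
    rlabels = c(if (task == "ade") "ADE" else "Lives_In", "NONE")
  ), class = "bionerel_vocab")
}

#' @export
print.bionerel_vocab <- function(x, ...) {
  cat("<bionerel_vocab> task=", x$task, ": ", length(x$word), " words, ",
      length(x$char), " chars, ", length(x$pos), " POS, ", length(x$dep),
      " dep types, ", length(x$elabels), " entity labels, ",
      length(x$rlabels), " relation labels\n", sep = "")
  invisible(x)
}

# index lookups; unseen items map to the UNK row (length + 1)
word_ids <- function(vocab, norm) {
  i <- match(norm, vocab$word)
  i[is.na(i)] <- length(vocab$word) + 1L
  i
}
pos_ids <- function(vocab, pos) {
  i <- match(pos, vocab$pos)
  i[is.na(i)] <- length(vocab$pos) + 1L
  i
}
dep_ids <- function(vocab, dep) {
  i <- match(dep, vocab$dep)
  i[is.na(i)] <- length(vocab$dep) + 1L
  i
}
char_ids <- function(vocab, norm) {
  cs <- strsplit(norm, "", fixed = TRUE)[[1]]
  i <- match(cs, vocab$char)
  i[is.na(i)] <- length(vocab$char) + 1L
  i
}
# padding row of the character table (after all chars + UNK)
char_pad_id <- function(vocab) length(vocab$char) + 2L

elabel_id <- function(vocab, label) {
  i <- match(label, vocab$elabels)
  if (anyNA(i)) stop("unknown entity label: ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}
# row of the label table holding the START symbol (position before token 1)
start_label_id <- function(vocab) length(vocab$elabels) + 1L

rlabel_id <- function(vocab, label) {
  i <- match(label, vocab$rlabels)
  if (anyNA(i)) stop("unknown relation label: ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}
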