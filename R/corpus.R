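#' Construct an annotated sentence
#'
#' The unit of processing: tokens with POS tags, a projective dependency
#' tree, gold entity mentions and gold binary relations. All token
#' indices are 1-based inclusive; heads follow the CoNLL convention
#' (0 = root).
#'
#' @param tokens data.frame with columns `surface`, `norm`, `pos` (`norm`
#'   is filled from `surface` when missing).
#' @param heads integer vector of governor indices, 0 for the root.
#' @param deprels character vector of dependency types, one per token.
#' @param entities data.frame with columns `start`, `end`, `type`
#'   (possibly 0 rows).
#' @param relations data.frame with columns `arg1`, `arg2` (row indices
#'   into `entities`) and `type` (possibly 0 rows).
#' @param validate check all structural invariants (single root, acyclic
#'   tree, non-nested entities)?
#' @return an object of class `annotated_sentence`.
#' @export
annotated_sentence <- function(tokens, heads, deprels,
                               entities = empty_entities(),
                               relations = empty_relations(),
                               validate = TRUE) {
  if (is.null(tokens$norm)) tokens$norm <- normalize_token(tokens$surface)
  sent <- structure(
    list(tokens = tokens, heads = as.integer(heads),
         deprels = as.character(deprels),
         entities = entities, relations = relations),
    class = "annotated_sentence")
  if (validate) validate_sentence(sent)
  sent
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence> ", paste(x$tokens$surface, collapse = " "), "\n",
      sep = "")
  cat("  ", nrow(x$entities), " entities, ", nrow(x$relations),
      " relations\n", sep = "")
  invisible(x)
}

#' @rdname annotated_sentence
#' @export
empty_entities <- function() {
  data.frame(start = integer(0), end = integer(0), type = character(0),
             stringsAsFactors = FALSE)
}

#' @rdname annotated_sentence
#' @export
empty_relations <- function() {
  data.frame(arg1 = integer(0), arg2 = integer(0), type = character(0),
             stringsAsFactors = FALSE)
}

validate_sentence <- function(sent) {
  n <- nrow(sent$tokens)
  if (n == 0L) stop("sentence has no tokens")
  if (length(sent$heads) != n || length(sent$deprels) != n)
    stop("parse length does not match token count")
  validate_tree(sent$heads)
  ent <- sent$entities
  if (nrow(ent) > 0L) {
    stopifnot(all(ent$start >= 1L), all(ent$end <= n),
              all(ent$start <= ent$end))
    if (anyDuplicated(ent[, c("start", "end")]))
      stop("two entities share an identical span")
    if (nrow(ent) > 1L) {
      for (i in seq_len(nrow(ent) - 1L)) for (j in (i + 1L):nrow(ent)) {
        nested <- (ent$start[i] <= ent$start[j] && ent$end[j] <= ent$end[i]) ||
                  (ent$start[j] <= ent$start[i] && ent$end[i] <= ent$end[j])
        if (nested) stop("nested entities are not allowed")
      }
    }
  }
  rel <- sent$relations
  if (nrow(rel) > 0L) {
    stopifnot(all(rel$arg1 >= 1L), all(rel$arg1 <= nrow(ent)),
              all(rel$arg2 >= 1L), all(rel$arg2 <= nrow(ent)),
              all(rel$arg1 != rel$arg2))
  }
  invisible(sent)
}

#' Remove nested and overlapping entity mentions
#'
#' When one mention's span contains or overlaps another's, the longer
#' mention is kept and the shorter dropped (ties: the earlier-listed one
#' survives). Returns the surviving rows plus an attribute
#' `n_dropped`.
#'
#' @param entities entity data.frame (`start`, `end`, `type`).
#' @return filtered data.frame with attribute `n_dropped`.
#' @export
filter_nested_entities <- function(entities) {
  n <- nrow(entities)
  if (n <= 1L) {
    attr(entities, "n_dropped") <- 0L
    return(entities)
  }
  len <- entities$end - entities$start + 1L
  keep_order <- order(-len, seq_len(n))  # longest first, stable
  keep <- logical(n)
  for (i in keep_order) {
    clash <- FALSE
    for (j in which(keep)) {
      if (entities$start[i] <= entities$end[j] &&
          entities$start[j] <= entities$end[i]) { clash <- TRUE; break }
    }
    if (!clash) keep[i] <- TRUE
  }
  out <- entities[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n - nrow(out)
  out
}

#' Read CoNLL-style dependency parses
#'
#' One block of rows per sentence, blank-line separated. Each row has at
#' least five whitespace-separated fields: index, token, POS tag, head
#' (1-based, 0 = root) and dependency type.
#'
#' @param text the sidecar file contents as a single string, or a
#'   character vector of lines.
#' @return a list of data.frames with columns `token`, `pos`, `head`,
#'   `deprel`.
#' @export
read_conll <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  blocks <- list(); cur <- character(0)
  for (ln in c(lines, "")) {
    if (grepl("^[[:space:]]*$", ln)) {
      if (length(cur) > 0L) { blocks[[length(blocks) + 1L]] <- cur; cur <- character(0) }
    } else cur <- c(cur, ln)
  }
  lapply(blocks, function(b) {
    fields <- strsplit(trimws(b), "[\t ]+")
    bad <- which(vapply(fields, length, 0L) < 5L)
    if (length(bad) > 0L)
      stop("malformed CoNLL row (fewer than 5 fields): ", b[bad[1]])
    data.frame(token = vapply(fields, `[[`, "", 2L),
               pos = vapply(fields, `[[`, "", 3L),
               head = as.integer(vapply(fields, `[[`, "", 4L)),
               deprel = vapply(fields, `[[`, "", 5L),
               stringsAsFactors = FALSE)
  })
}

#' Write CoNLL-style dependency parses
#'
#' @param sentences list of `annotated_sentence`.
#' @return a single string (blank-line separated blocks).
#' @export
write_conll <- function(sentences) {
  blocks <- vapply(sentences, function(s) {
    paste(sprintf("%d\t%s\t%s\t%d\t%s", seq_len(nrow(s$tokens)),
                  s$tokens$surface, s$tokens$pos, s$heads, s$deprels),
          collapse = "\n")
  }, "")
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

# Align a 0-based half-open character span onto token indices of one
# sentence.  Returns c(start, end) in 1-based token indices, or NULL when
# the span does not coincide with token boundaries.
align_span <- function(tok, char_start0, char_end0) {
  s <- which(tok$start == char_start0 + 1L)
  e <- which(tok$end == char_end0)
  if (length(s) != 1L || length(e) != 1L || s > e) return(NULL)
  c(s, e)
}

zero_drop_counts <- function() {
  c(unaligned = 0L, discontinuous = 0L, nested = 0L,
    cross_sentence_relation = 0L, dangling_relation = 0L)
}

#' Read a BioNLP-ST standoff document
#'
#' Parses the document text, its `.a1` entity lines
#' (`Tid<TAB>Type start end<TAB>text`, 0-based half-open character
#' offsets) and `.a2` relation lines (`Rid<TAB>Type Arg1:Tid Arg2:Tid`),
#' splits the text into sentences, tokenizes them, attaches the supplied
#' dependency parses and projects the character-offset annotations onto
#' token spans. Discontinuous entities (offset fields containing `;`),
#' entities that do not align with token boundaries, and nested entities
#' are dropped; relations whose arguments fall in different sentences or
#' refer to dropped entities are dropped. All drops are counted in the
#' `drop_counts` attribute of the result.
#'
#' @param txt_text document text.
#' @param a1_text contents of the `.a1` file ("" for none).
#' @param a2_text contents of the `.a2` file ("" for none).
#' @param parses CoNLL sidecar: a string or list from [read_conll()],
#'   one block per sentence in document order.
#' @return list of `annotated_sentence` with attribute `drop_counts`.
#' @export
read_standoff <- function(txt_text, a1_text = "", a2_text = "", parses) {
  if (is.character(parses)) parses <- read_conll(parses)
  sents <- split_sentences(txt_text)
  if (nrow(sents) != length(parses))
    stop("parses cover ", length(parses), " sentences but text splits into ",
         nrow(sents))
  drops <- zero_drop_counts()

  # tokenize each sentence; offsets made document-absolute
  toks <- vector("list", nrow(sents))
  for (i in seq_len(nrow(sents))) {
    tk <- tokenize(substring(txt_text, sents$start[i], sents$end[i]))
    tk$start <- tk$start + sents$start[i] - 1L
    tk$end <- tk$end + sents$start[i] - 1L
    if (nrow(tk) != nrow(parses[[i]]))
      stop("sentence ", i, ": parse has ", nrow(parses[[i]]),
           " rows but tokenizer produced ", nrow(tk), " tokens")
    toks[[i]] <- tk
  }

  # entities (.a1 T-lines)
  tmap <- list()   # Tid -> list(sent, start, end, type)
  if (nzchar(a1_text)) {
    for (ln in strsplit(a1_text, "\n", fixed = TRUE)[[1]]) {
      if (!nzchar(trimws(ln))) next
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L || !grepl("^T", parts[1]))
        stop("malformed .a1 line: ", ln)
      ann <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      if (grepl(";", parts[2], fixed = TRUE)) {
        drops["discontinuous"] <- drops["discontinuous"] + 1L
        next
      }
      if (length(ann) != 3L) stop("malformed .a1 annotation field: ", ln)
      cs <- as.integer(ann[2]); ce <- as.integer(ann[3])
      if (is.na(cs) || is.na(ce) || cs < 0L || ce > nchar(txt_text) || cs >= ce)
        stop("character offset outside text in .a1 line: ", ln)
      si <- which(sents$start <= cs + 1L & ce <= sents$end)
      sp <- if (length(si) == 1L)
        align_span(toks[[si]], cs, ce) else NULL
      if (is.null(sp)) {
        drops["unaligned"] <- drops["unaligned"] + 1L
        next
      }
      tmap[[parts[1]]] <- list(sent = si, start = sp[1], end = sp[2],
                               type = ann[1])
    }
  }

  # nested filtering per sentence, then rebuild surviving Tid map
  ents <- lapply(seq_len(nrow(sents)), function(i) empty_entities())
  tids <- lapply(seq_len(nrow(sents)), function(i) character(0))
  for (id in names(tmap)) {
    e <- tmap[[id]]
    ents[[e$sent]] <- rbind(ents[[e$sent]],
                            data.frame(start = e$start, end = e$end,
                                       type = e$type, stringsAsFactors = FALSE))
    tids[[e$sent]] <- c(tids[[e$sent]], id)
  }
  ent_index <- list()  # Tid -> c(sent, row)
  for (i in seq_along(ents)) {
    if (nrow(ents[[i]]) == 0L) next
    filt <- filter_nested_entities(ents[[i]])
    drops["nested"] <- drops["nested"] + attr(filt, "n_dropped")
    kept <- match(paste(filt$start, filt$end),
                  paste(ents[[i]]$start, ents[[i]]$end))
    attr(filt, "n_dropped") <- NULL
    tids[[i]] <- tids[[i]][kept]
    ents[[i]] <- filt
    for (r in seq_along(tids[[i]])) ent_index[[tids[[i]][r]]] <- c(i, r)
  }

  # relations (.a2 R-lines)
  rels <- lapply(seq_len(nrow(sents)), function(i) empty_relations())
  if (nzchar(a2_text)) {
    for (ln in strsplit(a2_text, "\n", fixed = TRUE)[[1]]) {
      if (!nzchar(trimws(ln))) next
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L || !grepl("^R", parts[1]))
        stop("malformed .a2 line: ", ln)
      ann <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      if (length(ann) != 3L || !grepl("^Arg1:", ann[2]) || !grepl("^Arg2:", ann[3]))
        stop("malformed .a2 relation field: ", ln)
      t1 <- sub("^Arg1:", "", ann[2]); t2 <- sub("^Arg2:", "", ann[3])
      a <- ent_index[[t1]]; b <- ent_index[[t2]]
      if (is.null(a) || is.null(b)) {
        drops["dangling_relation"] <- drops["dangling_relation"] + 1L
        next
      }
      if (a[1] != b[1]) {
        drops["cross_sentence_relation"] <- drops["cross_sentence_relation"] + 1L
        next
      }
      rels[[a[1]]] <- rbind(rels[[a[1]]],
                            data.frame(arg1 = a[2], arg2 = b[2], type = ann[1],
                                       stringsAsFactors = FALSE))
    }
  }

  out <- vector("list", nrow(sents))
  for (i in seq_len(nrow(sents))) {
    tk <- toks[[i]]
    parse <- parses[[i]]
    out[[i]] <- annotated_sentence(
      tokens = data.frame(surface = tk$surface,
                          norm = normalize_token(tk$surface),
                          pos = parse$pos, stringsAsFactors = FALSE),
      heads = parse$head, deprels = parse$deprel,
      entities = ents[[i]], relations = rels[[i]])
  }
  attr(out, "drop_counts") <- drops
  out
}

#' Read a sentence-record (ADE-style) corpus
#'
#' One record per line with three `|`-separated fields:
#' `sentence text|entity list|relation list`. Entities are
#' `;`-separated `Type,start,end` triples with 0-based half-open
#' character offsets into the sentence; relations are `;`-separated
#' `i,j,Type` triples whose `i`/`j` are 1-based indices into the entity
#' list of the record. Alignment, nested-entity filtering and drop
#' counting behave exactly as in [read_standoff()]; a relation whose
#' argument is removed by the nested filter is dropped and counted
#' (this is how overlapping gold annotations such as a drug inside its
#' own intoxication mention are removed).
#'
#' @param record_lines character vector of record lines.
#' @param parses CoNLL sidecar, one block per record.
#' @return list of `annotated_sentence` with attribute `drop_counts`.
#' @export
read_ade <- function(record_lines, parses = list()) {
  record_lines <- record_lines[nzchar(trimws(record_lines))]
  if (is.character(parses)) parses <- read_conll(parses)
  if (length(record_lines) == 0L) {
    out <- list()
    attr(out, "drop_counts") <- zero_drop_counts()
    return(out)
  }
  if (length(parses) != length(record_lines))
    stop("parses cover ", length(parses), " sentences but there are ",
         length(record_lines), " records")
  drops <- zero_drop_counts()
  out <- vector("list", length(record_lines))
  for (i in seq_along(record_lines)) {
    parts <- strsplit(record_lines[i], "|", fixed = TRUE)[[1]]
    if (length(parts) < 1L) stop("malformed record on line ", i)
    text <- parts[1]
    tk <- tokenize(text)
    parse <- parses[[i]]
    if (nrow(tk) != nrow(parse))
      stop("record ", i, ": parse has ", nrow(parse),
           " rows but tokenizer produced ", nrow(tk), " tokens")
    ent <- empty_entities()
    kept_of <- integer(0)   # original entity index per kept row
    if (length(parts) >= 2L && nzchar(parts[2])) {
      specs <- strsplit(parts[2], ";", fixed = TRUE)[[1]]
      for (k in seq_along(specs)) {
        f <- strsplit(specs[k], ",", fixed = TRUE)[[1]]
        if (length(f) != 3L) stop("malformed entity field on line ", i, ": ",
                                  specs[k])
        cs <- as.integer(f[2]); ce <- as.integer(f[3])
        if (is.na(cs) || is.na(ce) || cs < 0L || ce > nchar(text) || cs >= ce)
          stop("entity offsets outside sentence on line ", i)
        if (substring(text, cs + 1L, ce) == "") stop("empty entity span")
        sp <- align_span(tk, cs, ce)
        if (is.null(sp)) {
          drops["unaligned"] <- drops["unaligned"] + 1L
          next
        }
        ent <- rbind(ent, data.frame(start = sp[1], end = sp[2], type = f[1],
                                     stringsAsFactors = FALSE))
        kept_of <- c(kept_of, k)
      }
    }
    filt <- filter_nested_entities(ent)
    drops["nested"] <- drops["nested"] + attr(filt, "n_dropped")
    kept_rows <- match(paste(filt$start, filt$end), paste(ent$start, ent$end))
    attr(filt, "n_dropped") <- NULL
    orig2new <- rep(NA_integer_, max(c(kept_of, 0L)))
    orig2new[kept_of[kept_rows]] <- seq_len(nrow(filt))
    rel <- empty_relations()
    if (length(parts) >= 3L && nzchar(parts[3])) {
      specs <- strsplit(parts[3], ";", fixed = TRUE)[[1]]
      for (sp in specs) {
        f <- strsplit(sp, ",", fixed = TRUE)[[1]]
        if (length(f) != 3L) stop("malformed relation field on line ", i, ": ", sp)
        a <- as.integer(f[1]); b <- as.integer(f[2])
        na <- if (a >= 1L && a <= length(orig2new)) orig2new[a] else NA_integer_
        nb <- if (b >= 1L && b <= length(orig2new)) orig2new[b] else NA_integer_
        if (is.na(na) || is.na(nb)) {
          drops["dangling_relation"] <- drops["dangling_relation"] + 1L
          next
        }
        rel <- rbind(rel, data.frame(arg1 = na, arg2 = nb, type = f[3],
                                     stringsAsFactors = FALSE))
      }
    }
    out[[i]] <- annotated_sentence(
      tokens = data.frame(surface = tk$surface,
                          norm = normalize_token(tk$surface),
                          pos = parse$pos, stringsAsFactors = FALSE),
      heads = parse$head, deprels = parse$deprel,
      entities = filt, relations = rel)
  }
  attr(out, "drop_counts") <- drops
  out
}

#' Write a corpus in the standoff, record and CoNLL dialects
#'
#' Emits `doc.txt`, `doc.a1`, `doc.a2` (the whole corpus as one document,
#' one sentence per line), `records.ade` in the sentence-record dialect,
#' and `parses.conll`. The written files round-trip through
#' [read_standoff()] and [read_ade()].
#'
#' @param sentences list of `annotated_sentence`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named character vector of file paths.
#' @export
write_corpus <- function(sentences, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sep_join <- function(tok) paste(tok, collapse = " ")
  texts <- vapply(sentences, function(s) sep_join(s$tokens$surface), "")
  doc <- paste(texts, collapse = "\n")

  a1 <- character(0); a2 <- character(0); tid <- 0L; rid <- 0L
  offset <- 0L
  ade <- character(0)
  for (s in sentences) {
    tok <- s$tokens$surface
    starts <- offset + c(0L, cumsum(nchar(tok) + 1L))[seq_along(tok)]
    ends <- starts + nchar(tok)          # 0-based half-open
    ent_tids <- integer(nrow(s$entities))
    efield <- character(0)
    for (r in seq_len(nrow(s$entities))) {
      cs <- starts[s$entities$start[r]]; ce <- ends[s$entities$end[r]]
      tid <- tid + 1L
      ent_tids[r] <- tid
      a1 <- c(a1, sprintf("T%d\t%s %d %d\t%s", tid, s$entities$type[r], cs, ce,
                          substring(doc, cs + 1L, ce)))
      efield <- c(efield, sprintf("%s,%d,%d", s$entities$type[r],
                                  cs - offset, ce - offset))
    }
    rfield <- character(0)
    for (r in seq_len(nrow(s$relations))) {
      rid <- rid + 1L
      a2 <- c(a2, sprintf("R%d\t%s Arg1:T%d Arg2:T%d", rid, s$relations$type[r],
                          ent_tids[s$relations$arg1[r]],
                          ent_tids[s$relations$arg2[r]]))
      rfield <- c(rfield, sprintf("%d,%d,%s", s$relations$arg1[r],
                                  s$relations$arg2[r], s$relations$type[r]))
    }
    ade <- c(ade, paste(sep_join(tok), paste(efield, collapse = ";"),
                        paste(rfield, collapse = ";"), sep = "|"))
    offset <- offset + nchar(sep_join(tok)) + 1L
  }
  paths <- c(txt = file.path(dir, "doc.txt"), a1 = file.path(dir, "doc.a1"),
             a2 = file.path(dir, "doc.a2"), ade = file.path(dir, "records.ade"),
             conll = file.path(dir, "parses.conll"))
  writeLines(doc, paths["txt"])
  writeLines(a1, paths["a1"])
  writeLines(a2, paths["a2"])
  writeLines(ade, paths["ade"])
  cat(write_conll(sentences), file = paths["conll"])
  invisible(paths)
}
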