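#' Encode entity mentions as a BILOU label sequence
#'
#' Single-token mentions become `U-<type>`; multi-token mentions become
#' `B-<type>`, `I-<type>`... `L-<type>`; all remaining tokens are `O`.
#'
#' @param n_tokens number of tokens in the sentence.
#' @param entities data.frame with columns `start`, `end` (1-based
#'   inclusive token indices) and `type`; mentions must be contiguous and
#'   non-overlapping.
#' @return character vector of length `n_tokens`.
#' @export
encode_bilou <- function(n_tokens, entities) {
  labels <- rep("O", n_tokens)
  if (is.null(entities) || nrow(entities) == 0L) return(labels)
  stopifnot(all(entities$start >= 1L), all(entities$end <= n_tokens),
            all(entities$start <= entities$end))
  covered <- logical(n_tokens)
  for (i in seq_len(nrow(entities))) {
    s <- entities$start[i]; e <- entities$end[i]; ty <- entities$type[i]
    if (any(covered[s:e])) stop("overlapping entities cannot be BILOU-encoded")
    covered[s:e] <- TRUE
    if (s == e) {
      labels[s] <- paste0("U-", ty)
    } else {
      labels[s] <- paste0("B-", ty)
      labels[e] <- paste0("L-", ty)
      if (e - s > 1L) labels[(s + 1L):(e - 1L)] <- paste0("I-", ty)
    }
  }
  labels
}

#' Decode a BILOU label sequence into entity mentions
#'
#' Inverse of [encode_bilou()] on valid sequences. Invalid sequences are
#' repaired deterministically by a left-to-right scan:
#' * `B-t` while a run is open closes the open run at the previous token,
#'   then opens a new run;
#' * `I-t` or `L-t` without a compatible open run (no run, or a run of a
#'   different type) starts a new run at that token;
#' * `O`, `U-t`, or a label of a different type closes any open run at
#'   the previous token;
#' * a run still open at the end of the sentence is closed at the last
#'   token.
#'
#' @param labels character vector of BILOU labels.
#' @return data.frame with columns `start`, `end`, `type`; mentions are
#'   non-overlapping and ordered by `start`.
#' @export
decode_bilou <- function(labels) {
  n <- length(labels)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  open_start <- NA_integer_; open_type <- NA_character_
  close_open <- function(at) {
    starts <<- c(starts, open_start); ends <<- c(ends, at)
    types <<- c(types, open_type)
    open_start <<- NA_integer_; open_type <<- NA_character_
  }
  for (i in seq_len(n)) {
    lab <- labels[i]
    if (lab == "O") {
      if (!is.na(open_start)) close_open(i - 1L)
      next
    }
    tag <- substring(lab, 1L, 1L)
    ty <- substring(lab, 3L)
    if (tag == "U") {
      if (!is.na(open_start)) close_open(i - 1L)
      starts <- c(starts, i); ends <- c(ends, i); types <- c(types, ty)
    } else if (tag == "B") {
      if (!is.na(open_start)) close_open(i - 1L)
      open_start <- i; open_type <- ty
    } else if (tag == "I") {
      if (is.na(open_start) || open_type != ty) {
        if (!is.na(open_start)) close_open(i - 1L)
        open_start <- i; open_type <- ty  # repair: I without B opens a run
      }
    } else if (tag == "L") {
      if (!is.na(open_start) && open_type == ty) {
        close_open(i)
      } else {
        if (!is.na(open_start)) close_open(i - 1L)
        # repair: L without B is a single-token mention
        starts <- c(starts, i); ends <- c(ends, i); types <- c(types, ty)
      }
    } else {
      stop("not a BILOU label: ", lab)
    }
  }
  if (!is.na(open_start)) close_open(n)
  data.frame(start = starts, end = ends, type = types,
             stringsAsFactors = FALSE)
}

#' Enumerate the BILOU label set for a set of entity types
#'
#' @param types character vector of entity types.
#' @return character vector: `B-/I-/L-/U-` labels per type, then `"O"`.
#' @export
bilou_labels <- function(types) {
  c(as.vector(vapply(types, function(ty) paste0(c("B-", "I-", "L-", "U-"), ty),
                     character(4))), "O")
}
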