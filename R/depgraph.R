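#' Validate a dependency tree
#'
#' Checks the single-root, acyclic, everyone-reaches-root invariants of a
#' projective (basic) dependency parse stored as a head vector
#' (0 = root).
#'
#' @param heads integer vector of governor indices.
#' @return invisibly, `heads`.
#' @export
validate_tree <- function(heads) {
  n <- length(heads)
  if (n == 0L) stop("empty tree")
  if (any(is.na(heads)) || any(heads < 0L) || any(heads > n))
    stop("head index out of range")
  if (sum(heads == 0L) != 1L)
    stop("dependency graph must have exactly one root")
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (heads[j] != 0L) {
      if (seen[j]) stop("cycle in dependency graph at token ", i)
      seen[j] <- TRUE
      j <- heads[j]
    }
  }
  invisible(heads)
}

# path of token indices from u up to (and including) the root
ancestor_path <- function(heads, u) {
  path <- u
  while (heads[u] != 0L) {
    u <- heads[u]
    path <- c(path, u)
  }
  path
}

#' Lowest common ancestor in a dependency tree
#'
#' The deepest node that is an ancestor-or-self of both `u` and `v`.
#'
#' @param heads head vector (0 = root), assumed valid.
#' @param u,v 1-based token indices.
#' @return the token index of the LCA.
#' @export
tree_lca <- function(heads, u, v) {
  n <- length(heads)
  stopifnot(u >= 1L, u <= n, v >= 1L, v <= n)
  validate_tree(heads)
  pu <- ancestor_path(heads, u)
  pv <- ancestor_path(heads, v)
  common <- pv[pv %in% pu]
  if (length(common) == 0L) stop("no common ancestor; not a tree")
  common[1]   # first hit while climbing from v = deepest common
}

#' Shortest dependency path between two tokens
#'
#' The unique tree path between `a` and `b`, represented as the two
#' bottom-up climbs that meet at the lowest common ancestor. When the LCA
#' coincides with one of the endpoints that side's climb has length 1.
#'
#' @param heads head vector (0 = root), assumed valid.
#' @param a,b distinct 1-based token indices (typically entity anchors).
#' @return list with `up_a` (indices a..lca), `up_b` (indices b..lca) and
#'   `lca`; `length(up_a) + length(up_b) - 1` equals the number of nodes
#'   on the path.
#' @export
shortest_dep_path <- function(heads, a, b) {
  if (a == b) stop("shortest dependency path requires two distinct tokens")
  lca <- tree_lca(heads, a, b)
  climb <- function(x) {
    path <- x
    while (x != lca) {
      x <- heads[x]
      path <- c(path, x)
    }
    path
  }
  list(up_a = climb(a), up_b = climb(b), lca = lca)
}

#' Anchor token of an entity mention
#'
#' The mention's last token, used as the endpoint when building the
#' shortest dependency path between two entities. When tokenization
#' leaves a punctuation artifact as the final token it is still taken
#' literally.
#'
#' @param entity one-row entity data.frame (or list) with `start`, `end`.
#' @return the 1-based index of the last token.
#' @export
entity_anchor <- function(entity) {
  stopifnot(entity$start >= 1L, entity$start <= entity$end)
  as.integer(entity$end)
}
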