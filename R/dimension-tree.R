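#' Canonical balanced dimension tree
#'
#' Builds a binary dimension tree over the modes `1:d`. Starting from the root
#' (labelled with all modes, taken in `leaf_order`), every node splits its
#' `m` modes into the first `ceiling(m/2)` and the remaining `floor(m/2)`
#' modes, until each leaf holds a single mode. With the identity leaf order
#' this is the canonical balanced tree; any other permutation rearranges
#' which automata end up close to each other in the tree, which controls the
#' achievable hierarchical ranks.
#'
#' Nodes are stored root-first so that every parent precedes its children,
#' which is the traversal order the tensor arithmetic relies on.
#'
#' @param d number of modes (automata), `d >= 1`.
#' @param leaf_order permutation of `1:d` assigning automata to leaf
#'   positions (left to right). Defaults to the identity.
#' @return an object of class `dimension_tree` with fields `d`, `nnodes`,
#'   `left`, `right`, `parent` (integer vectors, `0L` meaning "none"),
#'   `modes` (list of integer mode sets per node), `leaf_mode` (mode carried
#'   by each leaf, `0L` for inner nodes), `leaf_node` (node index of the leaf
#'   holding each mode) and `leaf_order`.
#' @examples
#' tr <- balanced_tree(8)
#' tr$modes[[2]]  # left child of the root: modes 1:4
#' @export
balanced_tree <- function(d, leaf_order = seq_len(d)) {
  d <- as.integer(d)
  if (length(d) != 1L || is.na(d) || d < 1L)
    stop("'d' must be a single integer >= 1")
  leaf_order <- as.integer(leaf_order)
  if (length(leaf_order) != d || anyNA(leaf_order) ||
      !setequal(leaf_order, seq_len(d)))
    stop("'leaf_order' must be a permutation of 1:", d)

  nnodes <- 2L * d - 1L
  left <- right <- parent <- integer(nnodes)
  leaf_mode <- integer(nnodes)
  modes <- vector("list", nnodes)

  modes[[1L]] <- leaf_order
  next_free <- 2L
  # queue-based expansion keeps parent indices below child indices
  stack <- 1L
  while (length(stack)) {
    t <- stack[1L]; stack <- stack[-1L]
    lab <- modes[[t]]
    m <- length(lab)
    if (m == 1L) {
      leaf_mode[t] <- lab
      next
    }
    k <- ceiling(m / 2)
    l <- next_free; r <- next_free + 1L; next_free <- next_free + 2L
    left[t] <- l; right[t] <- r
    parent[l] <- t; parent[r] <- t
    modes[[l]] <- lab[seq_len(k)]
    modes[[r]] <- lab[(k + 1L):m]
    stack <- c(stack, l, r)
  }

  leaf_node <- integer(d)
  leaf_node[leaf_mode[leaf_mode > 0L]] <- which(leaf_mode > 0L)

  structure(
    list(d = d, nnodes = nnodes, left = left, right = right,
         parent = parent, modes = modes, leaf_mode = leaf_mode,
         leaf_node = leaf_node, leaf_order = leaf_order),
    class = "dimension_tree")
}

is_dimension_tree <- function(x) inherits(x, "dimension_tree")

#' @export
print.dimension_tree <- function(x, ...) {
  cat("Dimension tree over", x$d, "mode(s),", x$nnodes, "node(s)\n")
  cat("Leaf order:", paste(x$leaf_order, collapse = " "), "\n")
  cat(tree_newick(x), "\n")
  invisible(x)
}

#' Newick-style rendering of a dimension tree
#'
#' Serializes the nested split structure as a parenthesised string with the
#' mode index at each leaf, e.g. `"((1,2),3);"` for `d = 3`. Useful for
#' inspecting or logging tree layouts.
#'
#' @param tree a [balanced_tree()] object.
#' @return a single string.
#' @export
tree_newick <- function(tree) {
  stopifnot(is_dimension_tree(tree))
  rec <- function(t) {
    if (tree$left[t] == 0L) return(as.character(tree$leaf_mode[t]))
    paste0("(", rec(tree$left[t]), ",", rec(tree$right[t]), ")")
  }
  paste0(rec(1L), ";")
}

# depth of each node (root = 0); used by diagnostics
tree_depths <- function(tree) {
  depth <- integer(tree$nnodes)
  for (t in seq_len(tree$nnodes)[-1L]) depth[t] <- depth[tree$parent[t]] + 1L
  depth
}
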