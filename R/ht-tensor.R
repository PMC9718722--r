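#' Truncation control
#'
#' Settings for SVD-based rank truncation of hierarchical Tucker tensors.
#' `eps_trunc` is the maximum relative truncation error per truncation call:
#' the discarded node singular values are budgeted so that
#' `||x - trunc(x)|| <= eps_trunc * ||x||` (the budget is split uniformly
#' over the non-root nodes of the tree). `max_rank` optionally caps every
#' node rank regardless of the error budget (0 = no cap).
#'
#' @param eps_trunc nonnegative relative tolerance (default `1e-7`).
#' @param max_rank integer node-rank cap, 0 for none.
#' @return an object of class `trunc_control`.
#' @export
trunc_control <- function(eps_trunc = 1e-7, max_rank = 0L) {
  if (!is.numeric(eps_trunc) || length(eps_trunc) != 1L || eps_trunc < 0)
    stop("'eps_trunc' must be a nonnegative scalar")
  max_rank <- as.integer(max_rank)
  if (is.na(max_rank) || max_rank < 0L) stop("'max_rank' must be >= 0")
  structure(list(eps_trunc = eps_trunc, max_rank = max_rank),
            class = "trunc_control")
}

new_ht <- function(tree, dims, data) {
  structure(list(tree = tree, dims = as.integer(dims), data = data),
            class = "ht_tensor")
}

is_ht_tensor <- function(x) inherits(x, "ht_tensor")

same_tree <- function(a, b) {
  identical(a$left, b$left) && identical(a$right, b$right) &&
    identical(a$leaf_mode, b$leaf_mode)
}

check_pair <- function(x, y) {
  stopifnot(is_ht_tensor(x), is_ht_tensor(y))
  if (!identical(x$dims, y$dims) || !same_tree(x$tree, y$tree))
    stop("tensors live on different trees or mode sizes")
}

#' Per-node representation ranks of an HT tensor
#'
#' @param x an `ht_tensor`.
#' @return integer vector of ranks `r_t` in node order (root first).
#' @export
ht_ranks <- function(x) {
  stopifnot(is_ht_tensor(x))
  vapply(seq_len(x$tree$nnodes), function(t) {
    if (x$tree$left[t] == 0L) ncol(x$data[[t]]) else dim(x$data[[t]])[3L]
  }, integer(1L))
}

#' @export
print.ht_tensor <- function(x, ...) {
  cat("Hierarchical Tucker tensor:", x$tree$d, "mode(s), sizes (",
      paste(x$dims, collapse = ", "), ")\n", sep = " ")
  cat("Node ranks:", paste(ht_ranks(x), collapse = " "), "\n")
  cat("Storage:", ht_storage(x), "values (dense:",
      format(prod(x$dims), big.mark = ","), ")\n")
  invisible(x)
}

#' CP tensor (sum of elementary tensor products)
#'
#' @param dims mode sizes.
#' @param factors list of `d` matrices; matrix `j` is `dims[j] x r` and its
#'   `i`-th column is the mode-`j` vector of the `i`-th elementary term.
#' @return an object of class `cp_tensor`.
#' @export
cp_tensor <- function(dims, factors) {
  dims <- as.integer(dims)
  d <- length(dims)
  if (length(factors) != d) stop("need one factor matrix per mode")
  r <- ncol(factors[[1L]])
  for (j in seq_len(d)) {
    if (!is.matrix(factors[[j]]) || nrow(factors[[j]]) != dims[j] ||
        ncol(factors[[j]]) != r)
      stop("factor ", j, " must be ", dims[j], " x ", r)
  }
  structure(list(d = d, dims = dims, factors = factors, rank = r),
            class = "cp_tensor")
}

#' Convert a CP tensor to hierarchical Tucker form
#'
#' Structural conversion: leaf frames collect the CP mode vectors and the
#' transfer tensors are rank-`r` diagonals, so every node rank is bounded by
#' the CP representation rank, independent of the tree.
#'
#' @param x a [cp_tensor()].
#' @param tree a [balanced_tree()] over the same number of modes.
#' @return an `ht_tensor`.
#' @export
cp_to_ht <- function(x, tree = balanced_tree(x$d)) {
  stopifnot(inherits(x, "cp_tensor"), is_dimension_tree(tree),
            tree$d == x$d)
  r <- x$rank
  data <- vector("list", tree$nnodes)
  for (t in seq_len(tree$nnodes)) {
    if (tree$left[t] == 0L) {
      data[[t]] <- x$factors[[tree$leaf_mode[t]]]
    } else if (t == 1L && tree$nnodes > 1L) {
      C <- array(0, c(r, r, 1L))
      for (k in seq_len(r)) C[k, k, 1L] <- 1
      data[[t]] <- C
    } else {
      B <- array(0, c(r, r, r))
      for (k in seq_len(r)) B[k, k, k] <- 1
      data[[t]] <- B
    }
  }
  if (tree$nnodes == 1L)  # single mode: the tensor is the summed vector
    data[[1L]] <- matrix(rowSums(x$factors[[1L]]), ncol = 1L)
  new_ht(tree, x$dims, data)
}

#' Elementary unit and all-ones tensors
#'
#' `ht_unit` builds the canonical unit tensor `e_z` concentrated on the
#' global state `z` (the initial distribution of a chain started in `z`);
#' `ht_ones` builds the all-ones tensor used for mass computations. Both are
#' rank 1 at every node.
#'
#' @param state 0-based integer tuple of local states.
#' @param dims mode sizes.
#' @param tree dimension tree (canonical balanced tree by default).
#' @return an `ht_tensor`.
#' @export
ht_unit <- function(state, dims, tree = balanced_tree(length(dims))) {
  d <- length(dims)
  stopifnot(length(state) == d, all(state >= 0L), all(state < dims))
  factors <- lapply(seq_len(d), function(j) {
    v <- matrix(0, dims[j], 1L)
    v[state[j] + 1L, 1L] <- 1
    v
  })
  cp_to_ht(cp_tensor(dims, factors), tree)
}

#' @rdname ht_unit
#' @export
ht_ones <- function(dims, tree = balanced_tree(length(dims))) {
  factors <- lapply(dims, function(n) matrix(1, n, 1L))
  cp_to_ht(cp_tensor(dims, factors), tree)
}

# --- arithmetic --------------------------------------------------------------

#' Hierarchical Tucker arithmetic
#'
#' `ht_add` forms `a*x + b*y` structurally (node ranks add), `ht_scale`
#' rescales, `ht_inner` computes the Euclidean inner product by tree
#' contraction without materializing either tensor, and `ht_norm` is the
#' induced norm.
#'
#' @param x,y `ht_tensor`s on the same tree and mode sizes.
#' @param a,b,alpha scalars.
#' @return an `ht_tensor` (`ht_add`, `ht_scale`) or scalar (`ht_inner`,
#'   `ht_norm`).
#' @export
ht_add <- function(x, y, a = 1, b = 1) {
  check_pair(x, y)
  if (x$tree$nnodes == 1L)
    return(new_ht(x$tree, x$dims, list(a * x$data[[1L]] + b * y$data[[1L]])))
  new_ht(x$tree, x$dims, cpp_ht_add(x$tree, x$data, y$data, a, b))
}

#' @rdname ht_add
#' @export
ht_scale <- function(x, alpha) {
  stopifnot(is_ht_tensor(x))
  x$data[[1L]] <- x$data[[1L]] * alpha
  x
}

#' @rdname ht_add
#' @export
ht_inner <- function(x, y) {
  check_pair(x, y)
  if (x$tree$nnodes == 1L)
    return(sum(x$data[[1L]] * y$data[[1L]]))
  cpp_ht_inner(x$tree, x$data, y$data)
}

#' @rdname ht_add
#' @export
ht_norm <- function(x) sqrt(max(0, ht_inner(x, x)))

#' Orthogonalize an HT representation
#'
#' Leaves-to-root QR sweep after which every non-root leaf frame and
#' transfer matricization has orthonormal columns and the tensor's norm is
#' carried by the root transfer. The represented tensor is unchanged.
#'
#' @param x an `ht_tensor`.
#' @return the orthogonalized `ht_tensor`.
#' @export
ht_orthogonalize <- function(x) {
  stopifnot(is_ht_tensor(x))
  if (x$tree$nnodes == 1L) return(x)
  new_ht(x$tree, x$dims, cpp_ht_orthogonalize(x$tree, x$data))
}

#' Node singular values
#'
#' For each tree node `t`, the singular values of the matricization of the
#' tensor with row modes `t` (computed from the reduced Gramians of the
#' orthogonalized representation, never from the dense tensor). The root
#' entry holds the single value `||x||`; the two children of the root are
#' matricizations transposed of each other and share their spectrum.
#'
#' @param x an `ht_tensor`.
#' @return a list of nonincreasing numeric vectors, one per node in node
#'   order.
#' @export
node_singular_values <- function(x) {
  stopifnot(is_ht_tensor(x))
  if (x$tree$nnodes == 1L) return(list(ht_norm(x)))
  cpp_ht_node_svals(x$tree, x$data)
}

#' Truncate an HT tensor to lower rank
#'
#' Orthogonalizes, computes the reduced Gramians, and projects each non-root
#' node onto its leading singular subspace, choosing at node `t` the
#' smallest rank whose discarded squared singular values stay within the
#' per-node share of the total budget `(eps_trunc * ||x||)^2`. The total
#' error then satisfies
#' `||x - trunc(x)||^2 <= sum_t sum_{m > r_t} sigma_{t,m}^2`.
#'
#' @param x an `ht_tensor`.
#' @param ctrl a [trunc_control()].
#' @return the truncated `ht_tensor`.
#' @export
ht_truncate <- function(x, ctrl = trunc_control()) {
  stopifnot(is_ht_tensor(x), inherits(ctrl, "trunc_control"))
  if (x$tree$nnodes == 1L) return(x)
  new_ht(x$tree, x$dims,
         cpp_ht_truncate(x$tree, x$data, ctrl$eps_trunc, ctrl$max_rank))
}

#' Apply a CP operator to an HT tensor
#'
#' Applies `A = sum_i kron(A_i1, ..., A_id)` term by term (each term only
#' multiplies the leaf frames, leaving node ranks unchanged) and accumulates
#' the sum. In `"incremental"` mode (the default) the running sum is
#' truncated after every added term, keeping intermediate node ranks near
#' `rank(A) + rank(x)`; in `"batch"` mode the sum is accumulated exactly --
#' node ranks grow up to `rank(A) * rank(x)` -- and truncated once.
#'
#' @param a a [cp_operator()].
#' @param x an `ht_tensor` with matching mode sizes.
#' @param ctrl a [trunc_control()].
#' @param mode `"incremental"` or `"batch"`.
#' @param truncate set `FALSE` to skip all truncation (exact structural
#'   result; batch mode only).
#' @return an `ht_tensor`.
#' @export
apply_cp_operator <- function(a, x, ctrl = trunc_control(),
                              mode = c("incremental", "batch"),
                              truncate = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "cp_operator"), is_ht_tensor(x))
  if (!identical(as.integer(a$dims), x$dims))
    stop("operator and tensor mode sizes differ")
  if (x$tree$nnodes == 1L) {
    v <- x$data[[1L]]
    out <- matrix(0, nrow(v), 1L)
    for (tm in a$terms) out <- out + tm[[1L]] %*% v
    return(new_ht(x$tree, x$dims, list(out)))
  }
  eps <- if (truncate) ctrl$eps_trunc else -1
  data <- cpp_ht_apply_cp(x$tree, a$terms, rep(1, a$rank), x$data,
                          eps, ctrl$max_rank, mode == "incremental")
  new_ht(x$tree, x$dims, data)
}

# --- dense conversions (oracle scale) ----------------------------------------

# dense vector in the mixed-radix linearization of state_index()
# (mode 1 slowest), from a natural-order dense array
vec_kron <- function(A) {
  d <- length(dim(A))
  if (d <= 1L) return(as.vector(A))
  as.vector(aperm(A, rev(seq_len(d))))
}

array_from_kron <- function(v, dims) {
  d <- length(dims)
  if (d == 1L) return(array(v, dim = dims))
  aperm(array(v, dim = rev(dims)), rev(seq_len(d)))
}

#' Dense realizations of an HT tensor
#'
#' `ht_to_vec` expands the tensor into a dense vector over the linearized
#' state space (see [state_index()]); `ht_to_dense` reshapes it into a
#' `d`-dimensional array in natural mode order; `ht_entry` evaluates a
#' single entry in `O(d r^3)` without materializing anything.
#'
#' @param x an `ht_tensor`.
#' @param cap maximum admissible number of entries for the dense forms.
#' @param state 0-based integer tuple of local states.
#' @return a numeric vector, array, or scalar respectively.
#' @export
ht_to_vec <- function(x, cap = 2^14) {
  stopifnot(is_ht_tensor(x))
  N <- prod(x$dims)
  if (N > cap) stop("dense expansion would have ", N, " entries (cap ", cap, ")")
  if (x$tree$nnodes == 1L) return(as.vector(x$data[[1L]]))
  tr <- x$tree
  frame <- function(t) {
    if (tr$left[t] == 0L) return(x$data[[t]])
    U1 <- frame(tr$left[t]); U2 <- frame(tr$right[t])
    B <- x$data[[t]]
    r <- dim(B)[3L]
    # column (a, b) of kronecker(U1, U2) pairs a (slow) with b (fast)
    M <- matrix(aperm(B, c(2L, 1L, 3L)), nrow = dim(B)[1L] * dim(B)[2L])
    kronecker(U1, U2) %*% M
  }
  v_leaf <- as.vector(frame(1L))
  ord <- tr$leaf_order
  if (identical(ord, seq_len(tr$d))) return(v_leaf)
  # re-index from leaf order to the natural mode order
  states <- all_states(x$dims)
  idx <- apply(states, 1L, function(s) state_index(s[ord], x$dims[ord]))
  v_leaf[idx]
}

#' @rdname ht_to_vec
#' @export
ht_to_dense <- function(x, cap = 2^14) {
  array_from_kron(ht_to_vec(x, cap), x$dims)
}

#' @rdname ht_to_vec
#' @export
ht_entry <- function(x, state) {
  stopifnot(is_ht_tensor(x))
  d <- x$tree$d
  stopifnot(length(state) == d, all(state >= 0L), all(state < x$dims))
  tr <- x$tree
  ev <- function(t) {
    if (tr$left[t] == 0L)
      return(x$data[[t]][state[tr$leaf_mode[t]] + 1L, ])
    v1 <- ev(tr$left[t]); v2 <- ev(tr$right[t])
    B <- x$data[[t]]
    r <- dim(B)[3L]
    out <- numeric(r)
    for (k in seq_len(r)) out[k] <- as.numeric(v1 %*% B[, , k] %*% v2)
    out
  }
  as.numeric(ev(1L))
}

#' Matricization of a dense tensor
#'
#' Reshapes a dense array into the matrix whose rows are indexed by the
#' modes in `t` (first listed mode fastest) and whose columns are indexed by
#' the complementary modes in increasing order.
#'
#' @param b a dense array (or a vector in [state_index()] order together
#'   with `dims`).
#' @param t nonempty integer subset of modes.
#' @param dims mode sizes, required when `b` is a vector.
#' @return a matrix.
#' @export
matricize <- function(b, t, dims = dim(b)) {
  if (is.null(dim(b))) b <- array_from_kron(b, dims)
  d <- length(dim(b))
  t <- as.integer(t)
  if (length(t) == 0L || any(t < 1L) || any(t > d) || anyDuplicated(t))
    stop("'t' must be a nonempty subset of 1:", d)
  s <- setdiff(seq_len(d), t)
  if (length(s) == 0L) return(matrix(as.vector(b), nrow = length(b)))
  matrix(aperm(b, c(t, s)), nrow = prod(dim(b)[t]))
}

#' Storage count of an HT representation
#'
#' Number of stored values: `n_i * r_i` per leaf plus
#' `r_t1 * r_t2 * r_t` per inner node (the root has `r_root = 1`).
#'
#' @param x an `ht_tensor`.
#' @return an integer-valued scalar.
#' @export
ht_storage <- function(x) {
  stopifnot(is_ht_tensor(x))
  sum(vapply(seq_len(x$tree$nnodes), function(t) {
    if (x$tree$left[t] == 0L) prod(dim(x$data[[t]]))
    else prod(dim(x$data[[t]]))
  }, numeric(1L)))
}
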