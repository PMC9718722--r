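#' Validate a Mutual Hazard Network parameter matrix
#'
#' A Mutual Hazard Network (MHN) over `d` binary, irreversible genomic events
#' is parameterised by a `d x d` matrix `Theta` of nonnegative reals: the
#' diagonal entry `Theta[i, i]` is the baseline activation rate of event `i`,
#' and the off-diagonal `Theta[i, j]` is the multiplicative effect that an
#' already-active event `j` exerts on the activation rate of event `i`
#' (`> 1` promoting, `< 1` inhibiting, `1` neutral).
#'
#' @param x a square numeric matrix (or something coercible to one).
#' @return the validated `d x d` numeric matrix.
#' @examples
#' theta_matrix(matrix(c(1, 2, 0.5, 3), 2, 2, byrow = TRUE))
#' @export
theta_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("Theta must be numeric")
  if (nrow(x) != ncol(x))
    stop("Theta must be square, got ", nrow(x), " x ", ncol(x))
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("Theta[%d, %d] = %s is negative or non-finite",
                 bad[1L, 1L], bad[1L, 2L], format(x[bad[1L, , drop = FALSE]])))
  storage.mode(x) <- "double"
  unname(x)
}

#' Construct a stochastic automata network specification
#'
#' A stochastic automata network (SAN) couples `d` automata, automaton `i`
#' having `sizes[i]` local states `0, ..., sizes[i] - 1`. Each local
#' transition `x_i -> y_i` of automaton `i` carries, for every automaton
#' `j`, a vector of nonnegative effects over the local states of `j`: the
#' transition's rate in global state `x` is the product over `j` of the
#' effect of state `x_j`. The entry for `j = i` holds the baseline rate
#' (read at the transition's source state).
#'
#' @param sizes integer vector of local state-space sizes (`>= 2`).
#' @param transitions a list of length `d`; element `i` is a (possibly
#'   empty) list of transitions for automaton `i`, each a list with fields
#'   `from`, `to` (distinct 0-based local states) and `effects` (a list of
#'   `d` nonnegative numeric vectors, `effects[[j]]` of length `sizes[j]`).
#' @param mhn logical; marks specs derived from an MHN parameter matrix
#'   (binary automata, single `0 -> 1` transition each).
#' @param theta optional originating MHN matrix, kept for reference.
#' @return an object of class `san_spec`.
#' @seealso [mhn_to_san()], [build_generator_cp()]
#' @export
san_spec <- function(sizes, transitions, mhn = FALSE, theta = NULL) {
  sizes <- as.integer(sizes)
  d <- length(sizes)
  if (d < 1L || anyNA(sizes) || any(sizes < 2L))
    stop("'sizes' must give at least one automaton with >= 2 local states")
  if (!is.list(transitions) || length(transitions) != d)
    stop("'transitions' must be a list of length d = ", d)
  for (i in seq_len(d)) {
    for (tr in transitions[[i]]) {
      if (!is.list(tr) || is.null(tr$from) || is.null(tr$to) ||
          is.null(tr$effects))
        stop("transition entries need fields 'from', 'to', 'effects' ",
             "(automaton ", i, ")")
      if (tr$from == tr$to || tr$from < 0L || tr$to < 0L ||
          tr$from >= sizes[i] || tr$to >= sizes[i])
        stop(sprintf(
          "automaton %d: transition %d -> %d references invalid local states",
          i, tr$from, tr$to))
      if (length(tr$effects) != d)
        stop("automaton ", i, ": need one effect vector per automaton")
      for (j in seq_len(d)) {
        ef <- tr$effects[[j]]
        if (length(ef) != sizes[j] || any(!is.finite(ef)) || any(ef < 0))
          stop(sprintf(
            "automaton %d, transition %d -> %d: effect vector for automaton %d must be %d nonnegative finite values",
            i, tr$from, tr$to, j, sizes[j]))
      }
    }
  }
  structure(list(d = d, sizes = sizes, transitions = transitions,
                 mhn = isTRUE(mhn), theta = theta),
            class = "san_spec")
}

#' @export
print.san_spec <- function(x, ...) {
  m <- sum(lengths(x$transitions))
  cat("Stochastic automata network:", x$d, "automata,",
      m, "local transition(s)", if (x$mhn) "(MHN-derived)" else "", "\n")
  cat("Local state counts:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' Convert an MHN parameter matrix to a SAN specification
#'
#' Every event becomes a binary automaton with the single irreversible
#' transition `0 -> 1`. The effect of automaton `j` on the transition of
#' event `i` is `1` when event `j` is absent and `Theta[i, j]` when present;
#' the baseline entry (`j = i`) is `Theta[i, i]`.
#'
#' @param theta a `d x d` nonnegative matrix, see [theta_matrix()].
#' @return a `san_spec` with the `mhn` flag set.
#' @examples
#' sp <- mhn_to_san(matrix(c(1, 1.6, 1, 2), 2, 2, byrow = TRUE))
#' sp$transitions[[1]][[1]]$effects[[2]]  # c(1, 1.6)
#' @export
mhn_to_san <- function(theta) {
  theta <- theta_matrix(theta)
  d <- nrow(theta)
  transitions <- vector("list", d)
  for (i in seq_len(d)) {
    effects <- vector("list", d)
    for (j in seq_len(d)) {
      effects[[j]] <- if (j == i) rep(theta[i, i], 2L) else c(1, theta[i, j])
    }
    transitions[[i]] <- list(list(from = 0L, to = 1L, effects = effects))
  }
  san_spec(rep(2L, d), transitions, mhn = TRUE, theta = theta)
}

#' CP (sum-of-Kronecker-products) operator
#'
#' @param dims integer vector of mode sizes.
#' @param terms list of terms, each a list of `length(dims)` square matrices
#'   with matching mode sizes.
#' @return an object of class `cp_operator` with a `rank` equal to the
#'   number of terms.
#' @export
cp_operator <- function(dims, terms) {
  dims <- as.integer(dims)
  d <- length(dims)
  for (tm in terms) {
    if (length(tm) != d) stop("each term needs ", d, " factor matrices")
    for (j in seq_len(d))
      if (!is.matrix(tm[[j]]) || any(dim(tm[[j]]) != dims[j]))
        stop("factor ", j, " must be a ", dims[j], " x ", dims[j], " matrix")
  }
  structure(list(d = d, dims = dims, terms = terms, rank = length(terms)),
            class = "cp_operator")
}

#' @export
print.cp_operator <- function(x, ...) {
  cat("CP operator on modes (", paste(x$dims, collapse = ", "),
      "), representation rank ", x$rank, "\n", sep = "")
  invisible(x)
}

#' Kronecker-structured infinitesimal generator of a SAN
#'
#' Assembles the generator `Q` of the network as a CP operator with one
#' Kronecker term per local transition: for automata `j != i` the factor is
#' the diagonal matrix of the transition's effects over the states of `j`;
#' for `j = i` the factor moves mass from the source to the target state
#' (baseline rate at `(to, from)`, its negative at `(from, from)`). Columns
#' of the (conceptual) dense expansion index the source state, so every
#' column sums to zero.
#'
#' @param spec a [san_spec()] (or an MHN `Theta` matrix, which is converted
#'   first).
#' @return a [cp_operator()] of representation rank equal to the total
#'   number of local transitions.
#' @examples
#' q <- build_generator_cp(mhn_to_san(matrix(2, 1, 1)))
#' q$terms[[1]][[1]]  # matrix(c(-2, 2, 0, 0), 2, 2)
#' @export
build_generator_cp <- function(spec) {
  spec <- as_san_spec(spec)
  d <- spec$d
  terms <- list()
  for (i in seq_len(d)) {
    for (tr in spec$transitions[[i]]) {
      term <- vector("list", d)
      for (j in seq_len(d)) {
        if (j == i) {
          base <- tr$effects[[i]][tr$from + 1L]
          f <- matrix(0, spec$sizes[i], spec$sizes[i])
          f[tr$to + 1L, tr$from + 1L] <- base
          f[tr$from + 1L, tr$from + 1L] <- -base
        } else {
          f <- diag(tr$effects[[j]], nrow = spec$sizes[j])
        }
        term[[j]] <- f
      }
      terms <- c(terms, list(term))
    }
  }
  cp_operator(spec$sizes, terms)
}

as_san_spec <- function(x) {
  if (inherits(x, "san_spec")) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(mhn_to_san(as.matrix(x)))
  stop("expected a 'san_spec' or an MHN Theta matrix")
}

# --- dense state-space helpers (oracle scale only) ---------------------------

#' Linear index of a global state
#'
#' Global states are 0-based tuples `(x_1, ..., x_d)`; the linearization is
#' mixed-radix with `x_1` the slowest-varying index, matching the order of
#' Kronecker factors in the CP representation of the generator.
#'
#' @param x integer vector of local states (0-based) or a matrix with one
#'   state per row.
#' @param sizes local state-space sizes.
#' @return 1-based linear indices.
#' @export
state_index <- function(x, sizes) {
  if (is.matrix(x)) return(apply(x, 1L, state_index, sizes = sizes))
  d <- length(sizes)
  stopifnot(length(x) == d, all(x >= 0L), all(x < sizes))
  w <- rev(cumprod(rev(c(sizes[-1L], 1L))))
  as.integer(1L + sum(x * w))
}

#' Enumerate all global states
#'
#' @param sizes local state-space sizes; `prod(sizes)` must stay small.
#' @return an integer matrix, one 0-based state per row, in linearization
#'   order (see [state_index()]).
#' @export
all_states <- function(sizes) {
  d <- length(sizes)
  N <- prod(sizes)
  idx <- 0:(N - 1)
  out <- matrix(0L, N, d)
  rem <- idx
  for (j in d:1) {
    out[, j] <- as.integer(rem %% sizes[j])
    rem <- rem %/% sizes[j]
  }
  out
}

#' Dense infinitesimal generator (reference implementation)
#'
#' Materializes the full `|S| x |S|` generator entry by entry from the
#' transition rates (not from the CP factors), for use as an oracle at small
#' dimension: `Q[y, x]` is the product of the transition's effects at the
#' source state `x`, and the diagonal holds negative column sums.
#'
#' @param spec a [san_spec()] or MHN `Theta` matrix.
#' @param cap maximum admissible number of global states.
#' @return a dense matrix over the linearized state space.
#' @export
generator_dense <- function(spec, cap = 2^14) {
  spec <- as_san_spec(spec)
  N <- prod(spec$sizes)
  if (N > cap)
    stop("state space has ", N, " states, exceeding the dense cap of ", cap)
  states <- all_states(spec$sizes)
  Q <- matrix(0, N, N)
  for (xi in seq_len(N)) {
    x <- states[xi, ]
    for (i in seq_len(spec$d)) {
      for (tr in spec$transitions[[i]]) {
        if (tr$from != x[i]) next
        rate <- 1
        for (j in seq_len(spec$d)) {
          rate <- rate * (if (j == i) tr$effects[[i]][tr$from + 1L]
                          else tr$effects[[j]][x[j] + 1L])
        }
        y <- x
        y[i] <- tr$to
        Q[state_index(y, spec$sizes), xi] <- Q[state_index(y, spec$sizes), xi] + rate
      }
    }
  }
  diag(Q) <- diag(Q) - colSums(Q)
  Q
}

#' Uniformization rate bound
#'
#' Returns an upper bound `gamma >= max_x |Q[x, x]|` on the total exit rate,
#' computed from the separable parameters without enumerating the state
#' space. For an MHN-derived spec the bound is
#' `sum_i prod_j max(1, Theta[i, j])`; in general each automaton contributes
#' the maximum over its source states of the summed worst-case rates of the
#' transitions leaving that state (baseline at the source state times the
#' maximal effect of every other automaton).
#'
#' @param spec a [san_spec()] or MHN `Theta` matrix.
#' @return a positive scalar.
#' @examples
#' gamma_bound(matrix(c(1, 2, 0.5, 3), 2, 2, byrow = TRUE))  # 5
#' @export
gamma_bound <- function(spec) {
  spec <- as_san_spec(spec)
  if (spec$mhn && !is.null(spec$theta)) {
    # all baseline rates zero means every transition is disabled, even
    # though the max(1, .) bound itself would still be positive
    if (all(diag(spec$theta) == 0))
      stop("all transition rates are zero: the uniformization rate would be 0")
    g <- sum(apply(pmax(spec$theta, 1), 1L, prod))
  } else {
    g <- 0
    for (i in seq_len(spec$d)) {
      trs <- spec$transitions[[i]]
      if (!length(trs)) next
      per_state <- numeric(spec$sizes[i])
      for (tr in trs) {
        w <- tr$effects[[i]][tr$from + 1L]
        for (j in seq_len(spec$d))
          if (j != i) w <- w * max(tr$effects[[j]])
        per_state[tr$from + 1L] <- per_state[tr$from + 1L] + w
      }
      g <- g + max(per_state)
    }
  }
  if (g <= 0)
    stop("all transition rates are zero: the uniformization rate would be 0")
  g
}

#' Uniformized transition operator in CP form
#'
#' Forms `P = Id + Q / gamma` by rescaling the generator's CP terms and
#' appending a rank-1 identity term. For any `gamma` at least as large as
#' the largest diagonal magnitude of `Q`, the dense expansion of `P` is
#' column-stochastic with nonnegative entries.
#'
#' @param q the generator as a [cp_operator()].
#' @param gamma positive uniformization rate, see [gamma_bound()].
#' @return a [cp_operator()] of rank at most `rank(q) + 1`.
#' @export
uniformized_cp <- function(q, gamma) {
  stopifnot(inherits(q, "cp_operator"))
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0)
    stop("'gamma' must be a positive scalar")
  terms <- lapply(q$terms, function(tm) {
    tm[[1L]] <- tm[[1L]] / gamma
    tm
  })
  id_term <- lapply(q$dims, function(n) diag(1, n))
  cp_operator(q$dims, c(terms, list(id_term)))
}

#' Dense expansion of a CP operator (oracle)
#'
#' @param a a [cp_operator()].
#' @param cap maximum admissible number of global states.
#' @return the dense matrix `sum_i kron(A_i1, ..., A_id)` with the first
#'   factor slowest-varying.
#' @export
cp_operator_dense <- function(a, cap = 2^14) {
  N <- prod(a$dims)
  if (N > cap) stop("dense expansion would have ", N, " states (cap ", cap, ")")
  out <- matrix(0, N, N)
  for (tm in a$terms) {
    acc <- tm[[1L]]
    for (j in seq_len(a$d)[-1L]) acc <- kronecker(acc, tm[[j]])
    out <- out + acc
  }
  out
}
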