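# Dense oracles and random-instance generators shared across the tests.
# Everything here works entrywise / via base linear algebra, independent of
# the tree-structured code paths it is used to check.

# dense vector (state_index order, mode 1 slowest) of a CP tensor given as
# a list of d matrices with one column per elementary term
dense_cp_vec <- function(factors) {
  r <- ncol(factors[[1L]])
  acc <- 0
  for (i in seq_len(r)) {
    v <- factors[[1L]][, i]
    for (j in seq_along(factors)[-1L]) v <- kronecker(v, factors[[j]][, i])
    acc <- acc + v
  }
  as.vector(acc)
}

# random hierarchical Tucker tensor with generic (dense Gaussian) frames and
# transfer tensors; ranks are chosen admissibly at random
rand_ht <- function(dims, seed, max_rank = 4L, tree = NULL) {
  set.seed(seed)
  d <- length(dims)
  if (is.null(tree)) tree <- balanced_tree(d)
  ranks <- integer(tree$nnodes)
  ranks[1L] <- 1L
  for (t in seq_len(tree$nnodes)) {
    if (t > 1L) ranks[t] <- sample.int(max_rank, 1L)
    if (tree$left[t] == 0L)
      ranks[t] <- min(ranks[t], dims[tree$leaf_mode[t]])
  }
  data <- vector("list", tree$nnodes)
  for (t in seq_len(tree$nnodes)) {
    if (tree$left[t] == 0L) {
      n <- dims[tree$leaf_mode[t]]
      data[[t]] <- matrix(rnorm(n * ranks[t]), n, ranks[t])
    } else {
      r1 <- ranks[tree$left[t]]; r2 <- ranks[tree$right[t]]
      data[[t]] <- array(rnorm(r1 * r2 * ranks[t]), c(r1, r2, ranks[t]))
    }
  }
  htmarginal:::new_ht(tree, dims, data)
}

# random small SAN spec, optionally with non-binary automata and several
# (possibly reversing) transitions per automaton
rand_san <- function(seed, d = 3L, max_size = 3L) {
  set.seed(seed)
  sizes <- sample(2:max_size, d, replace = TRUE)
  transitions <- vector("list", d)
  for (i in seq_len(d)) {
    ntr <- sample(0:2, 1L)
    trs <- list()
    for (k in seq_len(ntr)) {
      fromto <- sample.int(sizes[i], 2L) - 1L
      effects <- lapply(seq_len(d), function(j)
        exp(rnorm(sizes[j], 0, 0.5)))
      trs <- c(trs, list(list(from = fromto[1L], to = fromto[2L],
                              effects = effects)))
    }
    transitions[[i]] <- trs
  }
  if (sum(lengths(transitions)) == 0L) {
    transitions[[1L]] <- list(list(
      from = 0L, to = 1L,
      effects = lapply(seq_len(d), function(j) exp(rnorm(sizes[j], 0, 0.5)))))
  }
  san_spec(sizes, transitions)
}

# unit vector over the linearized state space
dense_unit <- function(sizes, state = rep(0L, length(sizes))) {
  v <- numeric(prod(sizes))
  v[state_index(state, sizes)] <- 1
  v
}
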