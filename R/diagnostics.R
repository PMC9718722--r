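#' Effective rank of a hierarchical Tucker representation
#'
#' The constant node rank whose storage cost on the same tree matches the
#' representation's actual storage, rounded up to the nearest integer:
#' the smallest integer `r` with
#' `sum_leaves n_i * r + (#inner - 1) * r^3 + r^2 >= storage(x)`.
#' A representation whose node ranks all equal `r` has effective rank
#' exactly `r`.
#'
#' @param x an `ht_tensor`.
#' @return a positive integer.
#' @export
effective_rank <- function(x) {
  stopifnot(is_ht_tensor(x))
  actual <- ht_storage(x)
  r <- 1L
  while (constant_rank_storage(x$dims, x$tree, r) < actual) r <- r + 1L
  r
}

constant_rank_storage <- function(dims, tree, r) {
  if (tree$nnodes == 1L) return(dims[1L] * r)
  n_inner <- sum(tree$left > 0L)
  sum(dims) * r + (n_inner - 1) * r^3 + r^2
}

#' Storage counts for dense and hierarchical Tucker representations
#'
#' Either measures an actual `ht_tensor`, or evaluates the constant-rank
#' storage model for a chain of `d` automata with `n` local states each:
#' dense storage is `n^d` while the HT representation needs
#' `d*n*r + (d-2)*r^3 + r^2` values on a balanced tree.
#'
#' @param x an `ht_tensor`, or `NULL` to use the model.
#' @param d,n,rank model parameters when `x` is `NULL`.
#' @return a named numeric vector with components `ht` and `dense`.
#' @examples
#' storage_counts(d = 10)["dense"]  # 1024
#' @export
storage_counts <- function(x = NULL, d = NULL, n = 2L, rank = 1L) {
  if (!is.null(x)) {
    stopifnot(is_ht_tensor(x))
    return(c(ht = ht_storage(x), dense = prod(x$dims)))
  }
  stopifnot(!is.null(d), d >= 1, n >= 2, rank >= 1)
  tree <- balanced_tree(d)
  c(ht = constant_rank_storage(rep(n, d), tree, rank), dense = n^d)
}

#' Kullback-Leibler divergence with cutoff
#'
#' `KL(p_ref, p_approx) = sum_x p_ref[x] * log(p_ref[x] / p_approx[x])`
#' with the convention `0 * log(0) = 0`: reference entries at or below
#' `eps_cutoff` are dropped from the sum. Because a low-rank approximation
#' may carry tiny negative entries, any nonpositive `p_approx` entry that
#' survives the cutoff raises an error (the cutoff is too small for this
#' approximation) rather than being clamped. Natural logarithm.
#'
#' @param p_ref dense reference distribution.
#' @param p_approx dense approximation (entries may be slightly negative).
#' @param eps_cutoff cutoff on reference entries (default `1e-8`).
#' @return a scalar (not clamped to be nonnegative).
#' @export
kl_divergence <- function(p_ref, p_approx, eps_cutoff = 1e-8) {
  stopifnot(length(p_ref) == length(p_approx), eps_cutoff >= 0)
  keep <- p_ref > eps_cutoff
  if (any(p_approx[keep] <= 0))
    stop("approximation has nonpositive entries above the cutoff; ",
         "increase eps_cutoff or decrease the truncation error")
  sum(p_ref[keep] * log(p_ref[keep] / p_approx[keep]))
}

#' Singular-value spectra of exact marginal distributions
#'
#' Monte-Carlo study of low-rank approximability: for each sampled
#' parameter matrix the marginal distribution is computed by the dense
#' reference solver, matricized at every node of the dimension tree, and
#' decomposed by a dense SVD. Reported are the arithmetic mean spectrum per
#' node and the mean count of singular values that are numerically zero
#' (below `zero_tol` relative to the largest).
#'
#' @param design a [block_design()]; `2^d` must stay within `cap`.
#' @param tree dimension tree (canonical balanced tree by default).
#' @param n_samples number of sampled parameter matrices.
#' @param seed base seed; sample `s` uses `seed + s`.
#' @param zero_tol relative threshold for "numerically zero": a singular
#'   value counts as zero when it falls below `zero_tol` times the largest,
#'   i.e. at the double-precision resolution of the dense solve.
#' @param cap dense state-space cap.
#' @return a list with `mean_svals` (list of mean spectra per node),
#'   `mean_zero_counts` (numeric vector per node), `tree` and `depths`.
#' @export
spectrum_study <- function(design, tree = NULL, n_samples = 100L, seed = 1L,
                           zero_tol = 1e-15, cap = 2^14) {
  d <- design$d
  if (is.null(tree)) tree <- balanced_tree(d)
  stopifnot(tree$d == d, 2^d <= cap)
  sizes <- rep(2L, d)
  sums <- vector("list", tree$nnodes)
  zero_counts <- numeric(tree$nnodes)
  for (s in seq_len(n_samples)) {
    theta <- sample_theta(design, seed = seed + s)
    spec <- mhn_to_san(theta)
    q <- generator_dense(spec, cap = cap)
    p0 <- numeric(2^d); p0[1L] <- 1
    p <- dense_marginal(q, p0, cap = cap)
    for (t in seq_len(tree$nnodes)) {
      sv <- svd(matricize(p, tree$modes[[t]], dims = sizes), nu = 0, nv = 0)$d
      if (is.null(sums[[t]])) sums[[t]] <- numeric(length(sv))
      sums[[t]] <- sums[[t]] + sv
      zero_counts[t] <- zero_counts[t] + sum(sv < zero_tol * sv[1L])
    }
  }
  list(mean_svals = lapply(sums, function(v) v / n_samples),
       mean_zero_counts = zero_counts / n_samples,
       tree = tree, depths = tree_depths(tree))
}

#' Effective-rank and convergence studies of the low-rank solver
#'
#' `rank_study` runs the normalized truncated uniformization solver on
#' freshly sampled parameter matrices for each supplied design and records
#' the effective rank of each solution; `convergence_study` records the
#' relative-residual trajectory and fits the log-linear convergence slope
#' by least squares.
#'
#' @param designs a list of [block_design()] objects (`rank_study`).
#' @param design a single [block_design()] (`convergence_study`).
#' @param n_samples samples per design.
#' @param seed base seed; sample `s` uses `seed + s`.
#' @param tol,eps_trunc,max_iter,check_every solver settings.
#' @return `rank_study`: a data frame with one row per (design, sample);
#'   `convergence_study`: a list with the residual `curves` data frame and
#'   the fitted per-iteration `slopes` (log10 scale) per sample.
#' @export
rank_study <- function(designs, n_samples = 5L, seed = 1L, tol = 1e-4,
                       eps_trunc = 1e-7, max_iter = 10000L,
                       check_every = 10L) {
  if (inherits(designs, "block_design")) designs <- list(designs)
  rows <- list()
  for (g in designs) {
    for (s in seq_len(n_samples)) {
      theta <- sample_theta(g, seed = seed + s)
      fit <- marginal_lowrank(theta, tol = tol, eps_trunc = eps_trunc,
                              max_iter = max_iter, check_every = check_every)
      rows[[length(rows) + 1L]] <- data.frame(
        type = g$type, d = g$d, n_blocks = g$n_blocks, sample = s,
        seed = seed + s, effective_rank = effective_rank(fit$p),
        iterations = fit$iterations,
        residual = utils::tail(fit$history$residual, 1L),
        converged = fit$converged)
    }
  }
  do.call(rbind, rows)
}

#' @rdname rank_study
#' @export
convergence_study <- function(design, n_samples = 5L, seed = 1L, tol = 1e-4,
                              eps_trunc = 1e-7, max_iter = 10000L,
                              check_every = 10L) {
  curves <- list()
  slopes <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    theta <- sample_theta(design, seed = seed + s)
    fit <- marginal_lowrank(theta, tol = tol, eps_trunc = eps_trunc,
                            max_iter = max_iter, check_every = check_every)
    h <- fit$history
    h$sample <- s
    curves[[s]] <- h
    ok <- h$residual > 0
    slopes[s] <- stats::coef(
      stats::lm(log10(residual) ~ iteration, data = h[ok, ]))[["iteration"]]
  }
  list(curves = do.call(rbind, curves), slopes = slopes)
}
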