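#' Dense reference solvers for the time-marginal distribution
#'
#' The time-marginal distribution of a continuous-time Markov chain with
#' generator `Q`, observed at an `Exp(1)`-distributed random time, is the
#' unique solution of the linear system `(Id - Q) p = p(0)`.
#' `dense_marginal` solves this system directly. `dense_splitting_marginal`
#' instead uses the splitting `Id - Q = D + L` into the diagonal and the
#' strictly lower triangular part (after ordering the states of a
#' progressive binary chain by their number of active events), for which the
#' Neumann series terminates after exactly `d` terms because `L` is
#' nilpotent.
#'
#' @param q dense generator matrix over the linearized state space (columns
#'   index the source state; columns sum to zero).
#' @param p0 dense initial distribution vector.
#' @param cap maximum admissible state-space size.
#' @return the dense marginal distribution vector (sums to 1).
#' @examples
#' q <- generator_dense(mhn_to_san(matrix(1, 1, 1)))
#' dense_marginal(q, c(1, 0))  # c(0.5, 0.5)
#' @export
dense_marginal <- function(q, p0, cap = 2^14) {
  N <- length(p0)
  stopifnot(is.matrix(q), nrow(q) == N, ncol(q) == N)
  if (N > cap) stop("state space of size ", N, " exceeds the dense cap")
  solve(diag(1, N) - q, p0)
}

#' @rdname dense_marginal
#' @export
dense_splitting_marginal <- function(q, p0, cap = 2^14) {
  N <- length(p0)
  stopifnot(is.matrix(q), nrow(q) == N, ncol(q) == N)
  if (N > cap) stop("state space of size ", N, " exceeds the dense cap")
  d <- round(log2(N))
  if (2^d != N)
    stop("splitting solver requires a binary progressive chain (|S| = 2^d)")
  nact <- rowSums(all_states(rep(2L, d)))
  ord <- order(nact)
  A <- diag(1, N) - q[ord, ord, drop = FALSE]
  D <- diag(A)
  L <- A - diag(D, N)
  if (any(L[upper.tri(L, diag = TRUE)] != 0))
    stop("generator is not progressive: Id - Q is not lower triangular ",
         "under the event-count state order")
  b <- p0[ord]
  term <- b / D
  acc <- term
  # L moves mass up exactly one event-count level, so L^(d+1) = 0 and the
  # Neumann series terminates after the k = 0, ..., d terms
  for (k in seq_len(d)) {
    term <- -(L %*% term) / D
    acc <- acc + term
  }
  out <- numeric(N)
  out[ord] <- as.vector(acc)
  out
}

#' Total mass of the truncated uniformization series
#'
#' The partial sum `sum_{m=0}^{k} (gamma/(1+gamma))^m (P_gamma)^m p(0)` has
#' total mass `sum_{m<=k} (gamma/(1+gamma))^m` exactly, because each
#' application of the column-stochastic `P_gamma` preserves mass. In closed
#' form this is `((1+gamma)^{k+1} - gamma^{k+1}) / (1+gamma)^k`, evaluated
#' here in the numerically safe form `(1+gamma) * (1 - beta^{k+1})` with
#' `beta = gamma/(1+gamma)` to avoid overflow at large `k`.
#'
#' @param k truncation index, `k >= 0`.
#' @param gamma positive uniformization rate.
#' @return the exact mass (a scalar in `(1, 1+gamma)`).
#' @export
partial_sum_mass <- function(k, gamma) {
  stopifnot(k >= 0, gamma > 0)
  beta <- gamma / (1 + gamma)
  (1 + gamma) * (1 - beta^(k + 1))
}

#' Uniformization partial sums (dense oracle)
#'
#' Computes the unnormalized approximations from below
#' `ptilde^(m) = (1/(1+gamma)) sum_{j<=m} (beta P_gamma)^j p(0)` and their
#' normalized versions `p^(m) = ptilde^(m) / (1 - beta^(m+1))` for
#' `m = 0, ..., k`, with `beta = gamma/(1+gamma)`, in exact dense
#' arithmetic. The normalized iterates all have mass exactly 1; the
#' unnormalized ones approach `p` entrywise from below.
#'
#' @param q dense generator matrix.
#' @param p0 dense initial distribution.
#' @param k largest truncation index.
#' @param gamma uniformization rate with `gamma >= max |Q_xx|`.
#' @return a list with matrices `ptilde` and `pnorm` (one column per index
#'   `0..k`) and the vector `masses` of `(1+gamma) * ptilde` masses.
#' @export
neumann_partial_sums <- function(q, p0, k, gamma) {
  N <- length(p0)
  stopifnot(is.matrix(q), nrow(q) == N, k >= 0, gamma > 0)
  beta <- gamma / (1 + gamma)
  P <- diag(1, N) + q / gamma
  ptilde <- matrix(0, N, k + 1)
  pnorm <- matrix(0, N, k + 1)
  term <- p0 / (1 + gamma)
  acc <- term
  ptilde[, 1] <- acc
  pnorm[, 1] <- acc / (1 - beta)
  if (k >= 1) {
    for (m in seq_len(k)) {
      term <- beta * (P %*% term)
      acc <- acc + term
      ptilde[, m + 1] <- acc
      pnorm[, m + 1] <- acc / (1 - beta^(m + 1))
    }
  }
  list(ptilde = ptilde, pnorm = pnorm,
       masses = (1 + gamma) * colSums(ptilde))
}

#' Upper approximation from the truncated series
#'
#' Adds the missing geometric tail mass as a constant shift: with deficit
#' `1 - sum_{m<=k} gamma^m/(1+gamma)^{m+1} = beta^{k+1}`, the tensor
#' `phat^(k) = ptilde^(k) + beta^{k+1} * 1` bounds the marginal
#' distribution entrywise from above, complementing the lower bound
#' `ptilde^(k)`.
#'
#' @param ptilde the unnormalized partial sum, as a dense vector or
#'   `ht_tensor`.
#' @param k its truncation index.
#' @param gamma the uniformization rate used.
#' @return an object of the same kind as `ptilde`.
#' @export
upper_approx <- function(ptilde, k, gamma) {
  stopifnot(k >= 0, gamma > 0)
  deficit <- (gamma / (1 + gamma))^(k + 1)
  if (is_ht_tensor(ptilde))
    return(ht_add(ptilde, ht_ones(ptilde$dims, ptilde$tree), 1, deficit))
  ptilde + deficit
}

#' Relative residual of an approximate marginal distribution
#'
#' Computes `||(Id - Q) p - p(0)|| / ||p(0)||`. For HT inputs the operator
#' application is truncated with `ctrl` and the norm is evaluated through
#' inner products, never densely.
#'
#' @param q generator, as a [cp_operator()] (HT path) or dense matrix.
#' @param p approximation, as `ht_tensor` or dense vector.
#' @param p0 initial distribution, same kind as `p`.
#' @param ctrl a [trunc_control()] for the operator application.
#' @return a nonnegative scalar.
#' @export
relative_residual <- function(q, p, p0, ctrl = trunc_control()) {
  if (is_ht_tensor(p)) {
    stopifnot(inherits(q, "cp_operator"), is_ht_tensor(p0))
    w <- apply_cp_operator(q, p, ctrl, mode = "incremental")
    # || p - w - p0 ||^2 expanded in inner products
    r2 <- ht_inner(p, p) + ht_inner(w, w) + ht_inner(p0, p0) -
      2 * ht_inner(p, w) - 2 * ht_inner(p, p0) + 2 * ht_inner(w, p0)
    return(sqrt(max(0, r2)) / ht_norm(p0))
  }
  sqrt(sum(((p - q %*% p) - p0)^2)) / sqrt(sum(p0^2))
}

#' Theorem-style convergence envelope
#'
#' The normalized uniformization iterates satisfy
#' `||p^(k) - p|| <= c * (gamma/(1+gamma))^k` with
#' `c = ||p(0)/(1+gamma) - p|| + gamma * ||p||`. Given the exact dense
#' solution this computes the rate and constant of that envelope.
#'
#' @param gamma uniformization rate.
#' @param p exact dense marginal distribution.
#' @param p0 dense initial distribution.
#' @return a list with `rate` (in `(0,1)`) and `constant`.
#' @export
convergence_bound <- function(gamma, p, p0) {
  stopifnot(gamma > 0)
  list(rate = gamma / (1 + gamma),
       constant = sqrt(sum((p0 / (1 + gamma) - p)^2)) +
         gamma * sqrt(sum(p^2)))
}

#' Solver configuration
#'
#' @param gamma uniformization rate (`NULL` to derive via [gamma_bound()]).
#' @param tol relative-residual stopping tolerance.
#' @param eps_trunc relative truncation tolerance per truncation call.
#' @param max_iter iteration cap.
#' @param max_rank optional per-node rank cap (0 = none).
#' @param apply_mode `"incremental"` or `"batch"` operator application.
#' @param check_every residual evaluation stride (a residual evaluation
#'   costs one extra operator application).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(gamma = NULL, tol = 1e-4, eps_trunc = 1e-7,
                          max_iter = 10000L, max_rank = 0L,
                          apply_mode = c("incremental", "batch"),
                          check_every = 1L) {
  stopifnot(is.null(gamma) || gamma > 0, tol > 0, eps_trunc >= 0,
            max_iter >= 1, check_every >= 1)
  structure(list(gamma = gamma, tol = tol, eps_trunc = eps_trunc,
                 max_iter = as.integer(max_iter),
                 max_rank = as.integer(max_rank),
                 apply_mode = match.arg(apply_mode),
                 check_every = as.integer(check_every)),
            class = "solver_config")
}

#' Low-rank time-marginal distribution of a separable Markov chain
#'
#' Computes the solution of `(Id - Q) p = p(0)` in the hierarchical Tucker
#' format by the normalized truncated uniformization iteration: term tensors
#' are propagated as `y <- trunc(beta * P_gamma * y)` with
#' `beta = gamma/(1+gamma)` and `P_gamma = Id + Q/gamma`, the partial sum is
#' accumulated with truncation, and each reported iterate is divided by its
#' total mass `<1, p>` so that it sums to one exactly. The iteration stops
#' once the relative residual `||(Id - Q) p - p(0)|| / ||p(0)||` falls below
#' `tol`.
#'
#' `marginal_lowrank()` is the user-facing interface: it accepts an MHN
#' `Theta` matrix or a [san_spec()], assembles the generator, the
#' uniformization bound and the initial state, and returns a fitted-model
#' object with `print`, `summary`, `plot`, `residuals`, `predict` and
#' `simulate` methods. `solve_marginal_lowrank()` is the workhorse on
#' already-assembled CP/HT objects.
#'
#' @param model an MHN `Theta` matrix or [san_spec()].
#' @param q generator as a [cp_operator()].
#' @param p0 initial distribution as an `ht_tensor` (typically [ht_unit()]).
#' @param cfg a [solver_config()].
#' @param tree a [balanced_tree()]; canonical by default.
#' @param initial_state 0-based global start state (all zeros by default).
#' @param ... passed to [solver_config()].
#' @return an object of class `marginal_fit`; see
#'   [print.marginal_fit()] and friends.
#' @examples
#' fit <- marginal_lowrank(matrix(1, 1, 1), tol = 1e-6)
#' predict(fit, rbind(c(0), c(1)))  # both 0.5
#' @export
marginal_lowrank <- function(model, tree = NULL, initial_state = NULL, ...) {
  spec <- as_san_spec(model)
  if (is.null(tree)) tree <- balanced_tree(spec$d)
  if (is.null(initial_state)) initial_state <- rep(0L, spec$d)
  q <- build_generator_cp(spec)
  cfg <- solver_config(...)
  if (is.null(cfg$gamma)) cfg$gamma <- gamma_bound(spec)
  p0 <- ht_unit(initial_state, spec$sizes, tree)
  fit <- solve_marginal_lowrank(q, p0, cfg)
  fit$spec <- spec
  fit$initial_state <- initial_state
  fit
}

#' @rdname marginal_lowrank
#' @export
solve_marginal_lowrank <- function(q, p0, cfg = solver_config()) {
  stopifnot(inherits(q, "cp_operator"), is_ht_tensor(p0),
            inherits(cfg, "solver_config"))
  if (!identical(as.integer(q$dims), p0$dims))
    stop("generator and initial state mode sizes differ")
  gamma <- cfg$gamma
  if (is.null(gamma)) stop("cfg$gamma must be set (see gamma_bound())")
  beta <- gamma / (1 + gamma)
  ctrl <- trunc_control(cfg$eps_trunc, cfg$max_rank)
  tree <- p0$tree
  d1 <- tree$nnodes == 1L

  # P_gamma scaled by beta, as terms for the incremental kernel:
  # identity first (the dominant term), then the generator terms / gamma
  id_term <- lapply(q$dims, function(n) NULL)
  terms <- c(list(id_term), q$terms)
  coefs <- c(beta, rep(beta / gamma, q$rank))

  ones <- ht_ones(p0$dims, tree)
  y <- ht_scale(p0, 1 / (1 + gamma))
  s <- y

  hist_iter <- integer(0)
  hist_resid <- numeric(0)
  hist_mass <- numeric(0)
  hist_reff <- numeric(0)
  converged <- FALSE
  k_final <- 0L
  stagnated <- FALSE

  step <- function(x) {
    if (d1) {
      v <- x$data[[1L]]
      out <- coefs[1L] * v
      for (i in seq_len(q$rank))
        out <- out + coefs[i + 1L] * (q$terms[[i]][[1L]] %*% v)
      return(new_ht(tree, x$dims, list(out)))
    }
    new_ht(tree, x$dims,
           cpp_ht_apply_cp(tree, terms, coefs, x$data, cfg$eps_trunc,
                           cfg$max_rank, cfg$apply_mode == "incremental"))
  }

  for (k in seq_len(cfg$max_iter)) {
    y <- step(y)
    s <- ht_truncate(ht_add(s, y), ctrl)
    mass <- ht_inner(ones, s)
    if (!is.finite(mass) || mass <= 0)
      stop("numerical breakdown: the iterate lost all mass after ",
           "truncation; retry with a smaller eps_trunc")
    k_final <- k
    if (k %% cfg$check_every == 0L || k == cfg$max_iter) {
      p <- ht_scale(s, 1 / mass)
      resid <- relative_residual(q, p, p0, ctrl)
      hist_iter <- c(hist_iter, k)
      hist_resid <- c(hist_resid, resid)
      hist_mass <- c(hist_mass, mass)
      hist_reff <- c(hist_reff, effective_rank(p))
      if (resid < cfg$tol) {
        converged <- TRUE
        break
      }
      nh <- length(hist_resid)
      lag <- max(1L, 50L %/% cfg$check_every)
      if (nh > lag && hist_resid[nh] > 0.99 * hist_resid[nh - lag] &&
          !stagnated) {
        stagnated <- TRUE
        warning("residual stagnating; the truncation error may dominate -- ",
                "consider a smaller eps_trunc", call. = FALSE)
      }
    }
  }

  mass <- ht_inner(ones, s)
  p <- ht_scale(s, 1 / mass)
  if (!converged)
    warning("residual tolerance not reached within max_iter = ",
            cfg$max_iter, " iterations", call. = FALSE)

  structure(list(
    p = p,
    gamma = gamma,
    tol = cfg$tol,
    eps_trunc = cfg$eps_trunc,
    iterations = k_final,
    converged = converged,
    history = data.frame(iteration = hist_iter, residual = hist_resid,
                         mass = hist_mass, effective_rank = hist_reff),
    tree = tree,
    config = cfg,
    p0 = p0
  ), class = "marginal_fit")
}
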