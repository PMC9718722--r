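#' Methods for fitted marginal distributions
#'
#' A `marginal_fit` holds the low-rank approximation `p` of the
#' time-marginal distribution together with the solver trajectory.
#' `print` and `summary` report convergence, effective rank and storage;
#' `plot` draws the relative-residual decay on a log scale; `residuals`
#' returns the recorded residual history; `predict` evaluates state
#' probabilities entrywise from the tensor; `simulate` draws genotypes from
#' the fitted distribution (small dimension only, since sampling
#' materializes the distribution densely).
#'
#' @param x,object a `marginal_fit` from [marginal_lowrank()].
#' @param ... further arguments (passed to [graphics::plot()] for the plot
#'   method, ignored elsewhere).
#' @name marginal_fit-methods
NULL

#' @rdname marginal_fit-methods
#' @export
print.marginal_fit <- function(x, ...) {
  cat("Low-rank time-marginal distribution\n")
  cat("  modes:", x$tree$d, " uniformization rate gamma:",
      format(x$gamma, digits = 6), "\n")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (nrow(x$history))
    cat("  final relative residual:",
        format(utils::tail(x$history$residual, 1L), digits = 4),
        "(tol", format(x$tol, digits = 4), ")\n")
  cat("  effective rank:", effective_rank(x$p), "\n")
  invisible(x)
}

#' @rdname marginal_fit-methods
#' @export
summary.marginal_fit <- function(object, ...) {
  sc <- storage_counts(object$p)
  out <- list(
    d = object$tree$d,
    gamma = object$gamma,
    iterations = object$iterations,
    converged = object$converged,
    final_residual = if (nrow(object$history))
      utils::tail(object$history$residual, 1L) else NA_real_,
    tol = object$tol,
    eps_trunc = object$eps_trunc,
    mass = ht_inner(ht_ones(object$p$dims, object$p$tree), object$p),
    effective_rank = effective_rank(object$p),
    node_ranks = ht_ranks(object$p),
    storage_ht = unname(sc["ht"]),
    storage_dense = unname(sc["dense"]))
  class(out) <- "summary.marginal_fit"
  out
}

#' @export
print.summary.marginal_fit <- function(x, ...) {
  cat("Low-rank time-marginal distribution over", x$d, "automata\n")
  cat(sprintf("  gamma = %.6g, tol = %.3g, eps_trunc = %.3g\n",
              x$gamma, x$tol, x$eps_trunc))
  cat(sprintf("  %d iterations; converged: %s; final residual %.3g\n",
              x$iterations, x$converged, x$final_residual))
  cat(sprintf("  total mass <1, p> = %.15g\n", x$mass))
  cat(sprintf("  effective rank %d; storage %d values (dense: %s)\n",
              x$effective_rank, as.integer(x$storage_ht),
              format(x$storage_dense, big.mark = ",")))
  invisible(x)
}

#' @rdname marginal_fit-methods
#' @export
plot.marginal_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no residual history recorded")
  graphics::plot(h$iteration, h$residual, log = "y", type = "b",
                 xlab = "iteration", ylab = "relative residual", ...)
  graphics::abline(h = x$tol, lty = 2)
  invisible(x)
}

#' @rdname marginal_fit-methods
#' @export
residuals.marginal_fit <- function(object, ...) {
  stats::setNames(object$history$residual, object$history$iteration)
}

#' @rdname marginal_fit-methods
#' @param newdata a matrix of 0-based global states (one per row) or a
#'   single state vector.
#' @export
predict.marginal_fit <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  apply(newdata, 1L, function(s) ht_entry(object$p, as.integer(s)))
}

#' @rdname marginal_fit-methods
#' @param nsim number of states to draw.
#' @param seed optional seed.
#' @param cap dense cap for materializing the distribution.
#' @export
simulate.marginal_fit <- function(object, nsim = 1L, seed = NULL,
                                  cap = 2^14, ...) {
  if (!is.null(seed)) set.seed(seed)
  v <- ht_to_vec(object$p, cap = cap)
  v[v < 0] <- 0
  v <- v / sum(v)
  states <- all_states(object$p$dims)
  states[sample.int(length(v), nsim, replace = TRUE, prob = v), ,
         drop = FALSE]
}
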