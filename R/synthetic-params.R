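#' Block-structured synthetic MHN parameter designs
#'
#' Describes how to sample a `d x d` MHN parameter matrix with block
#' structure. The automata are partitioned into `n_blocks` contiguous
#' blocks of size `b = d / n_blocks`, representing non-interacting
#' subsystems (e.g. distinct regulatory pathways). Three types:
#'
#' * `"B1"` (strict block structure): entries within a block (diagonal
#'   included) are log-normal with `log Theta ~ N(0, sigma_within^2)`;
#'   all cross-block entries are exactly 1 (neutral).
#' * `"B2"` (neighbor blocks): additionally, for each pair of adjacent
#'   blocks, `neighbor_effects` uniformly chosen directed cross pairs
#'   receive log-normal effects with `sigma_between`.
#' * `"B3"`: additionally, `random_effects` directed pairs between any two
#'   distinct blocks receive log-normal effects with `sigma_between`.
#'
#' @param d number of automata; must be divisible by `n_blocks`.
#' @param n_blocks number of blocks.
#' @param sigma_within standard deviation of within-block log effects
#'   (default 0.25).
#' @param sigma_between standard deviation of cross-block log effects
#'   (default 0.125).
#' @param type `"B1"`, `"B2"` or `"B3"`.
#' @param neighbor_effects cross effects per adjacent block pair (B2/B3).
#' @param random_effects total extra cross effects (B3).
#' @param seed default seed used by [sample_theta()].
#' @return an object of class `block_design`.
#' @export
block_design <- function(d, n_blocks, sigma_within = 0.25,
                         sigma_between = 0.125,
                         type = c("B1", "B2", "B3"),
                         neighbor_effects = 4L, random_effects = 8L,
                         seed = NULL) {
  type <- match.arg(type)
  d <- as.integer(d); n_blocks <- as.integer(n_blocks)
  if (d < 1L || n_blocks < 1L || d %% n_blocks != 0L)
    stop("'d' (", d, ") must be divisible by 'n_blocks' (", n_blocks, ")")
  stopifnot(sigma_within > 0, sigma_between > 0)
  structure(list(d = d, n_blocks = n_blocks, b = d %/% n_blocks,
                 sigma_within = sigma_within, sigma_between = sigma_between,
                 type = type, neighbor_effects = as.integer(neighbor_effects),
                 random_effects = as.integer(random_effects), seed = seed),
            class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  cat("Block design ", x$type, ": d = ", x$d, ", ", x$n_blocks,
      " block(s) of size ", x$b, "\n", sep = "")
  invisible(x)
}

#' Block membership of each automaton
#'
#' @param design a [block_design()].
#' @return integer vector giving the block index (1-based) per automaton.
#' @export
describe_blocks <- function(design) {
  rep(seq_len(design$n_blocks), each = design$b)
}

#' Block-separating leaf order
#'
#' A fixed permutation that interleaves the blocks so that members of every
#' block land in both subtrees under the root of the balanced tree (e.g.
#' `1 5 2 6 3 7 4 8` for `d = 8` with 2 blocks). Used to demonstrate how a
#' tree that separates strongly interacting automata slows the decay of the
#' root-level singular values.
#'
#' @param d number of automata.
#' @param n_blocks number of (contiguous, equal-sized) blocks.
#' @return a permutation of `1:d`.
#' @export
block_separating_order <- function(d, n_blocks) {
  stopifnot(d %% n_blocks == 0L)
  b <- d %/% n_blocks
  as.integer(as.vector(t(matrix(seq_len(d), nrow = b, ncol = n_blocks))))
}

#' Sample a block-structured MHN parameter matrix
#'
#' Draws a `Theta` matrix according to a [block_design()]. All entries not
#' selected by the design are exactly 1. Cross-block effects are directed:
#' each selected ordered pair `(i, j)` receives a single log-normal entry,
#' drawn uniformly without replacement among the still-neutral admissible
#' pairs. Sampling is deterministic given `seed`.
#'
#' @param design a [block_design()].
#' @param seed integer seed (falls back to `design$seed`; required through
#'   one of the two).
#' @return a `d x d` parameter matrix.
#' @export
sample_theta <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "block_design"))
  if (is.null(seed)) stop("a seed is required for reproducible sampling")
  set.seed(as.integer(seed))
  d <- design$d; b <- design$b
  blocks <- describe_blocks(design)
  theta <- matrix(1, d, d)
  for (k in seq_len(design$n_blocks)) {
    idx <- which(blocks == k)
    theta[idx, idx] <- exp(stats::rnorm(b * b, 0, design$sigma_within))
  }
  draw_cross <- function(theta, candidates, count, sigma) {
    # candidates: 2-column matrix of ordered (i, j) pairs still neutral
    if (nrow(candidates) < count)
      stop("not enough neutral cross pairs to place ", count, " effects")
    pick <- candidates[sample.int(nrow(candidates), count), , drop = FALSE]
    theta[pick] <- exp(stats::rnorm(count, 0, sigma))
    theta
  }
  if (design$type %in% c("B2", "B3")) {
    for (k in seq_len(design$n_blocks - 1L)) {
      ii <- which(blocks == k); jj <- which(blocks == k + 1L)
      cand <- rbind(as.matrix(expand.grid(ii, jj)),
                    as.matrix(expand.grid(jj, ii)))
      cand <- cand[theta[cand] == 1, , drop = FALSE]
      theta <- draw_cross(theta, cand, design$neighbor_effects,
                          design$sigma_between)
    }
  }
  if (design$type == "B3") {
    cand <- as.matrix(expand.grid(seq_len(d), seq_len(d)))
    cand <- cand[blocks[cand[, 1L]] != blocks[cand[, 2L]], , drop = FALSE]
    cand <- cand[theta[cand] == 1, , drop = FALSE]
    theta <- draw_cross(theta, cand, design$random_effects,
                        design$sigma_between)
  }
  theta
}
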