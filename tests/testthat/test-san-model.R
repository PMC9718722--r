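test_that("theta validation names the offending entry", {
  m <- matrix(1, 2, 2)
  m[2, 1] <- -0.1
  expect_error(theta_matrix(m), "Theta\\[2, 1\\]")
  m[2, 1] <- Inf
  expect_error(theta_matrix(m), "Theta\\[2, 1\\]")
  expect_silent(theta_matrix(matrix(0, 1, 1)))
})

test_that("MHN conversion produces binary irreversible automata", {
  sp <- mhn_to_san(matrix(2, 1, 1))
  expect_identical(sp$sizes, 2L)
  expect_length(sp$transitions[[1L]], 1L)
  tr <- sp$transitions[[1L]][[1L]]
  expect_identical(c(tr$from, tr$to), c(0L, 1L))
  expect_equal(tr$effects[[1L]], c(2, 2))

  # fully neutral network: every effect is 1
  sp2 <- mhn_to_san(matrix(1, 2, 2))
  for (i in 1:2)
    for (j in 1:2)
      expect_true(all(sp2$transitions[[i]][[1L]]$effects[[j]] %in% 1))

  # promoting effect of an active event: state 0 neutral, state 1 carries it
  th <- matrix(1, 2, 2)
  th[2, 1] <- 1.6
  sp3 <- mhn_to_san(th)
  expect_equal(sp3$transitions[[2L]][[1L]]$effects[[1L]], c(1, 1.6))
})

test_that("CP generator matches the hand-built factors at d = 1", {
  q <- build_generator_cp(mhn_to_san(matrix(2, 1, 1)))
  expect_identical(q$rank, 1L)
  expect_equal(q$terms[[1L]][[1L]], matrix(c(-2, 2, 0, 0), 2, 2))
})

test_that("MHN generator has CP rank d and matches entrywise rates", {
  set.seed(42)
  theta <- matrix(exp(rnorm(4, 0, 0.3)), 2, 2)
  q <- build_generator_cp(mhn_to_san(theta))
  expect_identical(q$rank, 2L)

  # oracle: 4x4 generator assembled state by state from the rate product
  states <- all_states(c(2L, 2L))
  Qo <- matrix(0, 4, 4)
  for (x in 1:4) {
    for (i in 1:2) {
      if (states[x, i] != 0L) next
      rate <- theta[i, i]
      for (j in 1:2)
        if (j != i && states[x, j] == 1L) rate <- rate * theta[i, j]
      y <- states[x, ]
      y[i] <- 1L
      Qo[state_index(y, c(2L, 2L)), x] <- rate
    }
  }
  diag(Qo) <- -colSums(Qo)
  expect_equal(cp_operator_dense(q), Qo, tolerance = 1e-14)
})

test_that("CP expansion equals the dense generator for random SANs", {
  for (seed in 1:12) {
    spec <- rand_san(seed, d = sample(2:4, 1L))
    Qd <- generator_dense(spec)
    expect_equal(cp_operator_dense(build_generator_cp(spec)), Qd,
                 tolerance = 1e-12)
    # column-generator convention: <1, Q x> = 0 for random x
    x <- rnorm(ncol(Qd))
    expect_lt(abs(sum(Qd %*% x)), 1e-10 * sum(abs(x)))
    expect_true(all(Qd[row(Qd) != col(Qd)] >= 0))
  }
})

test_that("dense generator examples and size cap", {
  expect_equal(generator_dense(mhn_to_san(matrix(1, 1, 1))),
               matrix(c(-1, 1, 0, 0), 2, 2))
  Q2 <- generator_dense(mhn_to_san(matrix(1, 2, 2)))
  expect_equal(colSums(Q2), numeric(4))
  expect_identical(sum(Q2[row(Q2) != col(Q2)] != 0), 4L)
  expect_error(generator_dense(mhn_to_san(diag(15) + 1), cap = 2^14), "cap")
})

test_that("gamma bound dominates the generator diagonal", {
  expect_equal(gamma_bound(mhn_to_san(matrix(1, 3, 3))), 3)
  th <- matrix(c(1, 2, 0.5, 3), 2, 2, byrow = TRUE)
  expect_equal(gamma_bound(mhn_to_san(th)), 5)
  for (seed in 13:24) {
    spec <- rand_san(seed)
    g <- gamma_bound(spec)
    expect_gte(g, max(abs(diag(generator_dense(spec)))) - 1e-12)
  }
  # MHN path too
  for (seed in 1:6) {
    set.seed(seed)
    spec <- mhn_to_san(matrix(exp(rnorm(16, 0, 0.5)), 4, 4))
    expect_gte(gamma_bound(spec),
               max(abs(diag(generator_dense(spec)))) - 1e-12)
  }
  zero <- mhn_to_san(matrix(0, 2, 2))
  expect_error(gamma_bound(zero), "zero")
})

test_that("uniformized operator is column-stochastic and nonnegative", {
  q1 <- build_generator_cp(mhn_to_san(matrix(1, 1, 1)))
  P1 <- cp_operator_dense(uniformized_cp(q1, 1))
  expect_equal(P1, matrix(c(0, 1, 0, 1), 2, 2))

  for (seed in 25:30) {
    spec <- rand_san(seed)
    q <- build_generator_cp(spec)
    g <- gamma_bound(spec)
    P <- uniformized_cp(q, g)
    expect_lte(P$rank, q$rank + 1L)
    Pd <- cp_operator_dense(P)
    expect_equal(colSums(Pd), rep(1, ncol(Pd)), tolerance = 1e-12)
    expect_true(all(Pd >= -1e-14))
  }
  expect_error(uniformized_cp(q1, 0), "positive")
})
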