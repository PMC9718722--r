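test_that("dense marginal solves the closed-form single-event chains", {
  for (theta in c(1, 3)) {
    q <- generator_dense(mhn_to_san(matrix(theta, 1, 1)))
    p <- dense_marginal(q, c(1, 0))
    expect_equal(p, c(1 / (1 + theta), theta / (1 + theta)),
                 tolerance = 1e-14)
  }
  # d = 2, all effects neutral: (1/3, 1/6, 1/6, 1/3) over (00, 01, 10, 11)
  q2 <- generator_dense(mhn_to_san(matrix(1, 2, 2)))
  p2 <- dense_marginal(q2, dense_unit(c(2L, 2L)))
  expect_equal(p2, c(1 / 3, 1 / 6, 1 / 6, 1 / 3), tolerance = 1e-14)
  expect_equal(sum(p2), 1, tolerance = 1e-14)
  expect_true(all(p2 >= 0))
})

test_that("splitting solver reproduces the direct solve on progressive chains", {
  for (seed in 1:8) {
    set.seed(seed)
    d <- sample(1:5, 1L)
    theta <- matrix(exp(rnorm(d * d, 0, 0.4)), d, d)
    q <- generator_dense(mhn_to_san(theta))
    p0 <- dense_unit(rep(2L, d))
    expect_equal(dense_splitting_marginal(q, p0), dense_marginal(q, p0),
                 tolerance = 1e-10)
  }
})

test_that("splitting solver rejects non-progressive chains", {
  # a reversible 1-automaton network (0 -> 1 and 1 -> 0)
  spec <- san_spec(
    sizes = c(2L, 2L),
    transitions = list(
      list(list(from = 0L, to = 1L, effects = list(c(1, 1), c(1, 1))),
           list(from = 1L, to = 0L, effects = list(c(1, 1), c(1, 1)))),
      list()))
  q <- generator_dense(spec)
  expect_error(dense_splitting_marginal(q, dense_unit(c(2L, 2L))),
               "not progressive")
  expect_error(dense_splitting_marginal(matrix(0, 3, 3), numeric(3)),
               "2\\^d")
})

test_that("partial-sum mass follows the closed form", {
  expect_equal(partial_sum_mass(0, 0.7), 1)
  expect_equal(partial_sum_mass(1, 1), 3 / 2)
  expect_equal(partial_sum_mass(1, 2), 5 / 3)
  # closed form equals the printed expression at moderate k
  for (gamma in c(0.5, 1, 4)) {
    for (k in c(0, 3, 10)) {
      expect_equal(partial_sum_mass(k, gamma),
                   ((1 + gamma)^(k + 1) - gamma^(k + 1)) / (1 + gamma)^k,
                   tolerance = 1e-13)
    }
  }
  # no overflow at large k
  expect_equal(partial_sum_mass(5000, 50), 51, tolerance = 1e-12)
})

test_that("uniformization partial sums converge and respect the mass identity", {
  set.seed(3)
  theta <- matrix(exp(rnorm(9, 0, 0.3)), 3, 3)
  spec <- mhn_to_san(theta)
  q <- generator_dense(spec)
  gamma <- gamma_bound(spec)
  p0 <- dense_unit(rep(2L, 3))
  p <- dense_marginal(q, p0)

  ns <- neumann_partial_sums(q, p0, k = 60, gamma = gamma)
  # p^(0) = p(0)
  expect_equal(ns$pnorm[, 1], p0, tolerance = 1e-14)
  # normalized iterates have mass one, exactly
  expect_equal(colSums(ns$pnorm), rep(1, 61), tolerance = 1e-12)
  # the (1 + gamma)-scaled masses match the closed form exactly
  expect_equal(ns$masses,
               vapply(0:60, partial_sum_mass, numeric(1), gamma = gamma),
               tolerance = 1e-12)
  # approximation from below, entrywise nondecreasing
  expect_true(all(ns$ptilde <= p + 1e-12))
  expect_true(all(diff(t(ns$ptilde)) >= -1e-14))

  # single automaton, k = 50: geometric series reaches (1/2, 1/2)
  q1 <- generator_dense(mhn_to_san(matrix(1, 1, 1)))
  ns1 <- neumann_partial_sums(q1, c(1, 0), k = 50, gamma = 1)
  expect_equal(ns1$pnorm[, 51], c(0.5, 0.5), tolerance = 1e-10)
})

test_that("upper approximation brackets the marginal distribution", {
  # deficit at k = 0, gamma = 1 is 1/2
  expect_equal(upper_approx(c(0, 0), 0, 1), c(0.5, 0.5))

  q1 <- generator_dense(mhn_to_san(matrix(1, 1, 1)))
  ns <- neumann_partial_sums(q1, c(1, 0), k = 3, gamma = 1)
  p <- dense_marginal(q1, c(1, 0))
  ph <- upper_approx(ns$ptilde[, 4], 3, 1)
  expect_true(all(ns$ptilde[, 4] <= p + 1e-14))
  expect_true(all(ph >= p - 1e-14))

  set.seed(4)
  theta <- matrix(exp(rnorm(9, 0, 0.3)), 3, 3)
  spec <- mhn_to_san(theta)
  q <- generator_dense(spec)
  g <- gamma_bound(spec)
  ns3 <- neumann_partial_sums(q, dense_unit(rep(2L, 3)), k = 8, gamma = g)
  p3 <- dense_marginal(q, dense_unit(rep(2L, 3)))
  ph3 <- upper_approx(ns3$ptilde[, 9], 8, g)
  expect_true(all(ns3$ptilde[, 9] <= p3 + 1e-12))
  expect_true(all(ph3 >= p3 - 1e-12))

  # ht variant adds the constant shift
  e <- ht_unit(c(0L, 0L), c(2L, 2L))
  up <- upper_approx(e, 1, 1)
  expect_equal(ht_to_vec(up), ht_to_vec(e) + 0.25, tolerance = 1e-12)
})

test_that("relative residual agrees between dense and low-rank evaluation", {
  # p = p(0) at d = 1, theta = 1: residual ||(-Q) p0|| = sqrt(2)
  q1 <- generator_dense(mhn_to_san(matrix(1, 1, 1)))
  expect_equal(relative_residual(q1, c(1, 0), c(1, 0)), sqrt(2),
               tolerance = 1e-12)

  for (seed in 11:13) {
    set.seed(seed)
    theta <- matrix(exp(rnorm(36, 0, 0.25)), 6, 6)
    spec <- mhn_to_san(theta)
    qd <- generator_dense(spec)
    qcp <- build_generator_cp(spec)
    p0v <- dense_unit(rep(2L, 6))
    pv <- dense_marginal(qd, p0v)
    # exact solution embedded in HT: residual numerically zero
    fit <- marginal_lowrank(theta, tol = 1e-5, check_every = 5)
    p0h <- ht_unit(rep(0L, 6), rep(2L, 6))
    rr_lr <- relative_residual(qcp, fit$p, p0h, trunc_control(1e-10))
    rr_dn <- relative_residual(qd, ht_to_vec(fit$p), p0v)
    expect_lt(abs(rr_lr - rr_dn), 1e-6)
  }

  # exact dense solution, re-expressed exactly as an (untruncated) CP sum,
  # has residual at round-off level
  set.seed(14)
  theta3 <- matrix(exp(rnorm(9, 0, 0.3)), 3, 3)
  spec3 <- mhn_to_san(theta3)
  qd3 <- generator_dense(spec3)
  p3 <- dense_marginal(qd3, dense_unit(rep(2L, 3)))
  expect_lt(relative_residual(qd3, p3, dense_unit(rep(2L, 3))), 1e-8)
})

test_that("theorem envelope bounds the normalized iterates", {
  set.seed(21)
  theta <- matrix(exp(rnorm(16, 0, 0.3)), 4, 4)
  spec <- mhn_to_san(theta)
  q <- generator_dense(spec)
  gamma <- gamma_bound(spec)
  p0 <- dense_unit(rep(2L, 4))
  p <- dense_marginal(q, p0)
  cb <- convergence_bound(gamma, p, p0)
  expect_gt(cb$rate, 0); expect_lt(cb$rate, 1)
  ns <- neumann_partial_sums(q, p0, k = 120, gamma = gamma)
  for (k in 0:120) {
    err <- sqrt(sum((ns$pnorm[, k + 1] - p)^2))
    expect_lte(err, cb$constant * cb$rate^k + 1e-13)
  }
})

test_that("low-rank solver matches closed forms and keeps mass one", {
  fit <- marginal_lowrank(matrix(1, 1, 1), tol = 1e-6)
  expect_equal(ht_to_vec(fit$p), c(0.5, 0.5), tolerance = 1e-5)
  expect_true(fit$converged)

  for (seed in 31:35) {
    set.seed(seed)
    d <- sample(2:6, 1L)
    theta <- matrix(exp(rnorm(d * d, 0, 0.25)), d, d)
    fit <- marginal_lowrank(theta, tol = 1e-5, check_every = 5)
    pd <- dense_marginal(generator_dense(mhn_to_san(theta)),
                         dense_unit(rep(2L, d)))
    expect_lt(sqrt(sum((ht_to_vec(fit$p) - pd)^2)) / sqrt(sum(pd^2)), 1e-4)
    mass <- ht_inner(ht_ones(rep(2L, d)), fit$p)
    expect_equal(mass, 1, tolerance = 1e-12)
    expect_true(fit$converged)
    expect_true(all(diff(fit$history$mass) >= -1e-6))  # masses climb to 1
  }
})

test_that("solver reports non-convergence at the iteration cap", {
  set.seed(41)
  theta <- matrix(exp(rnorm(16, 0, 0.25)), 4, 4)
  expect_warning(
    fit <- marginal_lowrank(theta, tol = 1e-10, max_iter = 5),
    "max_iter")
  expect_false(fit$converged)
  expect_identical(fit$iterations, 5L)
})

test_that("fit methods expose the distribution consistently", {
  set.seed(51)
  theta <- matrix(exp(rnorm(16, 0, 0.25)), 4, 4)
  fit <- marginal_lowrank(theta, tol = 1e-5, check_every = 5)
  pd <- dense_marginal(generator_dense(mhn_to_san(theta)),
                       dense_unit(rep(2L, 4)))
  states <- all_states(rep(2L, 4))
  pr <- predict(fit, states)
  expect_equal(pr, pd, tolerance = 1e-4)
  expect_output(print(fit), "converged")
  s <- summary(fit)
  expect_equal(s$mass, 1, tolerance = 1e-12)
  expect_output(print(s), "effective rank")
  expect_true(all(residuals(fit) >= 0))
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_identical(dim(sim), c(50L, 4L))
  expect_true(all(sim %in% 0:1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
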