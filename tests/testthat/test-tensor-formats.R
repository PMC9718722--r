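test_that("matricization follows the declared index convention", {
  B <- array(0, c(2, 2, 2))
  for (x1 in 0:1) B[x1 + 1, , ] <- x1
  M <- matricize(B, 1L)
  expect_equal(M[1, ], rep(0, 4))
  expect_equal(M[2, ], rep(1, 4))

  # t = all modes: identity reshaping
  set.seed(1)
  A <- array(rnorm(24), c(2, 3, 4))
  expect_equal(as.vector(matricize(A, 1:3)), as.vector(A))

  # brute-force index arithmetic for t = {2}
  M2 <- matricize(A, 2L)
  for (x1 in 1:2) for (x2 in 1:3) for (x3 in 1:4) {
    row <- x2
    col <- x1 + (x3 - 1) * 2   # complement (1, 3), mode 1 fastest
    expect_equal(M2[row, col], A[x1, x2, x3])
  }
  expect_error(matricize(A, integer(0)), "nonempty")
})

test_that("CP to HT conversion preserves entries and bounds ranks", {
  dims <- c(2L, 3L, 2L, 2L)
  set.seed(7)
  fac <- lapply(dims, function(n) matrix(rnorm(n * 3), n, 3))
  x <- cp_to_ht(cp_tensor(dims, fac))
  expect_true(all(ht_ranks(x)[-1L] <= 3L))
  expect_equal(ht_to_vec(x), dense_cp_vec(fac), tolerance = 1e-12)

  # rank-1 CP: every node rank 1
  f1 <- lapply(dims, function(n) matrix(rnorm(n), n, 1))
  expect_true(all(ht_ranks(cp_to_ht(cp_tensor(dims, f1))) == 1L))

  # unit tensor: rank-1 with canonical unit entries
  e <- ht_unit(c(1L, 0L, 1L), c(2L, 2L, 2L))
  v <- ht_to_vec(e)
  expect_equal(v[state_index(c(1, 0, 1), c(2, 2, 2))], 1)
  expect_equal(sum(v != 0), 1L)
})

test_that("dense reconstruction, single entries and ones agree", {
  x <- rand_ht(c(2L, 3L, 2L, 2L), seed = 11)
  v <- ht_to_vec(x)
  A <- ht_to_dense(x)
  expect_equal(dim(A), c(2L, 3L, 2L, 2L))
  set.seed(2)
  for (k in 1:20) {
    s <- vapply(x$dims, function(n) sample.int(n, 1L) - 1L, integer(1L))
    expect_equal(ht_entry(x, s), v[state_index(s, x$dims)],
                 tolerance = 1e-12)
    expect_equal(A[matrix(s + 1L, 1L)], v[state_index(s, x$dims)],
                 tolerance = 1e-12)
  }
  ones <- ht_ones(c(2L, 2L, 2L))
  expect_equal(ht_to_vec(ones), rep(1, 8))
})

test_that("dense reconstruction respects non-identity leaf orders", {
  dims <- c(2L, 3L, 4L)
  set.seed(5)
  fac <- lapply(dims, function(n) matrix(rnorm(n * 2), n, 2))
  oracle <- dense_cp_vec(fac)
  for (ord in list(c(2L, 1L, 3L), c(3L, 2L, 1L), c(2L, 3L, 1L))) {
    x <- cp_to_ht(cp_tensor(dims, fac), balanced_tree(3, ord))
    expect_equal(ht_to_vec(x), oracle, tolerance = 1e-12)
    expect_equal(ht_entry(x, c(1L, 2L, 3L)),
                 oracle[state_index(c(1, 2, 3), dims)], tolerance = 1e-12)
  }
})

test_that("addition, scaling and inner products match dense arithmetic", {
  dims <- c(2L, 2L, 3L, 2L)
  x <- rand_ht(dims, seed = 21)
  y <- rand_ht(dims, seed = 22)
  vx <- ht_to_vec(x); vy <- ht_to_vec(y)

  z <- ht_add(x, y, a = 2, b = -0.5)
  expect_equal(ht_to_vec(z), 2 * vx - 0.5 * vy, tolerance = 1e-12)
  expect_true(all(ht_ranks(z) <= ht_ranks(x) + ht_ranks(y)))

  expect_equal(ht_inner(x, y), sum(vx * vy), tolerance = 1e-10)
  expect_equal(ht_norm(x), sqrt(sum(vx^2)), tolerance = 1e-10)

  # x + (-1) x vanishes
  expect_lt(ht_norm(ht_add(x, x, 1, -1)), 1e-12 * ht_norm(x))

  # <ones, e_z> = 1
  expect_equal(ht_inner(ht_ones(dims), ht_unit(c(0L, 1L, 2L, 0L), dims)), 1)
})

test_that("orthogonalization preserves the tensor and orthonormalizes nodes", {
  x <- rand_ht(c(2L, 2L, 2L, 3L), seed = 31)
  xo <- ht_orthogonalize(x)
  expect_equal(ht_to_vec(xo), ht_to_vec(x), tolerance = 1e-10)
  tr <- xo$tree
  for (t in 2:tr$nnodes) {
    M <- if (tr$left[t] == 0L) xo$data[[t]]
         else matrix(xo$data[[t]], ncol = dim(xo$data[[t]])[3L])
    expect_equal(crossprod(M), diag(1, ncol(M)), tolerance = 1e-12)
  }
})

test_that("node singular values match dense matricization SVDs", {
  x <- rand_ht(c(2L, 2L, 2L, 2L), seed = 41)
  sv <- node_singular_values(x)
  A <- ht_to_dense(x)
  tr <- x$tree
  for (t in 2:tr$nnodes) {
    ref <- svd(matricize(A, tr$modes[[t]]), nu = 0, nv = 0)$d
    got <- sv[[t]]
    # the representation carries at most r_t values; the dense spectrum
    # beyond that is exactly zero
    n <- min(length(got), length(ref))
    expect_equal(got[1:n], ref[1:n], tolerance = 1e-8)
    if (length(ref) > n) expect_true(all(abs(ref[-(1:n)]) < 1e-10))
  }
  expect_equal(sv[[1L]], sqrt(sum(A^2)), tolerance = 1e-10)
  # siblings under the root share their spectrum
  l <- sv[[tr$left[1L]]]; r <- sv[[tr$right[1L]]]
  n <- min(length(l), length(r))
  expect_equal(l[1:n], r[1:n], tolerance = 1e-10)

  # rank-1 tensor: a single nonzero value equal to the norm at every node
  e <- ht_unit(c(0L, 0L, 1L), c(2L, 2L, 2L))
  sve <- node_singular_values(ht_scale(e, 3))
  for (t in seq_along(sve)) {
    expect_equal(sve[[t]][1L], 3, tolerance = 1e-12)
    expect_true(all(abs(sve[[t]][-1L]) < 1e-12))
  }
})

test_that("truncation is lossless at eps 0 and obeys the error bound", {
  x <- rand_ht(c(2L, 3L, 2L, 2L), seed = 51)
  v <- ht_to_vec(x)

  expect_equal(ht_to_vec(ht_truncate(x, trunc_control(0))), v,
               tolerance = 1e-10)

  e <- ht_unit(c(0L, 1L, 0L, 1L), c(2L, 3L, 2L, 2L))
  et <- ht_truncate(e, trunc_control(0.5))
  expect_equal(ht_to_vec(et), ht_to_vec(e), tolerance = 1e-12)

  # discarded-singular-value bound, dense SVD oracle on the input tensor
  for (seed in 52:71) {
    y <- rand_ht(c(2L, 2L, 3L, 2L), seed = seed, max_rank = 5L)
    vy <- ht_to_vec(y)
    eps <- 10^runif(1, -8, -0.5)
    yt <- ht_truncate(y, trunc_control(eps))
    err2 <- sum((ht_to_vec(yt) - vy)^2)
    rk <- ht_ranks(yt)
    bound <- 0
    for (t in 2:y$tree$nnodes) {
      sv <- svd(matricize(vy, y$tree$modes[[t]], dims = y$dims),
                nu = 0, nv = 0)$d
      if (rk[t] < length(sv))
        bound <- bound + sum(sv[(rk[t] + 1L):length(sv)]^2)
    }
    expect_lte(err2, bound + 1e-12 * sum(vy^2))
    # and the requested relative accuracy was met
    expect_lte(sqrt(err2), eps * sqrt(sum(vy^2)) * (1 + 1e-10))
  }

  # rank caps are honored
  z <- rand_ht(c(2L, 2L, 2L, 2L), seed = 99, max_rank = 4L)
  zt <- ht_truncate(z, trunc_control(0, max_rank = 2L))
  expect_true(all(ht_ranks(zt) <= 2L))
})

test_that("operator application agrees with the dense product", {
  # identity operator leaves entries unchanged
  dims <- c(2L, 2L, 2L)
  x <- rand_ht(dims, seed = 61)
  idop <- cp_operator(dims, list(lapply(dims, function(n) diag(1, n))))
  expect_equal(ht_to_vec(apply_cp_operator(idop, x)), ht_to_vec(x),
               tolerance = 1e-10)

  # d = 3 MHN generator applied to e_000 equals the dense Q p(0)
  set.seed(62)
  spec <- mhn_to_san(matrix(exp(rnorm(9, 0, 0.3)), 3, 3))
  q <- build_generator_cp(spec)
  p0 <- ht_unit(c(0L, 0L, 0L), dims)
  for (mode in c("incremental", "batch")) {
    got <- ht_to_vec(apply_cp_operator(q, p0, mode = mode))
    expect_equal(got, as.vector(generator_dense(spec) %*% dense_unit(dims)),
                 tolerance = 1e-10)
  }

  # rank growth without truncation stays below r_a * r_x nodewise
  y <- rand_ht(dims, seed = 63, max_rank = 2L)
  exact <- apply_cp_operator(q, y, mode = "batch", truncate = FALSE)
  expect_true(all(ht_ranks(exact) <= q$rank * ht_ranks(y)))
  expect_equal(ht_to_vec(exact),
               as.vector(cp_operator_dense(q) %*% ht_to_vec(y)),
               tolerance = 1e-10)
})

test_that("storage counts follow the leaf/transfer formula", {
  x <- rand_ht(c(2L, 2L, 2L, 2L), seed = 71)
  rk <- ht_ranks(x)
  tr <- x$tree
  expected <- 0
  for (t in seq_len(tr$nnodes)) {
    expected <- expected +
      if (tr$left[t] == 0L) 2 * rk[t]
      else rk[tr$left[t]] * rk[tr$right[t]] * rk[t]
  }
  expect_equal(ht_storage(x), expected)
})
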