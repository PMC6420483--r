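test_that("detrending removes polynomial drifts and flags empty residuals", {
  Tt <- 100
  ramp <- matrix(rep(seq_len(Tt), each = 3), 3, Tt, byrow = FALSE)
  ts <- timeseries_matrix(ramp * c(1, -2, 0.5), subject_id = "s")
  expect_warning(out <- clean_timeseries(ts, detrend_order = 1L),
                 "zero residual variance")
  expect_true(all(out$values == 0))
  expect_equal(attr(out, "flagged"), 1:3)
})

test_that("residuals are orthogonal to nuisance regressors and standardized", {
  set.seed(42)
  Tt <- 200
  nuis <- cbind(rnorm(Tt), rnorm(Tt))
  X <- matrix(rnorm(6 * Tt), 6, Tt)
  out <- clean_timeseries(timeseries_matrix(X), nuisance = nuis,
                          detrend_order = 2L)
  expect_lt(max(abs(out$values %*% nuis)), 1e-8)
  expect_equal(rowMeans(out$values), rep(0, 6), tolerance = 1e-8)
  expect_equal(apply(out$values, 1, sd), rep(1, 6), tolerance = 1e-8)
})

test_that("a signal contaminated by a known nuisance series is recovered", {
  set.seed(7)
  Tt <- 500
  signal <- rnorm(Tt)
  nuis <- matrix(rnorm(Tt), ncol = 1)
  contaminated <- signal + 0.5 * nuis[, 1]
  out <- clean_timeseries(timeseries_matrix(rbind(contaminated)),
                          nuisance = nuis, detrend_order = 0L)
  expect_gt(cor(out$values[1, ], signal), 0.999)
})

test_that("graph smoothing: identity at sigma 0, exact kernel on a path", {
  g <- path_graph(9)
  set.seed(1)
  X <- matrix(rnorm(9 * 5), 9, 5)
  ts <- timeseries_matrix(X)
  expect_identical(smooth_on_graph(ts, g, 0), ts)

  # constant field is unchanged (rows sum to 1)
  cts <- timeseries_matrix(matrix(3.5, 9, 4))
  expect_equal(smooth_on_graph(cts, g, 2)$values, matrix(3.5, 9, 4))

  # unit impulse at the center vertex, sigma = 1, truncation at 3 sigma:
  # interior rows see distances 0..3 on both sides, so each row shares the
  # denominator w0 + 2(w1 + w2 + w3) and picks the weight of its distance
  imp <- timeseries_matrix(matrix(as.numeric(seq_len(9) == 5), 9, 1))
  sm <- smooth_on_graph(imp, g, 1)
  w <- exp(-(0:3)^2 / 2)
  full <- w[1] + 2 * sum(w[2:4])
  expect_equal(sm$values[5, 1], w[1] / full, tolerance = 1e-12)
  expect_equal(sm$values[4, 1], w[2] / full, tolerance = 1e-12)
  expect_equal(sm$values[6, 1], w[2] / full, tolerance = 1e-12)
  # rows nearer the path boundary lose kernel mass on one side
  expect_equal(sm$values[3, 1], w[3] / (w[1] + 2 * w[2] + 2 * w[3] + w[4]),
               tolerance = 1e-12)
  expect_equal(sm$values[2, 1], w[4] / (w[1] + 2 * w[2] + w[3] + w[4]),
               tolerance = 1e-12)
  expect_equal(sm$values[1, 1], 0)  # beyond 3 sigma of the impulse
})

test_that("smoothing is a convex combination: bounded by the input range", {
  g <- make_geometry(16, 4)
  set.seed(2)
  X <- matrix(rnorm(g$n_vertices * 3), g$n_vertices, 3)
  sm <- smooth_on_graph(timeseries_matrix(X), g, 2)
  for (j in 1:3) {
    expect_lte(max(sm$values[, j]), max(X[, j]) + 1e-12)
    expect_gte(min(sm$values[, j]), min(X[, j]) - 1e-12)
  }
})

test_that("incremental group PCA is exact when nothing is truncated", {
  set.seed(3)
  V <- 40
  # single subject, full dimension: same subspace as its own PCA
  X <- matrix(rnorm(V * 15), V, 15)
  g1 <- migp_reduce(list(timeseries_matrix(X)), internal_dim = 15)
  expect_lt(max_principal_angle(g1$values, svd(X)$u), 1e-8)

  # three subjects, internal_dim >= total timepoints: equals the PCA of
  # the temporal concatenation
  subs <- lapply(1:3, function(i)
    timeseries_matrix(matrix(rnorm(V * 10), V, 10), subject_id = i))
  gc <- migp_reduce(subs, internal_dim = 30, subject_order_seed = 4)
  concat <- do.call(cbind, lapply(subs, `[[`, "values"))
  expect_lt(max_principal_angle(gc$values, svd(concat)$u), 1e-6)
})

test_that("incremental group PCA recovers shared low-rank structure exactly", {
  set.seed(4)
  V <- 50
  L <- matrix(rnorm(V * 3), V, 3)     # shared rank-3 vertex subspace
  subs <- lapply(1:3, function(i)
    timeseries_matrix(L %*% matrix(rnorm(3 * 20), 3, 20), subject_id = i))
  g3 <- migp_reduce(subs, internal_dim = 3, subject_order_seed = 1)
  concat <- do.call(cbind, lapply(subs, `[[`, "values"))
  full <- svd(concat)$u[, 1:3]
  expect_lt(max_principal_angle(g3$values, full), 1e-6)
})

test_that("migp caps an oversized internal dimension with a warning", {
  set.seed(5)
  subs <- list(timeseries_matrix(matrix(rnorm(200), 20, 10)))
  expect_warning(g <- migp_reduce(subs, internal_dim = 99), "capped")
  expect_equal(ncol(g$values), 10)
})

test_that("dense connectome handles perfect correlation and zero variance", {
  base <- sin(seq_len(50))
  X <- rbind(base, 2 * base + 5, -base, rnorm(50))
  cn <- dense_connectome(timeseries_matrix(X))
  expect_equal(cn$values[1, 2], 1)
  expect_equal(cn$values[1, 3], -1)

  Xz <- rbind(rnorm(20), rep(1, 20))
  expect_warning(cz <- dense_connectome(timeseries_matrix(Xz)),
                 "zero-variance")
  expect_equal(cz$values[1, 2], 0)
  expect_equal(diag(cz$values), c(1, 1))
})

test_that("connectome invariants hold across random inputs", {
  for (seed in 1:50) {
    set.seed(seed)
    X <- matrix(rnorm(12 * 25), 12, 25)
    cn <- dense_connectome(timeseries_matrix(X))$values
    expect_identical(cn, t(cn))
    expect_equal(diag(cn), rep(1, 12))
    expect_true(all(cn >= -1 - 1e-12 & cn <= 1 + 1e-12))
  }
})
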