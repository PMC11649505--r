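# Spatial/channel attention, dense connections and the cross-attention
# fusion gate.

test_that("attention rows are probability vectors in both attention modes", {
  set.seed(20)
  Q <- matrix(rnorm(12 * 8), 12, 8)
  K <- matrix(rnorm(12 * 8), 12, 8)
  for (transposed in c(FALSE, TRUE)) {
    rows <- hyperseg:::attention_rows(Q, K, n_heads = 2L, transposed = transposed)
    for (A in rows) {
      expect_true(all(A >= 0))
      expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
    }
  }
})

test_that("channel attention similarity is channels-by-channels regardless of N", {
  set.seed(21)
  for (N in c(3L, 16L, 50L)) {
    Q <- matrix(rnorm(N * 8), N, 8)
    rows <- hyperseg:::attention_rows(Q, Q, n_heads = 2L, transposed = TRUE)
    for (A in rows) expect_equal(dim(A), c(4L, 4L))   # d_k = 8/2, independent of N
  }
})

test_that("scaled_dot_attention degenerates correctly", {
  set.seed(22)
  V <- matrix(rnorm(6 * 4), 6, 4)
  # zero Q, K: uniform attention -> every output row is the mean row of V
  out <- scaled_dot_attention(matrix(0, 6, 4), matrix(0, 6, 4), V, n_heads = 1L)
  expect_equal(out, matrix(colMeans(V), 6, 4, byrow = TRUE), tolerance = 1e-9)
  # single token: softmax over one element is 1, output == V
  v1 <- matrix(rnorm(4), 1, 4)
  expect_equal(scaled_dot_attention(v1 * 2, v1, v1, n_heads = 2L), v1)
})

test_that("spatial attention is permutation-equivariant", {
  set.seed(23)
  X <- matrix(rnorm(10 * 8), 10, 8)
  out <- scaled_dot_attention(X, X, X, n_heads = 2L)
  perm <- sample(10L)
  out_p <- scaled_dot_attention(X[perm, ], X[perm, ], X[perm, ], n_heads = 2L)
  expect_equal(out_p, out[perm, ], tolerance = 1e-9)
})

test_that("dense aggregation sums the full history and is linear", {
  X <- matrix(rnorm(12), 3, 4)
  Y <- matrix(rnorm(12), 3, 4)
  expect_equal(dense_aggregate(list(), shape = c(3, 4)), matrix(0, 3, 4))
  expect_equal(dense_aggregate(list(X)), X)
  expect_equal(dense_aggregate(list(X, Y)), X + Y)
  expect_equal(dense_aggregate(list(2 * X)), 2 * dense_aggregate(list(X)))
})

test_that("caf gate matches its scalar reference and stays inside (0, 2)", {
  expect_equal(caf(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2)),
               matrix(1, 2, 2))
  set.seed(24)
  for (rep in 1:5) {
    F1 <- matrix(rnorm(6, sd = 3), 2, 3)
    F2 <- matrix(rnorm(6, sd = 3), 2, 3)
    Fp <- matrix(rnorm(6, sd = 3), 2, 3)
    got <- caf(F1, F2, Fp)
    expect_lt(max(abs(got - ref_caf(F1, F2, Fp))), 1e-6)
    expect_true(all(got >= 0 & got <= 2))   # saturates to the bounds in floats
  }
  moderate <- caf(matrix(0.5, 2, 2), matrix(-0.3, 2, 2), matrix(0.8, 2, 2))
  expect_true(all(moderate > 0 & moderate < 2))
  expect_error(caf(matrix(0, 2, 2), matrix(0, 2, 3), matrix(0, 2, 2)), "shape")
})

test_that("scformer blocks preserve shape, grow history and stack densely", {
  set.seed(25)
  cfg <- hyperseg:::scf_config(8L, n_heads = 2L, n_blocks = 3L)
  mod <- hyperseg:::scf_init(cfg)
  tn_new <- hyperseg:::tn_new
  x <- tn_new(matrix(rnorm(9 * 8), 9, 8))

  res1 <- hyperseg:::tn_scf_block(mod$blocks[[1]], x, list(), x, cfg)
  expect_equal(dim(res1$out$v), c(9L, 8L))
  expect_length(res1$history, 1L)
  res2 <- hyperseg:::tn_scf_block(mod$blocks[[2]], res1$out, res1$history, res1$out, cfg)
  expect_length(res2$history, 2L)

  out <- hyperseg:::tn_scf_stack(mod, x)
  expect_equal(dim(out$v), c(9L, 8L))
  expect_identical(out$v, hyperseg:::tn_scf_stack(mod, x)$v)  # deterministic

  # block 3's dense path sees the sum of blocks 1 and 2
  s <- hyperseg:::tn_dense_sum(res2$history, c(9, 8))
  expect_equal(s$v, res1$out$v + res2$out$v)

  # single-block stack and the pure-linear ("no prenorm") reading also run
  cfg1 <- hyperseg:::scf_config(8L, n_heads = 2L, n_blocks = 1L, prenorm = FALSE)
  mod1 <- hyperseg:::scf_init(cfg1)
  expect_equal(dim(hyperseg:::tn_scf_stack(mod1, x)$v), c(9L, 8L))
})

test_that("first-block channel attention reduces to plain channel self-attention", {
  set.seed(26)
  cfg <- hyperseg:::scf_config(8L, n_heads = 2L, n_blocks = 1L, prenorm = FALSE)
  mod <- hyperseg:::scf_init(cfg)
  x <- hyperseg:::tn_new(matrix(rnorm(5 * 8), 5, 8))
  got <- hyperseg:::tn_mca(mod$blocks[[1]], x, list(), cfg)
  # direct construction: Q, K, V all from x through the same projections
  blk <- mod$blocks[[1]]
  lin <- function(l, m) sweep(m %*% l$w$v, 2, l$b$v, "+")
  direct <- scaled_dot_attention(lin(blk$mca$wq, x$v), lin(blk$mca$wk, x$v),
                                 lin(blk$mca$wv, x$v), n_heads = 2L,
                                 transposed = TRUE)
  direct <- lin(blk$mca$wo, direct)
  expect_equal(got$v, direct, tolerance = 1e-9)
})

test_that("mlp is deterministic without dropout and zero under zero weights", {
  set.seed(27)
  cfg <- hyperseg:::scf_config(8L, n_heads = 2L, n_blocks = 1L, dropout = 0)
  blk <- hyperseg:::scf_block_init(cfg, FALSE)
  x <- hyperseg:::tn_new(matrix(rnorm(6 * 8), 6, 8))
  y1 <- hyperseg:::tn_mlp(blk, x, cfg, train = TRUE)
  y2 <- hyperseg:::tn_mlp(blk, x, cfg, train = TRUE)
  expect_identical(y1$v, y2$v)
  expect_equal(dim(y1$v), dim(x$v))
  for (l in list(blk$mlp$fc1, blk$mlp$fc2)) { l$w$v[] <- 0; l$b$v[] <- 0 }
  expect_true(all(hyperseg:::tn_mlp(blk, x, cfg, train = FALSE)$v == 0))
})
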