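# Global attention block: stage-by-stage contracts against loop oracles,
# the residual identity, and parameter accounting.

test_that("projection flattens row-major and applies linear1", {
  # identity-like weights: C' = C = 3, identity weight, zero bias
  cfg <- gattn_config(embed_dim = 3L)
  p <- zero_gattn_params(3L, cfg)
  p$linear1$w <- diag(3)
  x <- rand_feature(2, 2, 3, seed = 4)
  z <- gattn_project(x, p)
  # row k is pixel (k %/% W, k %% W), h-major
  expect_equal(z[1, ], x[1, 1, ])
  expect_equal(z[2, ], x[1, 2, ])
  expect_equal(z[3, ], x[2, 1, ])
  expect_equal(z[4, ], x[2, 2, ])

  # all-zero weights and biases give an all-zero embedding
  expect_equal(gattn_project(x, zero_gattn_params(3L, cfg)),
               matrix(0, 4, 3))
})

test_that("projection matches a loop-based matrix-product oracle", {
  set.seed(11)
  cfg <- gattn_config(embed_dim = 4L, seed = 11)
  p <- gattn_init(8L, cfg)
  x <- rand_feature(4, 4, 8, seed = 12)
  z <- gattn_project(x, p)
  xf <- matrix(0, 16, 8)
  for (h in 1:4) for (w in 1:4) xf[(h - 1) * 4 + w, ] <- x[h, w, ]
  expected <- oracle_matmul(xf, p$linear1$w)
  for (i in 1:16) expected[i, ] <- expected[i, ] + p$linear1$b
  expect_equal(z, expected, tolerance = 1e-12)
})

test_that("projection rejects channel mismatches", {
  cfg <- gattn_config(embed_dim = 2L)
  p <- gattn_init(4L, cfg)
  expect_error(gattn_project(rand_feature(2, 2, 3), p), "channels")
})

test_that("query/key/value chunking partitions linear2 output contiguously", {
  cfg <- gattn_config(embed_dim = 2L)
  p <- zero_gattn_params(4L, cfg)
  # zero weights, bias = three distinct constants -> constant chunks
  p$linear2$b <- c(1, 1, 2, 2, 3, 3)
  z <- matrix(rnorm(10), 5, 2)
  qkv <- gattn_qkv(z, p)
  expect_equal(qkv$M1, matrix(1, 5, 2))
  expect_equal(qkv$M2, matrix(2, 5, 2))
  expect_equal(qkv$M3, matrix(3, 5, 2))

  # C'=1, H*W=2: hand-multiplied 1->3 weights
  p1 <- zero_gattn_params(1L, gattn_config(embed_dim = 1L))
  p1$linear2$w <- matrix(c(2, -1, 0.5), 1, 3)
  z1 <- matrix(c(3, -4), 2, 1)
  qkv1 <- gattn_qkv(z1, p1)
  expect_equal(qkv1$M1, matrix(c(6, -8), 2, 1))
  expect_equal(qkv1$M2, matrix(c(-3, 4), 2, 1))
  expect_equal(qkv1$M3, matrix(c(1.5, -2), 2, 1))

  # identity-ish weights on the first C' columns: M1 = Z, M2 = M3 = bias
  p2 <- zero_gattn_params(4L, cfg)
  p2$linear2$w[, 1:2] <- diag(2)
  qkv2 <- gattn_qkv(z, p2)
  expect_equal(qkv2$M1, z)
  expect_equal(qkv2$M2, matrix(0, 5, 2))
  expect_equal(qkv2$M3, matrix(0, 5, 2))
})

test_that("affinity is the full pairwise dot-product matrix", {
  expect_equal(gattn_affinity(diag(2), diag(2)), diag(2))
  expect_equal(gattn_affinity(matrix(c(1, 1), 1), matrix(c(2, 3), 1)),
               matrix(5))
  set.seed(21)
  m1 <- matrix(rnorm(12), 4, 3)
  m2 <- matrix(rnorm(12), 4, 3)
  mi <- gattn_affinity(m1, m2)
  expected <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) expected[i, j] <- sum(m1[i, ] * m2[j, ])
  expect_equal(mi, expected, tolerance = 1e-12)
  expect_equal(gattn_affinity(m1, m2, scaling = TRUE),
               expected / sqrt(3), tolerance = 1e-12)
})

test_that("aggregation is a plain matrix product", {
  set.seed(22)
  m3 <- matrix(rnorm(8), 4, 2)
  expect_equal(gattn_aggregate(diag(4), m3), m3)
  expect_equal(gattn_aggregate(matrix(0, 4, 4), m3), matrix(0, 4, 2))
  mi <- matrix(rnorm(16), 4, 4)
  expect_equal(gattn_aggregate(mi, m3), oracle_matmul(mi, m3),
               tolerance = 1e-12)
})

test_that("MLP recalibration is linear-relu-linear with shape inversion", {
  cfg <- gattn_config(embed_dim = 2L)
  pz <- zero_gattn_params(3L, cfg)
  mr <- matrix(rnorm(8), 4, 2)
  expect_equal(gattn_recalibrate(mr, pz, 2, 2), array(0, c(2, 2, 2)))

  # identity MLP passes nonnegative input through unchanged
  pid <- zero_gattn_params(3L, cfg)
  pid$mlp1$w <- diag(2); pid$mlp2$w <- diag(2)
  mrn <- matrix(abs(rnorm(8)), 4, 2)
  a <- gattn_recalibrate(mrn, pid, 2, 2)
  expect_equal(a[1, 1, ], mrn[1, ])
  expect_equal(a[1, 2, ], mrn[2, ])
  expect_equal(a[2, 1, ], mrn[3, ])
  expect_equal(a[2, 2, ], mrn[4, ])

  # seeded random MLP against an explicit two-step loop oracle
  set.seed(23)
  p <- gattn_init(3L, gattn_config(embed_dim = 2L, mlp_hidden = 3L))
  mr2 <- matrix(rnorm(8), 4, 2)
  hid <- oracle_matmul(mr2, p$mlp1$w)
  for (i in 1:4) hid[i, ] <- hid[i, ] + p$mlp1$b
  hid[hid < 0] <- 0
  out <- oracle_matmul(hid, p$mlp2$w)
  for (i in 1:4) out[i, ] <- out[i, ] + p$mlp2$b
  a2 <- gattn_recalibrate(mr2, p, 2, 2)
  expect_equal(matrix(aperm(a2, c(2, 1, 3)), 4, 2), out, tolerance = 1e-12)
})

test_that("channel squeeze is the per-pixel mean", {
  expect_equal(gattn_squeeze(array(3, c(2, 2, 4))), array(3, c(2, 2, 1)))
  a <- array(0, c(1, 1, 2)); a[1, 1, ] <- c(1, 3)
  expect_equal(gattn_squeeze(a), array(2, c(1, 1, 1)))
  set.seed(24)
  a2 <- array(rnorm(3 * 4 * 5), c(3, 4, 5))
  sq <- gattn_squeeze(a2)
  for (h in 1:3) for (w in 1:4)
    expect_equal(sq[h, w, 1], mean(a2[h, w, ]))
})

test_that("attention application is residual: (AR + 1) times the input", {
  x <- rand_feature(3, 3, 2, seed = 25)
  expect_equal(gattn_apply(x, array(0, c(3, 3, 1))), x)
  expect_equal(gattn_apply(x, array(1, c(3, 3, 1))), 2 * x)
  x1 <- array(0, c(1, 1, 2)); x1[1, 1, ] <- c(2, 4)
  out <- gattn_apply(x1, array(0.5, c(1, 1, 1)))
  expect_equal(out[1, 1, ], c(3, 6))
  expect_error(gattn_apply(x, array(0, c(2, 3, 1))), "3x3")
})

test_that("zero-parameter attention is an exact identity for any input", {
  for (s in 1:5) {
    h <- sample(1:5, 1); w <- sample(1:5, 1); cc <- sample(1:6, 1)
    cfg <- gattn_config(embed_dim = sample(1:3, 1))
    x <- rand_feature(h, w, cc, seed = 100 + s)
    out <- gattn_forward(x, zero_gattn_params(cc, cfg), cfg)
    expect_identical(out$output, x)
  }
})

test_that("forward pass matches the end-to-end loop oracle on 20 seeded instances", {
  for (s in 1:20) {
    set.seed(3000 + s)
    h <- sample(1:6, 1); w <- sample(1:6, 1)
    cc <- sample(1:8, 1); cp <- sample(1:4, 1)
    scaling <- s %% 2 == 0
    cfg <- gattn_config(embed_dim = cp, affinity_scaling = scaling,
                        seed = 3000 + s)
    p <- gattn_init(cc, cfg)
    x <- rand_feature(h, w, cc, seed = 4000 + s)
    got <- gattn_forward(x, p, cfg)
    want <- oracle_gattn(x, p, scaling = scaling)
    expect_equal(got$output, want$output, tolerance = 1e-5)
    expect_equal(got$trace$MI, want$MI, tolerance = 1e-5)
    expect_equal(got$trace$MR, want$MR, tolerance = 1e-5)
    expect_equal(dim(got$output), dim(x))
  }
})

test_that("degenerate 1x1 inputs reduce gracefully", {
  cfg <- gattn_config(embed_dim = 2L, seed = 9)
  p <- gattn_init(4L, cfg)
  x <- rand_feature(1, 1, 4, seed = 9)
  out <- gattn_forward(x, p, cfg)
  expect_equal(dim(out$trace$MI), c(1L, 1L))
  expect_equal(dim(out$output), c(1L, 1L, 4L))
})

test_that("permuting spatial positions permutes affinity and output consistently", {
  set.seed(31)
  cfg <- gattn_config(embed_dim = 3L, seed = 31)
  p <- gattn_init(4L, cfg)
  h <- 2; w <- 3
  x <- rand_feature(h, w, 4, seed = 32)
  # a permutation of the flattened (row-major) positions
  perm <- sample(h * w)
  xf <- matrix(0, h * w, 4)
  for (hh in 1:h) for (ww in 1:w) xf[(hh - 1) * w + ww, ] <- x[hh, ww, ]
  xpf <- xf[perm, , drop = FALSE]
  xp <- array(0, dim(x))
  for (hh in 1:h) for (ww in 1:w) xp[hh, ww, ] <- xpf[(hh - 1) * w + ww, ]
  a <- gattn_forward(x, p, cfg)
  b <- gattn_forward(xp, p, cfg)
  expect_equal(b$trace$MI, a$trace$MI[perm, perm], tolerance = 1e-10)
  # and the output is the identically permuted output
  of <- matrix(0, h * w, 4); opf <- matrix(0, h * w, 4)
  for (hh in 1:h) for (ww in 1:w) {
    of[(hh - 1) * w + ww, ] <- a$output[hh, ww, ]
    opf[(hh - 1) * w + ww, ] <- b$output[hh, ww, ]
  }
  expect_equal(opf, of[perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("parameter count matches exhaustive weight enumeration", {
  expect_identical(gattn_param_count(1L, gattn_config(1L, 1L)), 12L)
  expect_identical(gattn_param_count(512L, gattn_config(64L, 64L)), 53632L)
  set.seed(41)
  for (i in 1:10) {
    cc <- sample(1:64, 1); cp <- sample(1:16, 1); mh <- sample(1:16, 1)
    cfg <- gattn_config(embed_dim = cp, mlp_hidden = mh, seed = i)
    p <- gattn_init(cc, cfg)
    enum <- length(unlist(p, recursive = TRUE, use.names = FALSE))
    expect_equal(gattn_param_count(cc, cfg), enum)
  }
  # only linear1 depends on the input channel count
  cfg <- gattn_config(embed_dim = 8L)
  expect_equal(gattn_param_count(64L, cfg) - gattn_param_count(32L, cfg),
               32L * 8L)
})

test_that("analytic attention gradients agree with finite differences", {
  set.seed(55)
  cfg <- gattn_config(embed_dim = 2L, seed = 55)
  p <- gattn_init(3L, cfg)
  x <- rand_feature(3, 2, 3, seed = 56)
  fw <- lodgeseg:::gattn_forward_train(x, p, cfg)
  gy <- rand_feature(3, 2, 3, seed = 57)
  bw <- lodgeseg:::gattn_backward(gy, fw$cache)
  loss_at <- function(pp, xx) sum(gattn_forward(xx, pp, cfg)$output * gy)
  eps <- 1e-6
  # input gradient at two positions
  for (idx in list(c(1, 1, 1), c(3, 2, 3))) {
    xp <- x; xp[idx[1], idx[2], idx[3]] <- xp[idx[1], idx[2], idx[3]] + eps
    xm <- x; xm[idx[1], idx[2], idx[3]] <- xm[idx[1], idx[2], idx[3]] - eps
    num <- (loss_at(p, xp) - loss_at(p, xm)) / (2 * eps)
    expect_equal(bw$gx[idx[1], idx[2], idx[3]], num, tolerance = 1e-5)
  }
  # one weight per layer
  for (layer in c("linear1", "linear2", "mlp1", "mlp2")) {
    pp <- p; pm <- p
    pp[[layer]]$w[1, 1] <- pp[[layer]]$w[1, 1] + eps
    pm[[layer]]$w[1, 1] <- pm[[layer]]$w[1, 1] - eps
    num <- (loss_at(pp, x) - loss_at(pm, x)) / (2 * eps)
    expect_equal(bw$grads[[layer]]$w[1, 1], num, tolerance = 1e-5)
  }
})
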