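# Unit tests for the building blocks: self-attention, AAC, gating, SE, ASPP.

make_attn <- function(H, W, C = 5L, heads = 2L, dk = 8L, dv = 8L, seed = 1) {
  set.seed(seed)
  cfg <- aac_config(C, 4L * dv, dk_total = dk, dv_total = dv,
                    num_heads = heads, spatial_shape = c(H, W))
  list(cfg = cfg, proj = new_self_attention(cfg),
       x = array(rnorm(H * W * C * 2), c(H, W, C, 2)))
}

test_that("attention on a single pixel returns the value projection", {
  a <- make_attn(1L, 1L)
  y <- self_attention(a$x, a$cfg, a$proj)
  v <- vapply(seq_len(a$cfg$dv_total), function(co)
    sum(a$x[1, 1, , 1] * a$proj$wv$w$v[1, 1, , co]) + a$proj$wv$b$v[co],
    numeric(1))
  expect_equal(as.vector(y[1, 1, , 1]), v, tolerance = 1e-12)
})

test_that("zero queries and zero relative tables give uniform attention", {
  a <- make_attn(3L, 4L)
  a$proj$wq$w$v[] <- 0; a$proj$wq$b$v[] <- 0
  a$proj$rel_row$v[] <- 0; a$proj$rel_col$v[] <- 0
  y <- self_attention(a$x, a$cfg, a$proj)
  # every query output must equal the spatial mean of the value projections
  vproj <- gaadunet:::nn_conv2d_fw(a$x, a$proj$wv$w$v, a$proj$wv$b$v, 1L)
  mean_v <- apply(vproj, c(3, 4), mean)
  for (n in 1:2) for (c in seq_len(a$cfg$dv_total))
    expect_equal(as.vector(y[, , c, n]), rep(mean_v[c, n], 12), tolerance = 1e-12)
})

test_that("attention weights per query sum to one (all-ones value probe)", {
  for (heads in c(1L, 2L, 4L)) {
    a <- make_attn(4L, 3L, heads = heads, seed = heads)
    a$proj$wv$w$v[] <- 0
    a$proj$wv$b$v[] <- 1       # V == 1 everywhere, so output == row sums
    y <- self_attention(a$x, a$cfg, a$proj)
    expect_equal(as.vector(y), rep(1, length(y)), tolerance = 1e-6)
  }
})

test_that("attention matches the double-loop oracle on random inputs", {
  for (heads in c(1L, 2L, 4L)) {
    a <- make_attn(4L, 4L, heads = heads, seed = 10 + heads)
    expect_equal(self_attention(a$x, a$cfg, a$proj),
                 oracle_attention(a$x, a$cfg, a$proj), tolerance = 1e-5)
  }
})

test_that("relative logits are translation-consistent", {
  set.seed(4)
  H <- 4L; W <- 5L; dkh <- 3L
  Qrow <- rnorm(dkh)
  Qm <- matrix(Qrow, H * W, dkh, byrow = TRUE)   # constant query content
  rr <- matrix(rnorm((2 * H - 1) * dkh), 2 * H - 1, dkh)
  rc <- matrix(rnorm((2 * W - 1) * dkh), 2 * W - 1, dkh)
  Rel <- gaadunet:::att_rel_logits(Qm, rr, rc, H, W)
  idx <- gaadunet:::rel_index_matrices(H, W)
  # pick pairs of (query, key) pairs with identical (row, col) offsets
  off <- paste(idx$IR, idx$IC)
  for (o in sample(unique(off), 10)) {
    vals <- Rel[off == o]
    expect_lt(max(vals) - min(vals), 1e-12)
  }
})

test_that("attention rejects mismatched channels and oversized grids", {
  a <- make_attn(3L, 3L)
  bad <- array(0, c(3, 3, 7, 1))
  expect_error(self_attention(bad, a$cfg, a$proj), "channels")
  big <- array(0, c(5, 5, 5, 1))
  expect_error(self_attention(big, a$cfg, a$proj), "relative embedding")
})

test_that("AAC concatenates conv and attention branches with the right split", {
  set.seed(21)
  cfg <- aac_config(6L, 24L, dk_total = 8L, dv_total = 8L, num_heads = 2L,
                    spatial_shape = c(4L, 4L))
  blk <- new_aac(cfg, post_norm = FALSE)
  x <- array(rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  y <- aac_forward(x, params = blk)
  expect_equal(dim(y), c(4L, 4L, 24L, 2L))
  # branches recomputed independently and concatenated must agree exactly
  conv_branch <- gaadunet:::nn_conv2d_fw(x, blk$conv$w$v, blk$conv$b$v, 1L)
  attn <- self_attention(x, cfg, blk$attn)
  attn_branch <- gaadunet:::nn_conv2d_fw(attn, blk$attn_out$w$v,
                                         blk$attn_out$b$v, 1L)
  expect_equal(y[, , 1:16, ], conv_branch[, , , ], tolerance = 1e-12)
  expect_equal(y[, , 17:24, ], attn_branch[, , , ], tolerance = 1e-12)
})

test_that("AAC with zero input and zero biases returns zero", {
  set.seed(22)
  cfg <- aac_config(4L, 12L, dk_total = 4L, dv_total = 4L, num_heads = 2L,
                    spatial_shape = c(3L, 3L))
  blk <- new_aac(cfg, post_norm = FALSE)
  blk$conv$b$v[] <- 0
  blk$attn$wv$b$v[] <- 0
  blk$attn_out$b$v[] <- 0
  y <- aac_forward(array(0, c(3, 3, 4, 1)), params = blk)
  expect_equal(max(abs(y)), 0)
})

test_that("the attention split cannot consume all output channels", {
  expect_error(aac_config(8L, 32L, dk_total = 32L, dv_total = 32L),
               "dv_total")
})

test_that("gating with zero input returns zero and preserves shape", {
  set.seed(31)
  p <- new_gating(6L)
  x <- array(0, c(5, 4, 6, 2))
  expect_equal(gating_forward(x, p), x)
})

test_that("zero conv2 weights make the gate sigmoid(bias) exactly", {
  set.seed(32)
  p <- new_gating(4L)
  p$conv2$w$v[] <- 0
  x <- array(rnorm(3 * 3 * 4 * 2), c(3, 3, 4, 2))
  for (b in c(0, 0.7)) {
    p$conv2$b$v[] <- b
    expect_equal(gating_forward(x, p), x * (1 / (1 + exp(-b))),
                 tolerance = 1e-12)
  }
})

test_that("gating agrees with the elementwise oracle and is bounded", {
  for (s in 1:5) {
    set.seed(40 + s)
    C <- sample(3:8, 1)
    p <- new_gating(C)
    p$bn$state$mean <- rnorm(max(1, C %/% 2))
    p$bn$state$var <- runif(max(1, C %/% 2), 0.5, 2)
    x <- array(rnorm(4 * 4 * C * 2), c(4, 4, C, 2))
    z <- gating_forward(x, p)
    expect_equal(z, oracle_gating(x, p), tolerance = 1e-10)
    expect_true(all(abs(z) <= abs(x)))
    expect_true(all(sign(z[x != 0]) == sign(x[x != 0])))
  }
})

test_that("odd channel counts fall back to floor(C/2) without crashing", {
  set.seed(33)
  p <- new_gating(5L)
  expect_equal(dim(p$conv1$w$v)[4], 2L)
  x <- array(rnorm(4 * 4 * 5), c(4, 4, 5, 1))
  expect_equal(dim(gating_forward(x, p)), dim(x))
  expect_equal(dim(new_gating(1L)$conv1$w$v)[4], 1L)
})

test_that("SE with zero input returns zero; zero weights scale by 0.5", {
  set.seed(51)
  p <- new_se(8L)
  expect_equal(se_forward(array(0, c(4, 4, 8, 1)), p),
               array(0, c(4, 4, 8, 1)))
  p$fc1$w$v[] <- 0; p$fc1$b$v[] <- 0
  p$fc2$w$v[] <- 0; p$fc2$b$v[] <- 0
  x <- array(rnorm(4 * 4 * 8 * 2), c(4, 4, 8, 2))
  expect_equal(se_forward(x, p), 0.5 * x, tolerance = 1e-12)
})

test_that("SE gates equal the brute-force pool->fc->fc->sigmoid path", {
  set.seed(52)
  p <- new_se(8L, reduction = 4L)
  x <- array(rnorm(5 * 6 * 8 * 3), c(5, 6, 8, 3))
  y <- se_forward(x, p)
  sc <- oracle_se_scales(x, p)
  for (n in 1:3) for (c in 1:8)
    expect_equal(y[, , c, n], x[, , c, n] * sc[c, n], tolerance = 1e-12)
  expect_true(all(sc > 0 & sc < 1))
})

test_that("ASPP preserves constants under averaging kernels", {
  set.seed(61)
  p <- new_aspp(3L, 4L, rates = 1L)
  # averaging weights everywhere, zero biases, identity BN
  p$b1$w$v[] <- 1 / 3; p$b1$b$v[] <- 0
  p$dil[[1]]$w$v[] <- 1 / 27; p$dil[[1]]$b$v[] <- 0
  p$pool$w$v[] <- 1 / 3; p$pool$b$v[] <- 0
  p$proj$w$v[] <- 1 / 12; p$proj$b$v[] <- 0
  x <- array(0.8, c(6, 6, 3, 1))
  y <- aspp_forward(x, p)
  # interior pixels see the full averaging stencil -> exactly the constant
  expect_equal(max(abs(y[3:4, 3:4, , 1] - 0.8)), 0, tolerance = 1e-4)
})

test_that("ASPP has one branch per rate plus 1x1 and image pooling", {
  p <- new_aspp(4L, 6L, rates = c(2L, 5L))
  expect_length(p$dil, 2L)
  expect_equal(dim(p$proj$w$v)[3], (2L + 2L) * 6L)
  expect_error(new_aspp(4L, 6L, rates = c(0L, 2L)), "rates")
})

test_that("dilated branches reproduce the kernel pattern on an impulse", {
  set.seed(62)
  for (r in c(2L, 3L)) {
    w <- array(rnorm(3 * 3 * 1 * 1), c(3, 3, 1, 1))
    x <- array(0, c(9, 9, 1, 1))
    x[5, 5, 1, 1] <- 1
    y <- gaadunet:::nn_conv2d_fw(x, w, 0, r)
    expect_equal(y, oracle_dilated_conv(x, w, 0, r), tolerance = 1e-12)
    # impulse response: flipped kernel at spacing r around the impulse
    for (kh in 1:3) for (kw in 1:3)
      expect_equal(y[5 - (kh - 2) * r, 5 - (kw - 2) * r, 1, 1], w[kh, kw, 1, 1])
  }
})

test_that("blocks preserve batch and spatial dimensions at stride 1", {
  set.seed(71)
  x <- array(rnorm(6 * 4 * 8 * 3), c(6, 4, 8, 3))
  cfg <- aac_config(8L, 16L, dk_total = 4L, dv_total = 4L, num_heads = 2L,
                    spatial_shape = c(6L, 4L))
  expect_equal(dim(aac_forward(x, params = new_aac(cfg)))[c(1, 2, 4)],
               c(6L, 4L, 3L))
  expect_equal(dim(gating_forward(x, new_gating(8L))), dim(x))
  expect_equal(dim(se_forward(x, new_se(8L))), dim(x))
  expect_equal(dim(aspp_forward(x, new_aspp(8L, 5L, c(2L, 3L)))),
               c(6L, 4L, 5L, 3L))
})
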