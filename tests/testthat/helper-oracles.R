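# Independent brute-force oracles used to pin the implementation.

# Explicit double-loop multi-head attention with relative positional terms:
# loops over every (query, key) pixel pair, forms Q.K/sqrt(dk) plus the
# relative row/column offset terms, applies a softmax and sums the values.
oracle_attention <- function(x, cfg, proj) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  heads <- cfg$num_heads
  dkh <- cfg$dk_total / heads
  dvh <- cfg$dv_total / heads
  proj1x1 <- function(l, x) {
    Cout <- dim(l$w$v)[4]
    out <- array(0, c(H, W, Cout, N))
    for (n in 1:N) for (co in 1:Cout) for (i in 1:H) for (j in 1:W)
      out[i, j, co, n] <- sum(x[i, j, , n] * l$w$v[1, 1, , co]) + l$b$v[co]
    out
  }
  Q <- proj1x1(proj$wq, x); K <- proj1x1(proj$wk, x); V <- proj1x1(proj$wv, x)
  y <- array(0, c(H, W, cfg$dv_total, N))
  for (n in 1:N) for (h in 1:heads) {
    qc <- (h - 1) * dkh + 1:dkh
    vc <- (h - 1) * dvh + 1:dvh
    for (qi in 1:H) for (qj in 1:W) {
      logits <- matrix(0, H, W)
      for (ki in 1:H) for (kj in 1:W) {
        l <- sum(Q[qi, qj, qc, n] * K[ki, kj, qc, n])
        if (cfg$relative) {
          rr <- proj$rel_row$v[(ki - qi) + H, , h]
          rc <- proj$rel_col$v[(kj - qj) + W, , h]
          l <- l + sum(Q[qi, qj, qc, n] * (rr + rc))
        }
        logits[ki, kj] <- l / sqrt(dkh)
      }
      p <- exp(logits - max(logits)); p <- p / sum(p)
      acc <- numeric(dvh)
      for (ki in 1:H) for (kj in 1:W) acc <- acc + p[ki, kj] * V[ki, kj, vc, n]
      y[qi, qj, vc, n] <- acc
    }
  }
  y
}

# Elementwise scalar recomputation of the gating formula
# z = x * sigmoid(conv2(relu(bn(conv1(x))))) with 1x1 convs in eval mode.
oracle_gating <- function(x, params) {
  d <- dim(x)
  mid <- dim(params$conv1$w$v)[4]
  z <- array(0, d)
  st <- params$bn$state
  for (n in 1:d[4]) for (i in 1:d[1]) for (j in 1:d[2]) {
    y1 <- numeric(mid)
    for (c in 1:mid)
      y1[c] <- sum(x[i, j, , n] * params$conv1$w$v[1, 1, , c]) + params$conv1$b$v[c]
    y2 <- params$bn$gamma$v * (y1 - st$mean) / sqrt(st$var + 1e-5) + params$bn$beta$v
    y3 <- pmax(0, y2)
    y4 <- numeric(d[3])
    for (c in 1:d[3])
      y4[c] <- sum(y3 * params$conv2$w$v[1, 1, , c]) + params$conv2$b$v[c]
    z[i, j, , n] <- x[i, j, , n] / (1 + exp(-y4))
  }
  z
}

# Scalar-path recomputation of squeeze-and-excitation gates.
oracle_se_scales <- function(x, params) {
  d <- dim(x)
  scales <- matrix(0, d[3], d[4])
  for (n in 1:d[4]) {
    s <- vapply(1:d[3], function(c) mean(x[, , c, n]), numeric(1))
    h <- pmax(0, as.vector(crossprod(params$fc1$w$v, s)) + params$fc1$b$v)
    scales[, n] <- 1 / (1 + exp(-(as.vector(crossprod(params$fc2$w$v, h)) +
                                    params$fc2$b$v)))
  }
  scales
}

# Brute-force dilated same-padded convolution.
oracle_dilated_conv <- function(x, w, b, dil) {
  d <- dim(x); K <- dim(w)[1]; Cout <- dim(w)[4]; half <- (K - 1) / 2
  y <- array(0, c(d[1], d[2], Cout, d[4]))
  for (n in 1:d[4]) for (co in 1:Cout) for (i in 1:d[1]) for (j in 1:d[2]) {
    s <- b[co]
    for (ci in 1:d[3]) for (kh in 1:K) for (kw in 1:K) {
      ii <- i + (kh - 1 - half) * dil; jj <- j + (kw - 1 - half) * dil
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
        s <- s + x[ii, jj, ci, n] * w[kh, kw, ci, co]
    }
    y[i, j, co, n] <- s
  }
  y
}

# Exhaustive pixel-loop confusion counts.
oracle_confusion <- function(pred, gt, k) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] == k; g <- gt[i, j] == k
    if (p && g) tp <- tp + 1L else if (p) fp <- fp + 1L
    else if (g) fn <- fn + 1L else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# All-pairs distance matrix + percentile oracle for the surface metrics.
oracle_surface_metrics <- function(A, B) {
  D <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  dab <- apply(D, 1, min)
  dba <- apply(D, 2, min)
  list(hd95 = max(quantile(dab, 0.95, names = FALSE),
                  quantile(dba, 0.95, names = FALSE)),
       assd = (sum(dab) + sum(dba)) / (nrow(A) + nrow(B)))
}

random_mask <- function(H, W, p = c(0.5, 0.3, 0.2)) {
  matrix(sample(0:2, H * W, TRUE, prob = p), H, W)
}

random_points <- function(n, lim = 40L) {
  unique(cbind(sample.int(lim, n, TRUE) - 1L, sample.int(lim, n, TRUE) - 1L))
}

# A very small model configuration for fast structural tests.
tiny_model_config <- function(input_size = c(16L, 16L), ...) {
  model_config(input_size = input_size,
               encoder1_widths = c(4L, 4L, 6L, 8L),
               encoder2_widths = c(4L, 4L, 6L, 8L),
               decoder_widths = c(6L, 5L, 4L, 4L),
               aac_dk = 4L, aac_dv = 4L, aac_heads = 2L,
               aspp_rates = c(1L, 2L), se_reduction = 2L,
               vgg_convs = c(1L, 1L, 1L, 1L), ...)
}
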