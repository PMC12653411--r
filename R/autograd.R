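# Compact reverse-mode automatic differentiation.
#
# A tensor is an environment holding a numeric array `v`, an accumulated
# gradient `g`, and a `req` flag.  While recording is enabled every operation
# appends a closure to a global tape; ag_backward() replays the tape in
# reverse.  Feature maps are arrays with dim = c(H, W, C, N); vectors and
# matrices are used for per-channel parameters and squeeze-and-excitation
# descriptors.

.ag <- new.env(parent = emptyenv())
.ag$tape <- vector("list", 0L)
.ag$n <- 0L
.ag$recording <- FALSE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
ag_tensor <- function(v, req = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$req <- req
  class(e) <- "ag_tensor"
  e
}

ag_param <- function(v) ag_tensor(v, req = TRUE)

is_ag <- function(x) inherits(x, "ag_tensor")

# Wrap plain arrays so layer forwards accept either representation.
ag_wrap <- function(x) if (is_ag(x)) x else ag_tensor(x)

ag_recording <- function() .ag$recording

ag_set_recording <- function(on) {
  old <- .ag$recording
  .ag$recording <- isTRUE(on)
  invisible(old)
}

ag_reset_tape <- function() {
  .ag$tape <- vector("list", 0L)
  .ag$n <- 0L
  invisible(NULL)
}

# Run expr with the tape enabled; the caller still owns the backward pass.
with_tape <- function(expr) {
  old <- ag_set_recording(TRUE)
  on.exit(ag_set_recording(old), add = TRUE)
  force(expr)
}

ag_record <- function(out, inputs, backward) {
  if (.ag$recording && any(vapply(inputs, function(i) i$req, logical(1)))) {
    out$req <- TRUE
    .ag$n <- .ag$n + 1L
    .ag$tape[[.ag$n]] <- list(out = out, inputs = inputs, backward = backward)
  }
  out
}

ag_accum <- function(node, g) {
  if (!node$req) return(invisible(NULL))
  node$g <- if (is.null(node$g)) g else node$g + g
  invisible(NULL)
}

# Reverse sweep from a scalar loss node; clears the tape afterwards so the
# retained activations can be garbage collected.
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$v) == 1L)
  loss$g <- 1
  if (.ag$n > 0L) {
    for (k in rev(seq_len(.ag$n))) {
      nd <- .ag$tape[[k]]
      if (!is.null(nd$out$g)) nd$backward(nd$out$g)
      nd$out$g <- NULL  # free intermediate gradients eagerly
    }
  }
  loss$g <- 1
  ag_reset_tape()
  invisible(NULL)
}

# ---- elementwise and shape ops ------------------------------------------

ag_relu <- function(x) {
  x <- ag_wrap(x)
  out <- ag_tensor(nn_relu_fw(x$v))
  ag_record(out, list(x), function(g) ag_accum(x, nn_relu_bw(x$v, g)))
}

ag_sigmoid <- function(x) {
  x <- ag_wrap(x)
  s <- 1 / (1 + exp(-x$v))
  out <- ag_tensor(s)
  ag_record(out, list(x), function(g) ag_accum(x, g * s * (1 - s)))
}

ag_add <- function(x, y) {
  x <- ag_wrap(x); y <- ag_wrap(y)
  out <- ag_tensor(x$v + y$v)
  ag_record(out, list(x, y), function(g) {
    ag_accum(x, g)
    ag_accum(y, g)
  })
}

ag_mul <- function(x, y) {
  x <- ag_wrap(x); y <- ag_wrap(y)
  out <- ag_tensor(x$v * y$v)
  ag_record(out, list(x, y), function(g) {
    ag_accum(x, g * y$v)
    ag_accum(y, g * x$v)
  })
}

# Concatenate feature maps along the channel axis.
ag_concat_c <- function(xs) {
  xs <- lapply(xs, ag_wrap)
  dims <- lapply(xs, function(x) dim(x$v))
  H <- dims[[1]][1]; W <- dims[[1]][2]; N <- dims[[1]][4]
  chans <- vapply(dims, function(d) d[3], numeric(1))
  v <- array(0, c(H, W, sum(chans), N))
  at <- 0L
  for (k in seq_along(xs)) {
    v[, , at + seq_len(chans[k]), ] <- xs[[k]]$v
    at <- at + chans[k]
  }
  out <- ag_tensor(v)
  ag_record(out, xs, function(g) {
    at <- 0L
    for (k in seq_along(xs)) {
      ag_accum(xs[[k]], g[, , at + seq_len(chans[k]), , drop = FALSE])
      at <- at + chans[k]
    }
  })
}

# Softmax over the channel axis of a (H, W, C, N) map.
ag_softmax_c <- function(x) {
  x <- ag_wrap(x)
  d <- dim(x$v)
  A <- array(x$v, c(d[1] * d[2], d[3], d[4]))
  P <- A
  for (n in seq_len(d[4])) {
    M <- matrix(A[, , n], d[1] * d[2], d[3])
    E <- exp(M - apply(M, 1, max))
    P[, , n] <- E / rowSums(E)
  }
  p <- array(P, d)
  out <- ag_tensor(p)
  ag_record(out, list(x), function(g) {
    G <- array(g, c(d[1] * d[2], d[3], d[4]))
    GX <- G
    for (n in seq_len(d[4])) {
      Gm <- matrix(G[, , n], d[1] * d[2], d[3])
      Pm <- matrix(P[, , n], d[1] * d[2], d[3])
      GX[, , n] <- Pm * (Gm - rowSums(Gm * Pm))
    }
    ag_accum(x, array(GX, d))
  })
}

# ---- conv / pool / resample (C++ kernels) --------------------------------

ag_conv2d <- function(x, w, b, dil = 1L) {
  x <- ag_wrap(x)
  out <- ag_tensor(nn_conv2d_fw(x$v, w$v, b$v, as.integer(dil)))
  ag_record(out, list(x, w, b), function(g) {
    gr <- nn_conv2d_bw(x$v, w$v, g, as.integer(dil))
    ag_accum(x, gr$gx)
    ag_accum(w, gr$gw)
    ag_accum(b, gr$gb)
  })
}

ag_maxpool2 <- function(x) {
  x <- ag_wrap(x)
  r <- nn_maxpool2_fw(x$v)
  out <- ag_tensor(r$y)
  xd <- dim(x$v)
  ag_record(out, list(x), function(g) {
    ag_accum(x, nn_maxpool2_bw(r$idx, g, as.integer(xd)))
  })
}

ag_upsample2 <- function(x) {
  x <- ag_wrap(x)
  out <- ag_tensor(nn_upsample2_fw(x$v))
  xd <- dim(x$v)
  ag_record(out, list(x), function(g) {
    ag_accum(x, nn_upsample2_bw(g, as.integer(xd)))
  })
}

# ---- reductions and broadcasts -------------------------------------------

# Global average pooling: (H, W, C, N) -> (C, N).
ag_gap <- function(x) {
  x <- ag_wrap(x)
  d <- dim(x$v)
  A <- array(x$v, c(d[1] * d[2], d[3], d[4]))
  v <- apply(A, c(2, 3), mean)
  dim(v) <- c(d[3], d[4])
  out <- ag_tensor(v)
  ag_record(out, list(x), function(g) {
    gx <- array(rep(as.vector(g) / (d[1] * d[2]), each = d[1] * d[2]), d)
    ag_accum(x, gx)
  })
}

# Broadcast a (C, N) descriptor to a (H, W, C, N) map.
ag_broadcast_hw <- function(s, H, W) {
  s <- ag_wrap(s)
  d <- dim(s$v)
  v <- array(rep(as.vector(s$v), each = H * W), c(H, W, d[1], d[2]))
  out <- ag_tensor(v)
  ag_record(out, list(s), function(g) {
    G <- array(g, c(H * W, d[1], d[2]))
    gs <- apply(G, c(2, 3), sum)
    dim(gs) <- d
    ag_accum(s, gs)
  })
}

# Per-channel scaling of x (H, W, C, N) by gates s (C, N).
ag_scale_c <- function(x, s) {
  x <- ag_wrap(x); s <- ag_wrap(s)
  d <- dim(x$v)
  HW <- d[1] * d[2]
  sv <- array(rep(as.vector(s$v), each = HW), d)
  out <- ag_tensor(x$v * sv)
  ag_record(out, list(x, s), function(g) {
    ag_accum(x, g * sv)
    G <- array(g * x$v, c(HW, d[3], d[4]))
    gs <- apply(G, c(2, 3), sum)
    dim(gs) <- c(d[3], d[4])
    ag_accum(s, gs)
  })
}

# Dense map on (Cin, N) descriptors: out = t(W) %*% s + b, W dim (Cin, Cout).
ag_dense <- function(s, w, b) {
  s <- ag_wrap(s)
  v <- crossprod(w$v, s$v) + b$v
  out <- ag_tensor(v)
  ag_record(out, list(s, w, b), function(g) {
    ag_accum(s, w$v %*% g)
    ag_accum(w, s$v %*% t(g))
    ag_accum(b, rowSums(g))
  })
}

# ---- batch normalization --------------------------------------------------

# Per-channel normalization over (H, W, N).  `state` carries running moments
# (used in evaluation mode); training mode normalizes with batch statistics
# and updates the running moments with momentum `mom`.
ag_bn <- function(x, gamma, beta, state, training = FALSE, eps = 1e-5,
                  mom = 0.1) {
  x <- ag_wrap(x)
  d <- dim(x$v)
  m <- d[1] * d[2] * d[4]
  if (training) {
    st <- nn_bn_stats(x$v)
    mu <- st$mean
    va <- st$var
    state$mean <- (1 - mom) * state$mean + mom * mu
    state$var <- (1 - mom) * state$var + mom * va * m / max(1, m - 1)
  } else {
    mu <- state$mean
    va <- state$var
  }
  out <- ag_tensor(nn_bn_fw(x$v, gamma$v, beta$v, mu, va, eps))
  ag_record(out, list(x, gamma, beta), function(g) {
    gr <- nn_bn_bw(x$v, gamma$v, g, mu, va, eps, training)
    ag_accum(x, gr$gx)
    ag_accum(gamma, gr$ggamma)
    ag_accum(beta, gr$gbeta)
  })
}

# ---- multi-head 2-D self-attention with relative positional logits -------

# Offset index matrices for an H x W grid flattened column-major
# (p = (w-1)*H + h): row offsets in [-(H-1), H-1] shifted to 1..2H-1.
rel_index_matrices <- function(H, W) {
  hs <- rep(seq_len(H), W)
  ws <- rep(seq_len(W), each = H)
  IR <- outer(hs, hs, function(a, b) b - a) + H       # row_q - row_p
  IC <- outer(ws, ws, function(a, b) b - a) + W
  list(IR = IR, IC = IC)
}

# Relative-position logits for one head: Rel[p, q] = Q[p, ] . (rr[dRow] + rc[dCol]).
# Factored out so the translation-consistency property can be tested directly;
# `rows` restricts to a block of query pixels (memory-bounded forward).
att_rel_logits <- function(Qm, rr, rc, H, W, idx = rel_index_matrices(H, W),
                           rows = seq_len(H * W)) {
  HW <- H * W
  nr <- length(rows)
  Ar <- Qm[rows, , drop = FALSE] %*% t(rr)   # nr x (2H-1)
  Ac <- Qm[rows, , drop = FALSE] %*% t(rc)
  sel <- cbind(rep(seq_len(nr), times = HW), as.vector(idx$IR[rows, , drop = FALSE]))
  Rel <- matrix(Ar[sel], nr, HW)
  sel[, 2] <- as.vector(idx$IC[rows, , drop = FALSE])
  Rel + matrix(Ac[sel], nr, HW)
}

# Q, K: (H, W, dk_total, N); V: (H, W, dv_total, N); rr: (2H-1, dkh, heads);
# rc: (2W-1, dkh, heads).  Content and relative logits are jointly scaled by
# 1/sqrt(dkh) before the softmax.  Returns (H, W, dv_total, N).
ag_attention <- function(Q, K, V, rr, rc, heads, relative = TRUE) {
  Q <- ag_wrap(Q); K <- ag_wrap(K); V <- ag_wrap(V)
  d <- dim(Q$v)
  H <- d[1]; W <- d[2]; N <- d[4]
  HW <- H * W
  dkh <- d[3] / heads
  dvh <- dim(V$v)[3] / heads
  idx <- rel_index_matrices(H, W)
  scale <- 1 / sqrt(dkh)
  v <- array(0, c(H, W, dvh * heads, N))
  # the per-head softmax matrices are only needed for the backward pass;
  # caching them for a no-grad forward would hold O(heads * (HW)^2) memory
  keep <- .ag$recording && (Q$req || K$req || V$req || rr$req || rc$req)
  cache <- if (keep) vector("list", N * heads)
  # block of query pixels processed at once; bounds transient memory to
  # O(chunk * HW) while a single block still covers every training-size grid
  chunk <- max(1L, 4000000L %/% HW)
  for (n in seq_len(N)) {
    for (h in seq_len(heads)) {
      qc <- (h - 1) * dkh + seq_len(dkh)
      vc <- (h - 1) * dvh + seq_len(dvh)
      Qm <- matrix(Q$v[, , qc, n], HW, dkh)
      Km <- matrix(K$v[, , qc, n], HW, dkh)
      Vm <- matrix(V$v[, , vc, n], HW, dvh)
      rrh <- if (relative) matrix(rr$v[, , h], 2 * H - 1, dkh)
      rch <- if (relative) matrix(rc$v[, , h], 2 * W - 1, dkh)
      Y <- matrix(0, HW, dvh)
      Pfull <- if (keep) matrix(0, HW, HW)
      for (s in seq(1L, HW, by = chunk)) {
        rows <- s:min(HW, s + chunk - 1L)
        logits <- Qm[rows, , drop = FALSE] %*% t(Km)
        if (relative)
          logits <- logits + att_rel_logits(Qm, rrh, rch, H, W, idx, rows)
        logits <- logits * scale
        P <- exp(logits - apply(logits, 1, max))
        P <- P / rowSums(P)
        Y[rows, ] <- P %*% Vm
        if (keep) Pfull[rows, ] <- P
      }
      v[, , vc, n] <- array(Y, c(H, W, dvh))
      if (keep) cache[[(n - 1) * heads + h]] <- list(Qm = Qm, Km = Km,
                                                     Vm = Vm, P = Pfull)
    }
  }
  out <- ag_tensor(v)
  ag_record(out, list(Q, K, V, rr, rc), function(g) {
    gQ <- array(0, dim(Q$v)); gK <- array(0, dim(K$v)); gV <- array(0, dim(V$v))
    gRR <- array(0, dim(rr$v)); gRC <- array(0, dim(rc$v))
    for (n in seq_len(N)) {
      for (h in seq_len(heads)) {
        cc <- cache[[(n - 1) * heads + h]]
        qc <- (h - 1) * dkh + seq_len(dkh)
        vc <- (h - 1) * dvh + seq_len(dvh)
        gY <- matrix(g[, , vc, n], HW, dvh)
        gP <- gY %*% t(cc$Vm)
        gV[, , vc, n] <- gV[, , vc, n] + array(t(cc$P) %*% gY, c(H, W, dvh))
        dlog <- cc$P * (gP - rowSums(gP * cc$P))
        dlog <- dlog * scale
        gQm <- dlog %*% cc$Km
        gK[, , qc, n] <- gK[, , qc, n] + array(t(dlog) %*% cc$Qm, c(H, W, dkh))
        if (relative) {
          # gather-backward onto the (2H-1)/(2W-1) offset tables
          dAr <- matrix(0, HW, 2 * H - 1)
          for (o in seq_len(2 * H - 1)) {
            msk <- idx$IR == o
            if (any(msk)) dAr[, o] <- rowSums(dlog * msk)
          }
          dAc <- matrix(0, HW, 2 * W - 1)
          for (o in seq_len(2 * W - 1)) {
            msk <- idx$IC == o
            if (any(msk)) dAc[, o] <- rowSums(dlog * msk)
          }
          rrh <- matrix(rr$v[, , h], 2 * H - 1, dkh)
          rch <- matrix(rc$v[, , h], 2 * W - 1, dkh)
          gQm <- gQm + dAr %*% rrh + dAc %*% rch
          gRR[, , h] <- matrix(gRR[, , h], 2 * H - 1, dkh) + t(dAr) %*% cc$Qm
          gRC[, , h] <- matrix(gRC[, , h], 2 * W - 1, dkh) + t(dAc) %*% cc$Qm
        }
        gQ[, , qc, n] <- gQ[, , qc, n] + array(gQm, c(H, W, dkh))
      }
    }
    ag_accum(Q, gQ); ag_accum(K, gK); ag_accum(V, gV)
    ag_accum(rr, gRR); ag_accum(rc, gRC)
  })
}

# Multiply an RGB image by a per-pixel foreground gate (1 - background
# probability), broadcasting the gate over color channels.
ag_fg_gate <- function(image, probs) {
  image <- ag_wrap(image); probs <- ag_wrap(probs)
  d <- dim(image$v)
  fg <- 1 - probs$v[, , 1, , drop = FALSE]          # channel 1 = background
  fgb <- array(0, d)
  for (c in seq_len(d[3])) fgb[, , c, ] <- fg[, , 1, ]
  out <- ag_tensor(image$v * fgb)
  ag_record(out, list(image, probs), function(g) {
    ag_accum(image, g * fgb)
    gi <- g * image$v
    gfg <- gi[, , 1, , drop = FALSE]
    if (d[3] > 1)
      for (c in 2:d[3]) gfg <- gfg + gi[, , c, , drop = FALSE]
    gp <- array(0, dim(probs$v))
    gp[, , 1, ] <- -gfg[, , 1, ]
    ag_accum(probs, gp)
  })
}

# Weighted sum of scalar loss nodes.
ag_wsum <- function(nodes, weights) {
  v <- sum(vapply(seq_along(nodes), function(i) weights[i] * nodes[[i]]$v,
                  numeric(1)))
  out <- ag_tensor(v)
  ag_record(out, nodes, function(g) {
    for (i in seq_along(nodes)) ag_accum(nodes[[i]], g * weights[i])
  })
}
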