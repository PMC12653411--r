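# The bespoke building blocks: attention-augmented convolution (AAC),
# multiplicative gating, squeeze-and-excitation (SE), and atrous spatial
# pyramid pooling (ASPP).
#
# All blocks consume and produce feature maps laid out as (H, W, C, N)
# arrays.  Each forward accepts either a plain array or an internal autograd
# tensor and returns the matching type, so the blocks are usable both as
# standalone layers and inside the trainable network.

maybe_value <- function(out, input) if (is_ag(input)) out else out$v

#' Attention-augmented convolution configuration
#'
#' Hyperparameters for an AAC block: a standard convolution branch producing
#' `out_channels - dv_total` channels concatenated with a multi-head
#' self-attention branch producing `dv_total` channels.  `dk_total` and
#' `dv_total` are key/value dimensions summed over all heads (the reference
#' configuration distributes 32-dimensional keys and values across four
#' heads, i.e. 8 per head).
#'
#' @param in_channels,out_channels Input/output channel counts.
#' @param kernel_size Odd convolution kernel size for the conv branch.
#' @param dk_total,dv_total Total key/value dimensions (divisible by
#'   `num_heads`); `dv_total` must be smaller than `out_channels`.
#' @param num_heads Number of attention heads.
#' @param relative Use 2-D relative positional logits (learnable row/column
#'   offset embedding tables).
#' @param spatial_shape Integer `(rows, cols)` the block operates on; sizes
#'   the relative embedding tables (`2*rows - 1` and `2*cols - 1` entries).
#' @param stride Convolution stride; only stride 1 is supported.
#' @return A validated list of class `aac_config`.
#' @export
aac_config <- function(in_channels, out_channels, kernel_size = 3L,
                       dk_total = 32L, dv_total = 32L, num_heads = 4L,
                       relative = TRUE, spatial_shape = c(28L, 28L),
                       stride = 1L) {
  if (kernel_size %% 2 != 1) stop("aac_config: kernel_size must be odd")
  if (dk_total %% num_heads != 0 || dv_total %% num_heads != 0)
    stop("aac_config: dk_total and dv_total must be divisible by num_heads")
  if (dv_total >= out_channels)
    stop("aac_config: dv_total must be < out_channels ",
         "(the conv branch gets out_channels - dv_total channels)")
  if (stride != 1L) stop("aac_config: only stride 1 is supported")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_size = as.integer(kernel_size),
                 dk_total = as.integer(dk_total),
                 dv_total = as.integer(dv_total),
                 num_heads = as.integer(num_heads),
                 relative = isTRUE(relative),
                 spatial_shape = as.integer(spatial_shape),
                 stride = 1L),
            class = "aac_config")
}

#' Create self-attention projections for an AAC block
#'
#' Builds the learnable query/key/value projections (1x1 convolutions) and,
#' when `cfg$relative` is set, the per-head relative row/column offset
#' embedding tables with `2*H - 1` and `2*W - 1` entries.
#'
#' @param cfg An [aac_config()].
#' @return A parameter list usable with [self_attention()].
#' @export
new_self_attention <- function(cfg) {
  H <- cfg$spatial_shape[1]; W <- cfg$spatial_shape[2]
  dkh <- cfg$dk_total / cfg$num_heads
  sd <- 1 / sqrt(cfg$in_channels)
  proj <- list(
    kind = "self_attention",
    wq = new_conv(cfg$in_channels, cfg$dk_total, k = 1L, init_sd = sd),
    wk = new_conv(cfg$in_channels, cfg$dk_total, k = 1L, init_sd = sd),
    wv = new_conv(cfg$in_channels, cfg$dv_total, k = 1L, init_sd = sd)
  )
  if (cfg$relative) {
    rsd <- 1 / sqrt(dkh)
    proj$rel_row <- ag_param(array(stats::rnorm((2 * H - 1) * dkh * cfg$num_heads, 0, rsd),
                                   c(2 * H - 1, dkh, cfg$num_heads)))
    proj$rel_col <- ag_param(array(stats::rnorm((2 * W - 1) * dkh * cfg$num_heads, 0, rsd),
                                   c(2 * W - 1, dkh, cfg$num_heads)))
  }
  proj
}

#' Multi-head 2-D self-attention over a feature map
#'
#' Projects the input to queries, keys and values, forms per-head scaled
#' dot-product logits over all spatial positions (optionally adding relative
#' row/column positional terms), normalizes with a softmax so each query's
#' weights over the `H*W` keys sum to one, and aggregates the values.
#'
#' @param x Feature map `(H, W, in_channels, N)`.
#' @param cfg An [aac_config()].
#' @param proj Projections from [new_self_attention()].
#' @return Feature map `(H, W, dv_total, N)`.
#' @export
self_attention <- function(x, cfg, proj) {
  xn <- ag_wrap(x)
  d <- dim(xn$v)
  if (d[3] != cfg$in_channels)
    stop("self_attention: input has ", d[3], " channels, config expects ",
         cfg$in_channels)
  if (cfg$relative && (d[1] > cfg$spatial_shape[1] || d[2] > cfg$spatial_shape[2]))
    stop("self_attention: spatial dims ", d[1], "x", d[2],
         " exceed the relative embedding tables sized for ",
         cfg$spatial_shape[1], "x", cfg$spatial_shape[2])
  Q <- conv_fw(proj$wq, xn)
  K <- conv_fw(proj$wk, xn)
  V <- conv_fw(proj$wv, xn)
  if (cfg$relative && (d[1] < cfg$spatial_shape[1] || d[2] < cfg$spatial_shape[2])) {
    # center-crop the offset tables to the actual grid
    H <- d[1]; W <- d[2]
    H0 <- cfg$spatial_shape[1]; W0 <- cfg$spatial_shape[2]
    rr <- ag_tensor(proj$rel_row$v[(H0 - H + 1):(H0 + H - 1), , , drop = FALSE])
    rc <- ag_tensor(proj$rel_col$v[(W0 - W + 1):(W0 + W - 1), , , drop = FALSE])
    out <- ag_attention(Q, K, V, rr, rc, cfg$num_heads, TRUE)
  } else if (cfg$relative) {
    out <- ag_attention(Q, K, V, proj$rel_row, proj$rel_col, cfg$num_heads, TRUE)
  } else {
    dummy <- ag_tensor(array(0, c(1, 1, 1)))
    out <- ag_attention(Q, K, V, dummy, dummy, cfg$num_heads, FALSE)
  }
  maybe_value(out, x)
}

#' Create an attention-augmented convolution block
#'
#' The block concatenates a same-padded `kernel_size` convolution producing
#' `out_channels - dv_total` channels with a self-attention branch producing
#' `dv_total` channels (followed by a 1x1 output projection), then optionally
#' applies batch norm + ReLU to the concatenated map (`post_norm`).
#'
#' @param cfg An [aac_config()].
#' @param post_norm Apply BN + ReLU after concatenation (default `TRUE`).
#' @return A parameter list usable with [aac_forward()].
#' @export
new_aac <- function(cfg, post_norm = TRUE) {
  list(
    kind = "aac",
    cfg = cfg,
    conv = new_conv(cfg$in_channels, cfg$out_channels - cfg$dv_total,
                    k = cfg$kernel_size),
    attn = new_self_attention(cfg),
    attn_out = new_conv(cfg$dv_total, cfg$dv_total, k = 1L),
    post = if (post_norm) new_bn(cfg$out_channels),
    post_norm = isTRUE(post_norm)
  )
}

#' Attention-augmented convolution forward pass
#'
#' @param x Feature map `(H, W, in_channels, N)`.
#' @param cfg An [aac_config()] (defaults to the one stored in `params`).
#' @param params Block parameters from [new_aac()].
#' @param training Use batch statistics in the post-concat batch norm.
#' @return Feature map `(H, W, out_channels, N)`.
#' @export
aac_forward <- function(x, cfg = params$cfg, params, training = FALSE) {
  xn <- ag_wrap(x)
  if (dim(xn$v)[3] != cfg$in_channels)
    stop("aac_forward: input has ", dim(xn$v)[3], " channels, config expects ",
         cfg$in_channels)
  yc <- conv_fw(params$conv, xn)
  ya <- ag_wrap(self_attention(xn, cfg, params$attn))
  ya <- conv_fw(params$attn_out, ya)
  y <- ag_concat_c(list(yc, ya))
  if (params$post_norm) y <- ag_relu(bn_fw(params$post, y, training))
  maybe_value(y, x)
}

#' Create a gating block
#'
#' Two 1x1 convolutions with a batch-norm + ReLU bottleneck that squeeze the
#' channel count from `C` to `floor(C/2)` (minimum 1) and back, ending in a
#' sigmoid; the resulting mask multiplies the input elementwise.
#'
#' @param channels Input/output channel count `C`.
#' @return A parameter list usable with [gating_forward()].
#' @export
new_gating <- function(channels) {
  mid <- max(1L, channels %/% 2L)
  list(kind = "gating", channels = as.integer(channels),
       conv1 = new_conv(channels, mid, k = 1L),
       bn = new_bn(mid),
       conv2 = new_conv(mid, channels, k = 1L))
}

#' Gating block forward pass
#'
#' Computes `z = x * sigmoid(Conv2(ReLU(BN(Conv1(x)))))`.  The mask lies in
#' (0, 1), so elementwise `|z| <= |x|` and `z` keeps the sign of `x`.
#'
#' @param x Feature map `(H, W, C, N)`.
#' @param params Parameters from [new_gating()].
#' @param training Batch-norm mode.
#' @return Feature map with the same shape as `x`.
#' @export
gating_forward <- function(x, params, training = FALSE) {
  xn <- ag_wrap(x)
  if (dim(xn$v)[3] != params$channels)
    stop("gating_forward: input has ", dim(xn$v)[3],
         " channels, params expect ", params$channels)
  g <- ag_sigmoid(conv_fw(params$conv2,
                          ag_relu(bn_fw(params$bn, conv_fw(params$conv1, xn),
                                        training))))
  maybe_value(ag_mul(xn, g), x)
}

#' Create a squeeze-and-excitation block
#'
#' @param channels Input channel count.
#' @param reduction Bottleneck reduction ratio (default 8); the squeezed
#'   width is `max(1, floor(channels / reduction))`.
#' @return A parameter list usable with [se_forward()].
#' @export
new_se <- function(channels, reduction = 8L) {
  mid <- max(1L, channels %/% reduction)
  fc1 <- new_dense(channels, mid)
  # the squeeze descriptor is nonnegative (post-ReLU features), so a
  # positive bias keeps the narrow bottleneck units active at initialization
  fc1$b$v[] <- 1
  list(kind = "se", channels = as.integer(channels),
       fc1 = fc1,
       fc2 = new_dense(mid, channels))
}

#' Squeeze-and-excitation forward pass
#'
#' Global average pooling followed by two linear maps (ReLU then sigmoid)
#' yields per-channel gates in (0, 1) that rescale the input.
#'
#' @param x Feature map `(H, W, C, N)`.
#' @param params Parameters from [new_se()].
#' @return Feature map with the same shape as `x`.
#' @export
se_forward <- function(x, params) {
  xn <- ag_wrap(x)
  s <- ag_gap(xn)
  s <- ag_sigmoid(dense_fw(params$fc2, ag_relu(dense_fw(params$fc1, s))))
  maybe_value(ag_scale_c(xn, s), x)
}

#' Create an atrous spatial pyramid pooling block
#'
#' Parallel branches: a 1x1 convolution, one same-padded 3x3 dilated
#' convolution per rate, and a global image-pooling branch, concatenated on
#' the channel axis and projected back to `out_channels` by a 1x1
#' convolution followed by BN + ReLU.
#'
#' @param in_channels,out_channels Channel counts.
#' @param rates Dilation rates (default `c(6, 12, 18)`); all must be >= 1.
#' @return A parameter list usable with [aspp_forward()].
#' @export
new_aspp <- function(in_channels, out_channels, rates = c(6L, 12L, 18L)) {
  if (any(rates < 1)) stop("new_aspp: dilation rates must be >= 1")
  list(kind = "aspp", rates = as.integer(rates),
       b1 = new_conv(in_channels, out_channels, k = 1L),
       dil = lapply(rates, function(r) new_conv(in_channels, out_channels,
                                                k = 3L, dil = r)),
       pool = new_dense(in_channels, out_channels),
       proj = new_conv((length(rates) + 2L) * out_channels, out_channels, k = 1L),
       bn = new_bn(out_channels))
}

#' Atrous spatial pyramid pooling forward pass
#'
#' @param x Feature map `(H, W, C, N)` (nonempty).
#' @param params Parameters from [new_aspp()].
#' @param training Batch-norm mode.
#' @return Feature map `(H, W, out_channels, N)`.
#' @export
aspp_forward <- function(x, params, training = FALSE) {
  xn <- ag_wrap(x)
  d <- dim(xn$v)
  branches <- c(list(conv_fw(params$b1, xn)),
                lapply(params$dil, function(l) conv_fw(l, xn)),
                list(ag_broadcast_hw(dense_fw(params$pool, ag_gap(xn)),
                                     d[1], d[2])))
  y <- conv_fw(params$proj, ag_concat_c(branches))
  maybe_value(ag_relu(bn_fw(params$bn, y, training)), x)
}
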