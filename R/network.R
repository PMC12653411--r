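# GAAD-U-Net assembly: Phase 1 is a VGG-19-style encoder (four blocks, 2/2/4/4
# convolutions, pooling after the first three) with an AAC -> gating -> ASPP
# bottleneck and an SE decoder; Phase 2 re-encodes the input gated by the
# Phase-1 foreground, with conditional pooling (no pooling in its first block)
# and a triple-input decoder that concatenates upsampled features with both
# the Phase-2 encoder skip and the corresponding Phase-1 decoder output.
# The two phase outputs are fused by a 1x1 convolution + softmax.

#' GAAD-U-Net model configuration
#'
#' @param num_classes Number of output classes (3: background, cytoplasm,
#'   nucleus).
#' @param input_size Integer `(rows, cols)`; both must be divisible by 8
#'   (three 2x2 pooling stages precede the bottleneck, which therefore sits
#'   at 1/8 resolution: 28x28 for 224x224 inputs, 64x64 for 512x512).
#' @param encoder1_widths Channel widths of the four Phase-1 (VGG-19-style)
#'   encoder blocks.
#' @param encoder2_widths Channel widths of the four Phase-2 encoder blocks.
#' @param decoder_widths Channel widths of the four decoder blocks (shared
#'   scheme between phases).
#' @param use_aac,use_gating Ablation switches for the bottleneck AAC block
#'   and gating block.
#' @param aac_dk,aac_dv,aac_heads Attention key/value totals and head count
#'   for the bottleneck AAC blocks.
#' @param aspp_rates ASPP dilation rates.
#' @param se_reduction Squeeze-and-excitation reduction ratio.
#' @param vgg_convs Convolutions per Phase-1 encoder block (VGG-19: 2,2,4,4).
#' @return A validated list of class `gaad_config`.
#' @export
model_config <- function(num_classes = 3L,
                         input_size = c(224L, 224L),
                         encoder1_widths = c(64L, 128L, 256L, 512L),
                         encoder2_widths = encoder1_widths,
                         decoder_widths = rev(encoder1_widths) %/% 2L,
                         use_aac = TRUE, use_gating = TRUE,
                         aac_dk = 32L, aac_dv = 32L, aac_heads = 4L,
                         aspp_rates = c(6L, 12L, 18L),
                         se_reduction = 8L,
                         vgg_convs = c(2L, 2L, 4L, 4L)) {
  input_size <- as.integer(input_size)
  if (any(input_size %% 8L != 0L))
    stop("model_config: input rows and cols must be divisible by 8, got ",
         paste(input_size, collapse = "x"))
  stopifnot(length(encoder1_widths) == 4, length(encoder2_widths) == 4,
            length(decoder_widths) == 4, length(vgg_convs) == 4)
  cfg <- structure(list(
    num_classes = as.integer(num_classes),
    input_size = input_size,
    encoder1_widths = as.integer(encoder1_widths),
    encoder2_widths = as.integer(encoder2_widths),
    decoder_widths = as.integer(decoder_widths),
    use_aac = isTRUE(use_aac), use_gating = isTRUE(use_gating),
    aac_dk = as.integer(aac_dk), aac_dv = as.integer(aac_dv),
    aac_heads = as.integer(aac_heads),
    aspp_rates = as.integer(aspp_rates),
    se_reduction = as.integer(se_reduction),
    vgg_convs = as.integer(vgg_convs),
    bottleneck_size = input_size %/% 8L
  ), class = "gaad_config")
  if (cfg$use_aac) {
    # validate the attention split at both bottlenecks
    aac_config(encoder1_widths[4], encoder1_widths[4], dk_total = aac_dk,
               dv_total = aac_dv, num_heads = aac_heads,
               spatial_shape = cfg$bottleneck_size)
    aac_config(encoder2_widths[4], encoder2_widths[4], dk_total = aac_dk,
               dv_total = aac_dv, num_heads = aac_heads,
               spatial_shape = cfg$bottleneck_size)
  }
  cfg
}

new_enc_block1 <- function(in_ch, width, n_convs) {
  convs <- list(new_cbr(in_ch, width))
  for (i in seq_len(n_convs - 1L)) convs[[i + 1L]] <- new_cbr(width, width)
  list(kind = "enc1", convs = convs)
}

new_enc_block2 <- function(in_ch, width, se_reduction) {
  list(kind = "enc2",
       convs = list(new_cbr(in_ch, width), new_cbr(width, width)),
       se = new_se(width, se_reduction))
}

new_dec_block <- function(in_ch, width, se_reduction) {
  list(kind = "dec",
       convs = list(new_cbr(in_ch, width), new_cbr(width, width)),
       se = new_se(width, se_reduction))
}

new_bottleneck <- function(cfg, width) {
  list(kind = "bottleneck",
       aac = if (cfg$use_aac)
         new_aac(aac_config(width, width, dk_total = cfg$aac_dk,
                            dv_total = cfg$aac_dv, num_heads = cfg$aac_heads,
                            spatial_shape = cfg$bottleneck_size)),
       gating = if (cfg$use_gating) new_gating(width),
       aspp = new_aspp(width, width, cfg$aspp_rates))
}

#' Build a GAAD-U-Net model
#'
#' Allocates all learnable parameters for the two-phase network described by
#' `cfg`, using the R random number generator (seed it for reproducible
#' initialization).
#'
#' @param cfg A [model_config()].
#' @return A model object of class `gaad_model`.
#' @export
gaad_model <- function(cfg = model_config()) {
  w <- cfg$encoder1_widths; v <- cfg$encoder2_widths; dw <- cfg$decoder_widths
  sr <- cfg$se_reduction
  p1_enc <- list(new_enc_block1(3L, w[1], cfg$vgg_convs[1]),
                 new_enc_block1(w[1], w[2], cfg$vgg_convs[2]),
                 new_enc_block1(w[2], w[3], cfg$vgg_convs[3]),
                 new_enc_block1(w[3], w[4], cfg$vgg_convs[4]))
  p1_dec <- list(new_dec_block(w[4] + w[4], dw[1], sr),
                 new_dec_block(dw[1] + w[3], dw[2], sr),
                 new_dec_block(dw[2] + w[2], dw[3], sr),
                 new_dec_block(dw[3] + w[1], dw[4], sr))
  p2_enc <- list(new_enc_block2(3L, v[1], sr),
                 new_enc_block2(v[1], v[2], sr),
                 new_enc_block2(v[2], v[3], sr),
                 new_enc_block2(v[3], v[4], sr))
  p2_dec <- list(new_dec_block(v[4] + v[4] + dw[1], dw[1], sr),
                 new_dec_block(dw[1] + v[3] + dw[2], dw[2], sr),
                 new_dec_block(dw[2] + v[2] + dw[3], dw[3], sr),
                 new_dec_block(dw[3] + v[1] + dw[4], dw[4], sr))
  # the fusion head starts as a pass-through average of the two phase maps
  # (identity-style initialization), so the fused prediction is consistent
  # with the phases from the first step and only learns adjustments
  fuse <- new_conv(2L * cfg$num_classes, cfg$num_classes, k = 1L)
  fuse$w$v[] <- 0
  for (k in seq_len(cfg$num_classes)) {
    fuse$w$v[1, 1, k, k] <- 2
    fuse$w$v[1, 1, cfg$num_classes + k, k] <- 2
  }
  structure(list(
    cfg = cfg,
    p1 = list(enc = p1_enc, bneck = new_bottleneck(cfg, w[4]), dec = p1_dec,
              head = new_conv(dw[4], cfg$num_classes, k = 1L)),
    p2 = list(enc = p2_enc, bneck = new_bottleneck(cfg, v[4]), dec = p2_dec,
              head = new_conv(dw[4], cfg$num_classes, k = 1L)),
    fuse = fuse
  ), class = "gaad_model")
}

#' @export
print.gaad_model <- function(x, ...) {
  cfg <- x$cfg
  cat("GAAD-U-Net model\n")
  cat("  input:", paste(cfg$input_size, collapse = "x"),
      " classes:", cfg$num_classes, "\n")
  cat("  encoder widths:", paste(cfg$encoder1_widths, collapse = ","),
      " decoder widths:", paste(cfg$decoder_widths, collapse = ","), "\n")
  cat("  AAC:", cfg$use_aac, " gating:", cfg$use_gating,
      " parameters:", n_parameters(x), "\n")
  invisible(x)
}

run_convs <- function(block, x, training) {
  for (l in block$convs) x <- cbr_fw(l, x, training)
  x
}

run_bottleneck <- function(bn, x, training) {
  if (!is.null(bn$aac)) x <- ag_wrap(aac_forward(x, params = bn$aac,
                                                 training = training))
  if (!is.null(bn$gating)) x <- ag_wrap(gating_forward(x, bn$gating, training))
  ag_wrap(aspp_forward(x, bn$aspp, training))
}

run_dec_block <- function(block, x, training) {
  x <- run_convs(block, x, training)
  ag_wrap(se_forward(x, block$se))
}

check_input_dims <- function(cfg, image) {
  d <- dim(image)
  if (length(d) != 4L || d[3] != 3L)
    stop("expected a (H, W, 3, N) image array, got dim ",
         paste(d, collapse = "x"))
  if (d[1] != cfg$input_size[1] || d[2] != cfg$input_size[2])
    stop("image is ", d[1], "x", d[2], " but the model was configured for ",
         paste(cfg$input_size, collapse = "x"))
}

#' Phase-1 forward pass
#'
#' Runs the VGG-19-style encoder (2x2 max pooling after blocks 1-3), the
#' bottleneck cascade (AAC when enabled, gating when enabled, then ASPP) on
#' the 1/8-resolution block-4 output, and the four SE decoder blocks (the
#' first concatenates the block-4 skip without upsampling; the rest upsample
#' bilinearly and concatenate blocks 3/2/1).  A 1x1 convolution + softmax
#' head yields the Phase-1 probability map at full input resolution.
#'
#' @param model A [gaad_model()].
#' @param image `(H, W, 3, N)` array (or autograd tensor).
#' @param training Batch-norm mode.
#' @return A list with `prob` (the `(H, W, num_classes, N)` probability
#'   map), `skips` (the four decoder outputs, deepest first, reused by
#'   Phase 2) and `bottleneck_dim` (the shape of the bottleneck feature).
#' @export
phase1_forward <- function(model, image, training = FALSE) {
  cfg <- model$cfg
  plain <- !is_ag(image)
  x <- ag_wrap(image)
  check_input_dims(cfg, x$v)
  e <- vector("list", 4L)
  for (i in 1:4) {
    if (i > 1L) x <- ag_maxpool2(x)
    x <- run_convs(model$p1$enc[[i]], x, training)
    e[[i]] <- x
  }
  b <- run_bottleneck(model$p1$bneck, x, training)
  bdim <- dim(b$v)
  d <- vector("list", 4L)
  u <- b
  for (i in 1:4) {
    if (i > 1L) u <- ag_upsample2(u)
    u <- ag_concat_c(list(u, e[[5L - i]]))
    u <- run_dec_block(model$p1$dec[[i]], u, training)
    d[[i]] <- u
  }
  prob <- ag_softmax_c(conv_fw(model$p1$head, u))
  if (plain) {
    list(prob = prob$v, skips = lapply(d, function(z) z$v),
         bottleneck_dim = bdim)
  } else {
    list(prob = prob, skips = d, bottleneck_dim = bdim)
  }
}

#' Gate the input image by the Phase-1 foreground
#'
#' Multiplies the image by `1 - P(background)` from the Phase-1 probability
#' map, broadcast over color channels.  At inference this predicted
#' foreground replaces the ground-truth mask used in the original
#' formulation, keeping the model self-contained.
#'
#' @param image `(H, W, 3, N)` array or tensor.
#' @param mask1 `(H, W, num_classes, N)` probability map.
#' @return The gated image, same type and shape as `image`.
#' @export
phase2_input <- function(image, mask1) {
  di <- dim(if (is_ag(image)) image$v else image)
  dm <- dim(if (is_ag(mask1)) mask1$v else mask1)
  if (any(di[c(1, 2, 4)] != dm[c(1, 2, 4)]))
    stop("phase2_input: image and mask are not spatially aligned")
  maybe_value(ag_fg_gate(ag_wrap(image), ag_wrap(mask1)), image)
}

#' Phase-2 forward pass
#'
#' Four encoder blocks with conditional max pooling (the first block keeps
#' full resolution; blocks 2-4 pool 2x2), each ending in SE; the same
#' bottleneck cascade as Phase 1 (independent parameters); and four decoder
#' blocks that concatenate upsampled features with the Phase-2 encoder skip
#' and the matching Phase-1 decoder output before convolutions + SE.
#'
#' @param model A [gaad_model()].
#' @param x2 Gated input from [phase2_input()], `(H, W, 3, N)`.
#' @param phase1_skips The `skips` list returned by [phase1_forward()].
#' @param training Batch-norm mode.
#' @return The Phase-2 probability map (same type as `x2`).
#' @export
phase2_forward <- function(model, x2, phase1_skips, training = FALSE) {
  cfg <- model$cfg
  plain <- !is_ag(x2)
  x <- ag_wrap(x2)
  check_input_dims(cfg, x$v)
  skips <- lapply(phase1_skips, ag_wrap)
  f <- vector("list", 4L)
  for (i in 1:4) {
    if (i > 1L) x <- ag_maxpool2(x)       # conditional pooling: none in block 1
    x <- run_convs(model$p2$enc[[i]], x, training)
    x <- ag_wrap(se_forward(x, model$p2$enc[[i]]$se))
    f[[i]] <- x
  }
  u <- run_bottleneck(model$p2$bneck, x, training)
  for (i in 1:4) {
    if (i > 1L) u <- ag_upsample2(u)
    enc_skip <- f[[5L - i]]
    dec_skip <- skips[[i]]
    du <- dim(u$v); de <- dim(enc_skip$v); dd <- dim(dec_skip$v)
    if (any(du[c(1, 2)] != de[c(1, 2)]) || any(du[c(1, 2)] != dd[c(1, 2)]))
      stop("phase2_forward: skip shape mismatch at decoder block ", i,
           " (features ", du[1], "x", du[2],
           ", encoder skip ", de[1], "x", de[2],
           ", phase-1 skip ", dd[1], "x", dd[2], ")")
    u <- ag_concat_c(list(u, enc_skip, dec_skip))
    u <- run_dec_block(model$p2$dec[[i]], u, training)
  }
  prob <- ag_softmax_c(conv_fw(model$p2$head, u))
  maybe_value(prob, x2)
}

#' Full GAAD-U-Net forward pass
#'
#' Runs Phase 1, gates the input by the Phase-1 foreground (or by the
#' ground-truth foreground when `teacher_forcing`), runs Phase 2, then
#' concatenates the two phase probability maps on the channel axis and
#' applies a 1x1 convolution + softmax to produce the final three-class map.
#'
#' @param model A [gaad_model()].
#' @param image `(H, W, 3, N)` array or tensor.
#' @param training Batch-norm mode.
#' @param gt_mask Optional `(H, W, N)` integer label array used only when
#'   `teacher_forcing = TRUE`.
#' @param teacher_forcing Gate the Phase-2 input with the ground-truth
#'   foreground instead of the predicted one (training-time option).
#' @return A list with `final`, `out1`, `out2` probability maps (arrays when
#'   `image` is an array; autograd tensors otherwise).  The intermediate
#'   maps support deep-supervision losses.
#' @export
gaad_forward <- function(model, image, training = FALSE, gt_mask = NULL,
                         teacher_forcing = FALSE) {
  plain <- !is_ag(image)
  img <- ag_wrap(image)
  p1 <- phase1_forward(model, img, training)
  if (teacher_forcing) {
    if (is.null(gt_mask))
      stop("gaad_forward: teacher_forcing requires gt_mask")
    d <- dim(img$v)
    fg <- array(as.numeric(gt_mask != 0L), c(d[1], d[2], 1, d[4]))
    fgb <- array(0, d)
    for (c in seq_len(d[3])) fgb[, , c, ] <- fg[, , 1, ]
    x2 <- ag_mul(img, ag_tensor(fgb))
  } else {
    x2 <- ag_wrap(phase2_input(img, p1$prob))
  }
  out2 <- ag_wrap(phase2_forward(model, x2, p1$skips, training))
  fused <- conv_fw(model$fuse, ag_concat_c(list(ag_wrap(p1$prob), out2)))
  final <- ag_softmax_c(fused)
  if (plain) {
    list(final = final$v, out1 = if (is_ag(p1$prob)) p1$prob$v else p1$prob,
         out2 = out2$v, bottleneck_dim = p1$bottleneck_dim)
  } else {
    list(final = final, out1 = p1$prob, out2 = out2,
         bottleneck_dim = p1$bottleneck_dim)
  }
}

#' Convert a probability map to a class mask
#'
#' Per-pixel argmax over the class axis; ties resolve to the lowest class
#' index for determinism.
#'
#' @param prob `(H, W, C, N)` probability map (or `(H, W, C)` for one image).
#' @return An `(H, W)` integer matrix for a single image, else `(H, W, N)`.
#' @export
prob_to_mask <- function(prob) {
  d <- dim(prob)
  single <- length(d) == 3L
  if (single) dim(prob) <- c(d[1], d[2], d[3], 1)
  d <- dim(prob)
  out <- array(0L, c(d[1], d[2], d[4]))
  for (n in seq_len(d[4])) {
    best <- prob[, , 1, n]
    lab <- matrix(0L, d[1], d[2])
    for (c in seq_len(d[3])[-1]) {
      upd <- prob[, , c, n] > best
      best[upd] <- prob[, , c, n][upd]
      lab[upd] <- c - 1L
    }
    out[, , n] <- lab
  }
  if (single) out[, , 1] else out
}
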