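# Structural and behavioral tests of the assembled two-phase network.

test_that("input sizes must be divisible by 8", {
  expect_error(model_config(input_size = c(100, 100)), "divisible by 8")
  expect_silent(model_config(input_size = c(96, 96),
                             encoder1_widths = c(4, 4, 4, 8),
                             encoder2_widths = c(4, 4, 4, 8),
                             decoder_widths = c(4, 4, 4, 4),
                             aac_dk = 4, aac_dv = 4, aac_heads = 2))
})

test_that("phase-1 bottleneck sits at 1/8 resolution with block-4 width", {
  set.seed(1)
  mc <- tiny_model_config(input_size = c(24L, 32L))
  m <- gaad_model(mc)
  x <- array(runif(24 * 32 * 3 * 2), c(24, 32, 3, 2))
  out <- phase1_forward(m, x)
  expect_equal(out$bottleneck_dim, c(3L, 4L, 8L, 2L))
  expect_equal(dim(out$prob), c(24L, 32L, 3L, 2L))
  expect_length(out$skips, 4L)
  # decoder outputs double in resolution from 1/8 up to full
  expect_equal(t(vapply(out$skips, function(s) dim(s)[1:2], integer(2))),
               cbind(c(3L, 6L, 12L, 24L), c(4L, 8L, 16L, 32L)))
})

test_that("probability maps are normalized per pixel", {
  set.seed(2)
  m <- gaad_model(tiny_model_config())
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  out <- gaad_forward(m, x)
  for (p in list(out$final, out$out1, out$out2)) {
    s <- apply(p, c(1, 2, 4), sum)
    expect_lt(max(abs(s - 1)), 1e-5)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("ablation switches remove the corresponding bottleneck stages", {
  set.seed(3)
  mc <- tiny_model_config(use_aac = FALSE, use_gating = FALSE)
  m <- gaad_model(mc)
  expect_null(m$p1$bneck$aac)
  expect_null(m$p1$bneck$gating)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  out <- gaad_forward(m, x)
  expect_equal(dim(out$final), c(16L, 16L, 3L, 1L))
})

test_that("parameter counts are strictly ordered over the ablation lattice", {
  counts <- vapply(list(c(FALSE, FALSE), c(FALSE, TRUE),
                        c(TRUE, FALSE), c(TRUE, TRUE)),
                   function(sw) {
                     set.seed(9)
                     n_parameters(gaad_model(tiny_model_config(
                       use_aac = sw[1], use_gating = sw[2])))
                   }, numeric(1))
  # Base < Base+Gating < Base+AAC < Base+AAC+Gating
  expect_true(counts[1] < counts[2])
  expect_true(counts[2] < counts[3])
  expect_true(counts[3] < counts[4])
})

test_that("phase-2 input gates the image by the predicted foreground", {
  img <- array(runif(8 * 8 * 3), c(8, 8, 3, 1))
  bg <- array(0, c(8, 8, 3, 1)); bg[, , 1, ] <- 1          # all background
  expect_equal(phase2_input(img, bg), img * 0)
  fg <- array(0, c(8, 8, 3, 1)); fg[, , 2, ] <- 1          # all cytoplasm
  expect_equal(phase2_input(img, fg), img)
  # half foreground: output support matches the foreground support exactly
  half <- array(0, c(8, 8, 3, 1))
  half[, 1:4, 1, ] <- 1; half[, 5:8, 3, ] <- 1
  y <- phase2_input(img, half)
  expect_equal(max(abs(y[, 1:4, , ])), 0)
  expect_equal(y[, 5:8, , ], img[, 5:8, , ])
  expect_error(phase2_input(img, array(0, c(4, 4, 3, 1))), "aligned")
})

test_that("forward passes are deterministic in evaluation mode", {
  set.seed(5)
  m <- gaad_model(tiny_model_config())
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  o1 <- gaad_forward(m, x)
  o2 <- gaad_forward(m, x)
  expect_identical(o1$final, o2$final)
})

test_that("argmax masks are valid class maps with low-index tie-breaking", {
  set.seed(6)
  m <- gaad_model(tiny_model_config())
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  mask <- prob_to_mask(gaad_forward(m, x)$final)
  expect_true(all(mask %in% 0:2))
  ties <- array(1 / 3, c(2, 2, 3))
  expect_equal(prob_to_mask(ties), matrix(0L, 2, 2))
})

test_that("every learnable parameter receives gradient on some random batch", {
  set.seed(7)
  m <- gaad_model(tiny_model_config())
  params <- gaadunet:::collect_params(m)
  got <- rep(FALSE, length(params))
  opt <- gaadunet:::adam_state(params)
  for (batch in 1:6) {
    # union over random batches, stepping the optimizer in between so a
    # ReLU unit that is coincidentally closed at initialization can reopen;
    # a structurally dead branch stays at zero gradient forever
    x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
    gt <- array(sample(0:2, 16 * 16 * 2, TRUE), c(16, 16, 2))
    gaadunet:::zero_grads(params)
    gaadunet:::with_tape({
      out <- gaad_forward(m, gaadunet:::ag_tensor(x), training = TRUE)
      l <- gaadunet:::ag_wsum(list(gaadunet:::ag_dice_loss(out$out1, gt),
                                   gaadunet:::ag_dice_loss(out$out2, gt),
                                   gaadunet:::ag_dice_loss(out$final, gt)),
                              c(1, 1, 1))
      gaadunet:::ag_backward(l)
    })
    got <- got | vapply(params, function(p) !is.null(p$g) && max(abs(p$g)) > 0,
                        logical(1))
    if (all(got)) break
    opt <- gaadunet:::adam_step(opt, 1e-2)
  }
  expect_true(all(got))
})

test_that("decoder input channels match the config-derived arithmetic", {
  set.seed(12)
  cfg <- model_config(input_size = c(32L, 32L),
                      encoder1_widths = c(5L, 7L, 9L, 11L),
                      encoder2_widths = c(4L, 6L, 8L, 10L),
                      decoder_widths = c(9L, 8L, 7L, 6L),
                      aac_dk = 4L, aac_dv = 4L, aac_heads = 2L,
                      vgg_convs = c(1L, 1L, 1L, 1L))
  m <- gaad_model(cfg)
  w <- cfg$encoder1_widths; v <- cfg$encoder2_widths; dw <- cfg$decoder_widths
  # phase 1: bottleneck output + encoder skip per block
  exp1 <- c(w[4] + w[4], dw[1] + w[3], dw[2] + w[2], dw[3] + w[1])
  # phase 2: upsampled features + encoder-2 skip + phase-1 decoder skip
  exp2 <- c(v[4] + v[4] + dw[1], dw[1] + v[3] + dw[2],
            dw[2] + v[2] + dw[3], dw[3] + v[1] + dw[4])
  for (i in 1:4) {
    expect_equal(dim(m$p1$dec[[i]]$convs[[1]]$conv$w$v)[3:4],
                 c(exp1[i], dw[i]))
    expect_equal(dim(m$p2$dec[[i]]$convs[[1]]$conv$w$v)[3:4],
                 c(exp2[i], dw[i]))
  }
  # forward pass agrees with the same arithmetic end to end
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  out <- gaad_forward(m, x)
  expect_equal(dim(out$final), c(32L, 32L, 3L, 1L))
})

test_that("phase-2 skip shape mismatches name the offending stage", {
  set.seed(8)
  m <- gaad_model(tiny_model_config())
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  p1 <- phase1_forward(m, x)
  bad <- p1$skips
  bad[[2]] <- bad[[2]][1:2, 1:2, , , drop = FALSE]
  expect_error(phase2_forward(m, phase2_input(x, p1$prob), bad),
               "decoder block 2")
})

test_that("teacher forcing gates phase 2 with the ground-truth foreground", {
  set.seed(10)
  m <- gaad_model(tiny_model_config())
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  gt <- matrix(0L, 16, 16); gt[5:10, 5:10] <- 1L
  out <- gaad_forward(m, x, gt_mask = array(gt, c(16, 16, 1)),
                      teacher_forcing = TRUE)
  expect_equal(dim(out$final), c(16L, 16L, 3L, 1L))
  expect_error(gaad_forward(m, x, teacher_forcing = TRUE), "gt_mask")
})
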