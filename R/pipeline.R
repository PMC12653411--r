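# Training / prediction / evaluation orchestration and file I/O.

#' Polynomial learning-rate decay
#'
#' `base_lr * (1 - step / total_steps)^power`, clamped to 0 past
#' `total_steps`.
#'
#' @param step Current step, `0 <= step`.
#' @param total_steps Total scheduled steps.
#' @param base_lr Initial learning rate.
#' @param power Decay exponent (default 0.9).
#' @return The learning rate at `step`.
#' @export
poly_lr <- function(step, total_steps, base_lr, power = 0.9) {
  frac <- pmax(0, 1 - step / total_steps)
  base_lr * frac^power
}

#' Training configuration
#'
#' @param epochs Number of passes over the training set.
#' @param batch_size Images per optimization step (reference recipe: 4 for
#'   512x512 inputs, 16 for 224x224).
#' @param learning_rate Adam learning rate (reference recipe: 1e-4).
#' @param lr_power Polynomial decay exponent.
#' @param loss_weights Weights for the (phase-1, phase-2, final) Dice
#'   losses.
#' @param augmentation Optional [augmentation_config()] applied to training
#'   batches.
#' @param teacher_forcing Gate the Phase-2 input with the ground-truth
#'   foreground during training.
#' @param seed Seed controlling initialization, shuffling and augmentation.
#' @param checkpoint_path Optional path; the best-validation-DSC model (or
#'   the final model when no validation data) is written there.
#' @param eval_every Compute train/validation metrics every this many
#'   epochs (the final epoch is always scored); intermediate epochs log
#'   `NA` metrics.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 4L, learning_rate = 1e-4,
                         lr_power = 0.9, loss_weights = c(1, 1, 1),
                         augmentation = NULL, teacher_forcing = FALSE,
                         seed = 1L, checkpoint_path = NULL, eval_every = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, eval_every >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_power = lr_power,
                 loss_weights = loss_weights, augmentation = augmentation,
                 teacher_forcing = isTRUE(teacher_forcing),
                 seed = as.integer(seed), checkpoint_path = checkpoint_path,
                 eval_every = as.integer(eval_every)),
            class = "train_config")
}

stack_batch <- function(data, idx) {
  H <- nrow(data[[1]]$mask); W <- ncol(data[[1]]$mask)
  n <- length(idx)
  x <- array(0, c(H, W, 3, n))
  y <- array(0L, c(H, W, n))
  for (j in seq_along(idx)) {
    x[, , , j] <- data[[idx[j]]]$image
    y[, , j] <- data[[idx[j]]]$mask
  }
  list(x = x, y = y)
}

# Mean final-map metrics of a model over a dataset (no gradient tape).
dataset_scores <- function(model, data, batch = 4L) {
  accs <- ious <- dscs <- numeric(0)
  for (s in seq(1, length(data), by = batch)) {
    idx <- s:min(length(data), s + batch - 1)
    b <- stack_batch(data, idx)
    out <- gaad_forward(model, b$x)
    pm <- prob_to_mask(out$final)
    for (j in seq_along(idx)) {
      r <- evaluate_masks(pm[, , j], b$y[, , j])
      accs <- c(accs, r$accuracy)
      ious <- c(ious, r$mean_iou)
      dscs <- c(dscs, r$mean_dsc)
    }
  }
  c(accuracy = mean(accs), mean_iou = mean(ious), mean_dsc = mean(dscs))
}

#' Train a GAAD-U-Net
#'
#' Optimizes the weighted sum of soft Dice losses on the Phase-1, Phase-2
#' and fused output maps with Adam under polynomial learning-rate decay.
#' All randomness (initialization, shuffling, augmentation) derives from
#' `cfg$seed`, so identical configurations reproduce identical runs.
#'
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @param train_data List of `list(image, mask)` pairs (e.g. from
#'   [synth_dataset()]).
#' @param val_data Optional validation list; when given, the checkpoint
#'   keeps the best mean-validation-DSC parameters.
#' @param steps Optional hard cap on total optimization steps (overrides
#'   `epochs * steps_per_epoch` when smaller scheduling is wanted).
#' @param model Optional pre-built [gaad_model()] to continue training.
#' @param verbose Print one line per epoch.
#' @return A list with `model`, `log` (one row per epoch: losses, learning
#'   rate, train/validation accuracy/IoU/DSC) and `checkpoint_path`.
#' @export
train_gaad <- function(model_cfg, cfg, train_data, val_data = NULL,
                       steps = NULL, model = NULL, verbose = FALSE) {
  if (length(train_data) == 0L) stop("train_gaad: empty training set")
  set.seed(cfg$seed)
  if (is.null(model)) model <- gaad_model(model_cfg)
  params <- collect_params(model)
  opt <- adam_state(params)
  spe <- ceiling(length(train_data) / cfg$batch_size)
  total_steps <- if (is.null(steps)) cfg$epochs * spe else steps
  n_epochs <- if (is.null(steps)) cfg$epochs else ceiling(steps / spe)
  step <- 0L
  log <- NULL
  best_dsc <- -Inf
  lw <- cfg$loss_weights
  for (ep in seq_len(n_epochs)) {
    ord <- sample(length(train_data))
    ep_loss <- numeric(0)
    lr <- NA_real_
    for (s in seq(1, length(ord), by = cfg$batch_size)) {
      if (step >= total_steps) break
      idx <- ord[s:min(length(ord), s + cfg$batch_size - 1)]
      b <- stack_batch(train_data, idx)
      if (!is.null(cfg$augmentation)) {
        for (j in seq_along(idx)) {
          a <- augment_pair(b$x[, , , j], b$y[, , j], cfg$augmentation,
                            seed = cfg$seed * 1000L + step * 64L + j)
          b$x[, , , j] <- a$image
          b$y[, , j] <- a$gt
        }
      }
      lr <- poly_lr(step, total_steps, cfg$learning_rate, cfg$lr_power)
      zero_grads(params)
      loss_val <- with_tape({
        out <- gaad_forward(model, ag_tensor(b$x), training = TRUE,
                            gt_mask = b$y,
                            teacher_forcing = cfg$teacher_forcing)
        l1 <- ag_dice_loss(out$out1, b$y)
        l2 <- ag_dice_loss(out$out2, b$y)
        l3 <- ag_dice_loss(out$final, b$y)
        loss <- ag_wsum(list(l1, l2, l3), lw)
        ag_backward(loss)
        loss$v
      })
      if (!is.finite(loss_val))
        stop("train_gaad: non-finite loss at step ", step,
             " (lr = ", lr, "); aborting")
      opt <- adam_step(opt, lr)
      ep_loss <- c(ep_loss, loss_val)
      step <- step + 1L
    }
    do_eval <- ep %% (cfg$eval_every %||% 1L) == 0L || ep == n_epochs ||
      step >= total_steps
    tr <- if (do_eval) dataset_scores(model, train_data) else
      c(accuracy = NA, mean_iou = NA, mean_dsc = NA)
    va <- if (do_eval && !is.null(val_data)) dataset_scores(model, val_data) else
      c(accuracy = NA, mean_iou = NA, mean_dsc = NA)
    log <- rbind(log, data.frame(
      epoch = ep, steps = step, loss = mean(ep_loss), lr = lr,
      train_accuracy = tr["accuracy"], train_iou = tr["mean_iou"],
      train_dsc = tr["mean_dsc"], val_accuracy = va["accuracy"],
      val_iou = va["mean_iou"], val_dsc = va["mean_dsc"],
      row.names = NULL))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  lr %.2e  train DSC %.4f  val DSC %s",
                      ep, mean(ep_loss), lr, tr["mean_dsc"],
                      ifelse(is.na(va["mean_dsc"]), "-",
                             sprintf("%.4f", va["mean_dsc"]))))
    if (!is.null(cfg$checkpoint_path) && do_eval) {
      score <- if (!is.null(val_data)) va["mean_dsc"] else tr["mean_dsc"]
      if (is.na(score)) score <- -Inf
      if (score >= best_dsc) {
        best_dsc <- score
        save_checkpoint(model, cfg$checkpoint_path)
      }
    }
    if (step >= total_steps) break
  }
  list(model = model, log = log, checkpoint_path = cfg$checkpoint_path)
}

#' Predict class masks for a batch of images
#'
#' @param model A [gaad_model()] or a checkpoint path.
#' @param images A list of `(H, W, 3)` arrays, or one such array.
#' @param batch Images per forward pass.
#' @return A list of `(H, W)` integer class masks over \{0, 1, 2\}.
#' @export
predict_gaad <- function(model, images, batch = 4L) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!is.list(images)) images <- list(images)
  out <- vector("list", length(images))
  for (s in seq(1, length(images), by = batch)) {
    idx <- s:min(length(images), s + batch - 1)
    H <- dim(images[[idx[1]]])[1]; W <- dim(images[[idx[1]]])[2]
    x <- array(0, c(H, W, 3, length(idx)))
    for (j in seq_along(idx)) x[, , , j] <- images[[idx[j]]]
    pm <- prob_to_mask(gaad_forward(model, x)$final)
    for (j in seq_along(idx)) out[[idx[j]]] <- pm[, , j]
  }
  out
}

#' Evaluate a model over a paired dataset
#'
#' Runs prediction on every image with a ground-truth mask and aggregates
#' [evaluate_masks()] reports; the summary row is the mean of the per-image
#' rows.  Entries with a missing mask are listed in `skipped`.
#'
#' @param model A [gaad_model()] or checkpoint path.
#' @param dataset A list of `list(image, mask)` entries (mask may be `NULL`
#'   or missing, in which case the image is skipped).
#' @param exclude_background Passed to [evaluate_masks()].
#' @return A list of class `wbc_eval` with `per_image` (data frame),
#'   `summary` (named means) and `skipped` (indices without masks).
#' @export
evaluate_dataset <- function(model, dataset, exclude_background = FALSE) {
  if (is.character(model)) model <- load_checkpoint(model)
  has_mask <- vapply(dataset, function(d) !is.null(d$mask), logical(1))
  skipped <- which(!has_mask)
  keep <- which(has_mask)
  preds <- predict_gaad(model, lapply(dataset[keep], `[[`, "image"))
  rows <- lapply(seq_along(keep), function(j) {
    r <- evaluate_masks(preds[[j]], dataset[[keep[j]]]$mask,
                        exclude_background = exclude_background)
    data.frame(index = keep[j], accuracy = r$accuracy, mean_iou = r$mean_iou,
               mean_dsc = r$mean_dsc, mean_hd95 = r$mean_hd95,
               mean_assd = r$mean_assd)
  })
  per_image <- do.call(rbind, rows)
  summary <- colMeans(per_image[, -1, drop = FALSE])
  structure(list(per_image = per_image, summary = summary, skipped = skipped),
            class = "wbc_eval")
}

#' @export
print.wbc_eval <- function(x, ...) {
  cat("Dataset evaluation over", nrow(x$per_image), "images",
      if (length(x$skipped)) paste0("(", length(x$skipped), " skipped)"), "\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Write an evaluation report to CSV and/or JSON
#'
#' The CSV holds one row per image plus a `summary` row; the JSON mirrors
#' the full report structure.
#'
#' @param report A `wbc_eval` from [evaluate_dataset()].
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_eval_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    df <- report$per_image
    df$index <- as.character(df$index)
    sm <- data.frame(index = "summary", t(report$summary))
    names(sm) <- names(df)
    utils::write.csv(rbind(df, sm), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(per_image = report$per_image,
                              summary = as.list(report$summary),
                              skipped = report$skipped),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

# ---- checkpointing --------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save model parameters and configuration to a single file
#'
#' @param model A [gaad_model()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  params <- collect_params(model)
  states <- collect_bn_states(model)
  saveRDS(list(format = "gaadunet_checkpoint",
               version = CHECKPOINT_VERSION,
               config = model$cfg,
               params = lapply(params, function(p) p$v),
               bn_states = lapply(states, function(s)
                 list(mean = s$mean, var = s$var))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Rebuilds the model from the embedded configuration and restores all
#' parameters and batch-norm running statistics; validates the file format
#' and version.
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A [gaad_model()].
#' @export
load_checkpoint <- function(path) {
  ck <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("load_checkpoint: cannot read '", path, "': ", conditionMessage(e)))
  if (!is.list(ck) || !identical(ck$format, "gaadunet_checkpoint"))
    stop("load_checkpoint: '", path, "' is not a gaadunet checkpoint")
  if (!identical(ck$version, CHECKPOINT_VERSION))
    stop("load_checkpoint: checkpoint version ", ck$version,
         " is not supported (expected ", CHECKPOINT_VERSION, ")")
  model <- gaad_model(ck$config)
  params <- collect_params(model)
  if (length(params) != length(ck$params))
    stop("load_checkpoint: parameter count mismatch (config incompatibility)")
  for (i in seq_along(params)) {
    if (!identical(dim(params[[i]]$v), dim(ck$params[[i]])) &&
        length(params[[i]]$v) != length(ck$params[[i]]))
      stop("load_checkpoint: parameter ", i, " shape mismatch")
    params[[i]]$v <- ck$params[[i]]
  }
  states <- collect_bn_states(model)
  for (i in seq_along(states)) {
    states[[i]]$mean <- ck$bn_states[[i]]$mean
    states[[i]]$var <- ck$bn_states[[i]]$var
  }
  model
}

# ---- mask / image file I/O -----------------------------------------------

#' Read/write class masks and images as PNG
#'
#' Masks are stored as single-channel 8-bit PNGs whose gray levels are the
#' class indices (0, 1, 2).  [mask_to_color()] renders the two display
#' palettes used for visual inspection: `"blue_red"` (nucleus blue,
#' cytoplasm red) and `"white_gray"` (nucleus white, cytoplasm gray).
#'
#' @param mask `(H, W)` integer class matrix.
#' @param path File path.
#' @return `read_mask_png()` returns an integer matrix; `write_mask_png()`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask) / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' @rdname write_mask_png
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

#' @rdname write_mask_png
#' @param palette `"blue_red"` or `"white_gray"`.
#' @export
mask_to_color <- function(mask, palette = c("blue_red", "white_gray")) {
  palette <- match.arg(palette)
  cols <- if (palette == "blue_red") {
    list(bg = c(0, 0, 0), cyto = c(1, 0, 0), nuc = c(0, 0, 1))
  } else {
    list(bg = c(0, 0, 0), cyto = c(0.5, 0.5, 0.5), nuc = c(1, 1, 1))
  }
  out <- array(0, c(nrow(mask), ncol(mask), 3))
  for (c in 1:3) {
    pl <- matrix(cols$bg[c], nrow(mask), ncol(mask))
    pl[mask == 1L] <- cols$cyto[c]
    pl[mask == 2L] <- cols$nuc[c]
    out[, , c] <- pl
  }
  out
}

#' Load a paired image/mask dataset from directories
#'
#' Expects `images/*.png` with masks of the same file name under `masks/`.
#' Images without a matching mask get `mask = NULL` (reported as skipped by
#' [evaluate_dataset()]).
#'
#' @param dir Dataset root containing `images/` and `masks/`.
#' @return A list of `list(image, mask, name)` entries.
#' @export
load_dataset_dir <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), pattern = "\\.png$",
                          full.names = TRUE))
  if (!length(imgs)) stop("load_dataset_dir: no images under ", dir)
  lapply(imgs, function(f) {
    mf <- file.path(dir, "masks", basename(f))
    list(image = read_image_png(f),
         mask = if (file.exists(mf)) read_mask_png(mf),
         name = basename(f))
  })
}

#' Write a synthetic dataset to disk
#'
#' Produces `images/*.png`, `masks/*.png` (gray-level class indices) and a
#' `manifest.csv` with file name, seed and cell count per scene.
#'
#' @param n Number of scenes.
#' @param spec A [scene_spec()].
#' @param seed Base seed (scene `i` uses `seed + i - 1`).
#' @param dir Output directory.
#' @return The manifest data frame, invisibly.
#' @export
write_synth_dataset <- function(n, spec, seed, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(filename = character(0), seed = integer(0),
                         n_cells = integer(0))
  for (i in seq_len(n)) {
    sc <- generate_scene(spec, seed = seed + i - 1L)
    fn <- sprintf("scene_%04d.png", i)
    write_image_png(sc$image, file.path(dir, "images", fn))
    write_mask_png(sc$mask, file.path(dir, "masks", fn))
    manifest <- rbind(manifest, data.frame(filename = fn, seed = seed + i - 1L,
                                           n_cells = sc$n_cells))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
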