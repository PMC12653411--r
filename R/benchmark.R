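# Small-scale capacity benchmark: a width-reduced GAAD-U-Net must be able to
# memorize a handful of synthetic scenes.  Shared by the test suite and the
# acceptance script so both exercise the identical configuration.

#' Width-reduced overfitting benchmark
#'
#' Trains a width-reduced GAAD-U-Net (encoder widths 16/32/64/128, i.e. the
#' reference widths divided by four) for a fixed number of Adam steps on a
#' small set of synthetic 96x96 scenes, then evaluates the mean Dice of the
#' final output map on those same scenes.  A healthy implementation
#' memorizes this set (train DSC > 0.9); failure indicates broken gradients
#' or a dead branch.
#'
#' @param seed Seed for scene generation, initialization and shuffling.
#' @param steps Optimization steps (default 200).
#' @param n_scenes Number of training scenes (default 8).
#' @param batch_size Images per step (default 2).
#' @param learning_rate Adam learning rate for this small-batch benchmark
#'   (default 1e-2).
#' @return A list with `train_dsc`, the per-epoch `log`, the trained
#'   `model`, and the scene list `data`.
#' @export
overfit_benchmark <- function(seed = 1L, steps = 200L, n_scenes = 8L,
                              batch_size = 2L, learning_rate = 1e-2) {
  spec <- scene_spec(image_size = c(96L, 96L), n_cells = c(1L, 3L),
                     cytoplasm_radius = c(10, 16))
  data <- synth_dataset(n_scenes, spec, seed = 1000L * seed)
  mc <- model_config(input_size = c(96L, 96L),
                     encoder1_widths = c(16L, 32L, 64L, 128L),
                     encoder2_widths = c(16L, 32L, 64L, 128L),
                     decoder_widths = c(64L, 32L, 16L, 8L))
  tc <- train_config(epochs = ceiling(steps / ceiling(n_scenes / batch_size)),
                     batch_size = batch_size, learning_rate = learning_rate,
                     seed = seed, eval_every = 10L)
  fit <- train_gaad(mc, tc, data, steps = steps)
  list(train_dsc = utils::tail(fit$log$train_dsc, 1), log = fit$log,
       model = fit$model, data = data)
}
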