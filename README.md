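# gaadunet

Gated attention-augmented Double U-Net (GAAD-U-Net) for white blood cell
segmentation, in R.

Stained-smear microscopy images are segmented per pixel into three classes
— background (0), cytoplasm (1) and nucleus (2). Separating cytoplasm from
the surrounding blood components is the hard part: boundaries are
low-contrast, cells touch and overlap, and staining varies between
laboratories. GAAD-U-Net addresses this with a two-phase (double)
encoder–decoder architecture whose bottlenecks run a sequential refinement
cascade:

1. **attention-augmented convolution (AAC)** — the channel-wise
   concatenation of a standard convolution with multi-head self-attention
   over all spatial positions,
   `y_aac = Concat(Conv2D(x), Attention(x))`, where per-head logits are
   `(q·k + q·(r_row + r_col)) / sqrt(d_k)` with learnable relative-offset
   embeddings `r_row`, `r_col`;
2. **gating** — `z = x ⊙ σ(Conv₂(ReLU(BN(Conv₁(x)))))`, an elementwise
   multiplicative mask that suppresses irrelevant activations; and
3. **ASPP** — parallel dilated convolutions (rates 6/12/18) plus 1×1 and
   image-pooling branches for multi-scale context.

Phase 1 is a VGG-19-style encoder (blocks of 2/2/4/4 convolutions, 2×2
pooling after the first three, so the bottleneck sits at 1/8 resolution —
28×28 for 224×224 inputs) with a squeeze-and-excitation decoder. Phase 2
re-encodes the image gated by Phase 1's predicted foreground and its
decoder concatenates three inputs per block: upsampled features, the
Phase-2 encoder skip, and the matching Phase-1 decoder output. A 1×1
convolution fuses both phase outputs into the final three-class softmax
map.

The package also provides the full evaluation suite (pixel accuracy, IoU,
DSC, 95th-percentile Hausdorff distance and average symmetric surface
distance, with explicit boundary-extraction and aggregation conventions),
the multi-class soft Dice training objective, Adam with polynomial
learning-rate decay, a synthetic stained-smear scene generator plus the
flip/rotate/noise/brightness augmentation policy, and a command-line
interface — everything runs on one CPU with no dataset downloads, on top
of a compact reverse-mode autodiff engine with C++ (RcppArmadillo)
kernels.

## Worked example

Train a width-reduced model on eight synthetic 96×96 scenes and evaluate
on four held-out scenes (about five minutes on one CPU):

```r
library(gaadunet)
spec  <- scene_spec(image_size = c(96L, 96L), n_cells = c(1L, 3L),
                    cytoplasm_radius = c(10, 16))
train <- synth_dataset(8, spec, seed = 1000)

mc  <- model_config(input_size = c(96L, 96L),
                    encoder1_widths = c(16L, 32L, 64L, 128L),
                    encoder2_widths = c(16L, 32L, 64L, 128L),
                    decoder_widths  = c(64L, 32L, 16L, 8L))
tc  <- train_config(batch_size = 2, learning_rate = 1e-2, seed = 1,
                    eval_every = 10)
fit <- train_gaad(mc, tc, train, steps = 200)

test   <- synth_dataset(4, spec, seed = 2000)
report <- evaluate_dataset(fit$model, test)
print(report)
```

```
Dataset evaluation over 4 images
 accuracy  mean_iou  mean_dsc mean_hd95 mean_assd
   0.9950    0.9563    0.9742    0.4408    0.1236
```

`accuracy` is the fraction of correctly labeled pixels; `mean_iou` and
`mean_dsc` are macro means over the three classes (`DSC = 2·IoU/(1+IoU)`
per class); `mean_hd95` and `mean_assd` are boundary distances in pixels
(0 = perfect contours), macro-averaged over the two foreground classes.

Single-image reports break the numbers down per class:

```r
pred <- predict_gaad(fit$model, test[[1]]$image)[[1]]
evaluate_masks(pred, test[[1]]$mask)
```

```
Segmentation metrics (macro mean)
  accuracy 0.9888  mean IoU 0.8667  mean DSC 0.9181
  mean HD95 1.1180 px  mean ASSD 0.3303 px
 class       iou       dsc  accuracy     hd95       assd flag
     0 0.9884130 0.9941728 0.9889323       NA         NA   ok
     1 0.6156716 0.7621247 0.9888238 2.236068 0.63982378   ok
     2 0.9959677 0.9979798 0.9998915 0.000000 0.02083333   ok
```

The same pipeline is scriptable from a shell via the bundled CLI:

```sh
GAAD=$(Rscript -e 'cat(system.file("cli", "gaad.R", package = "gaadunet"))')
Rscript $GAAD synth   --out data --seed 7 --n 16
Rscript $GAAD train   --data data --checkpoint model.rds --seed 7
Rscript $GAAD predict --checkpoint model.rds --data data --out pred
Rscript $GAAD eval    --checkpoint model.rds --data data --out report
```

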