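# Synthetic stained-smear scene generator.
#
# Scenes emulate the challenges of white-blood-cell benchmark imagery:
# elliptical leukocytes whose dark-stained nucleus sits strictly inside a
# paler cytoplasm, variable stain color/brightness/contrast, textured
# backgrounds with red-blood-cell-like distractor blobs (labeled
# background), optional cell adhesion, and additive Gaussian pixel noise.
# Labels: 0 = background, 1 = cytoplasm, 2 = nucleus; conflicts resolve
# nucleus > cytoplasm > background.

#' Scene specification for the synthetic generator
#'
#' @param image_size Integer `(rows, cols)`.
#' @param n_cells Cell count, or a `(min, max)` range sampled uniformly.
#' @param cytoplasm_radius `(min, max)` major-axis radius in pixels.
#' @param nucleus_fraction `(min, max)` ratio of nucleus to cytoplasm radius,
#'   in (0, 1); with a ratio below 1 every nucleus lies strictly inside its
#'   cytoplasm.
#' @param stain_palette Named list of RGB triplets in `[0, 1]`:
#'   `background`, `cytoplasm`, `nucleus`, `distractor`.
#' @param brightness_jitter `(min, max)` additive brightness offset.
#' @param noise_sigma `(min, max)` Gaussian pixel-noise standard deviation
#'   (fraction of dynamic range).
#' @param allow_overlap Permit adjacent/overlapping cells.
#' @param distractor_density Expected red-blood-cell-like blobs per pixel
#'   (they stay labeled background).
#' @param seed Optional integer default seed for [generate_scene()].
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size = c(128L, 128L),
                       n_cells = c(1L, 4L),
                       cytoplasm_radius = c(16, 28),
                       nucleus_fraction = c(0.45, 0.7),
                       stain_palette = list(
                         background = c(0.93, 0.88, 0.92),
                         cytoplasm = c(0.76, 0.62, 0.84),
                         nucleus = c(0.36, 0.18, 0.52),
                         distractor = c(0.88, 0.58, 0.58)),
                       brightness_jitter = c(-0.12, 0.12),
                       noise_sigma = c(0.01, 0.03),
                       allow_overlap = FALSE,
                       distractor_density = 2e-4,
                       seed = NULL) {
  if (length(n_cells) == 1L) n_cells <- c(n_cells, n_cells)
  stopifnot(all(image_size >= 16), nucleus_fraction[1] > 0,
            nucleus_fraction[2] < 1, cytoplasm_radius[1] > 2)
  structure(list(image_size = as.integer(image_size),
                 n_cells = as.integer(n_cells),
                 cytoplasm_radius = cytoplasm_radius,
                 nucleus_fraction = nucleus_fraction,
                 stain_palette = stain_palette,
                 brightness_jitter = brightness_jitter,
                 noise_sigma = noise_sigma,
                 allow_overlap = isTRUE(allow_overlap),
                 distractor_density = distractor_density,
                 seed = seed),
            class = "scene_spec")
}

# Run expr under a private RNG stream, restoring the caller's stream after.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Membership of grid pixels in a rotated ellipse (pixel centers, 0-based).
ellipse_mask <- function(H, W, cy, cx, a, b, theta) {
  ys <- matrix(seq_len(H) - 1, H, W) - cy
  xs <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
  u <- ys * cos(theta) + xs * sin(theta)
  v <- -ys * sin(theta) + xs * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

jitter_color <- function(base, sd = 0.04) pmin(1, pmax(0, base + stats::rnorm(3, 0, sd)))

# clamp to [0, 1] preserving the dim attribute (pmin/pmax drop it)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Generate one synthetic stained-smear scene
#'
#' Renders `n_cells` elliptical cells (cytoplasm label 1 enclosing one
#' nucleus label 2 each) over a textured background with distractor blobs,
#' applies per-cell stain-color jitter, a scene-wide brightness offset and
#' additive Gaussian noise.  The same `spec` and `seed` always reproduce the
#' scene exactly.
#'
#' @param spec A [scene_spec()].
#' @param seed Integer seed (defaults to `spec$seed`); required for
#'   reproducibility.
#' @return A list with `image` (`(H, W, 3)` array in `[0, 1]`), `mask`
#'   (`(H, W)` integer matrix over \{0, 1, 2\}), and `n_cells`.
#' @export
generate_scene <- function(spec, seed = spec$seed) {
  if (is.null(seed)) stop("generate_scene: a seed is required")
  with_seed(seed, {
    H <- spec$image_size[1]; W <- spec$image_size[2]
    n <- if (spec$n_cells[1] == spec$n_cells[2]) spec$n_cells[1] else
      sample(spec$n_cells[1]:spec$n_cells[2], 1)
    # place cells, rejecting overlaps unless allowed
    cells <- list()
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        a <- stats::runif(1, spec$cytoplasm_radius[1], spec$cytoplasm_radius[2])
        b <- a * stats::runif(1, 0.7, 1)
        theta <- stats::runif(1, 0, pi)
        margin <- a + 2
        if (2 * margin >= min(H, W)) margin <- min(H, W) / 2 - 1
        cy <- stats::runif(1, margin, H - 1 - margin)
        cx <- stats::runif(1, margin, W - 1 - margin)
        ok <- TRUE
        if (!spec$allow_overlap && length(cells)) {
          for (cl in cells) {
            if (sqrt((cy - cl$cy)^2 + (cx - cl$cx)^2) < a + cl$a + 3) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) {
          frac <- stats::runif(1, spec$nucleus_fraction[1], spec$nucleus_fraction[2])
          # offset keeps the nucleus ellipse >= 2 px inside the cytoplasm
          omax <- max(0, (1 - frac) * min(a, b) - 2)
          oang <- stats::runif(1, 0, 2 * pi)
          orad <- stats::runif(1, 0, omax)
          cells[[length(cells) + 1L]] <- list(
            cy = cy, cx = cx, a = a, b = b, theta = theta, frac = frac,
            ncy = cy + orad * cos(oang), ncx = cx + orad * sin(oang))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("generate_scene: could not place ", n, " non-overlapping cells",
             " in a ", H, "x", W, " scene; enlarge the image, reduce",
             " n_cells, or set allow_overlap = TRUE")
    }
    mask <- matrix(0L, H, W)
    for (cl in cells)
      mask[ellipse_mask(H, W, cl$cy, cl$cx, cl$a, cl$b, cl$theta) & mask == 0L] <- 1L
    for (cl in cells)
      mask[ellipse_mask(H, W, cl$ncy, cl$ncx, cl$a * cl$frac, cl$b * cl$frac,
                        cl$theta)] <- 2L
    # background: base stain tone + coarse blockwise texture
    pal <- spec$stain_palette
    img <- array(0, c(H, W, 3))
    blk <- 8L
    tex <- matrix(stats::rnorm(ceiling(H / blk) * ceiling(W / blk), 0, 0.02),
                  ceiling(H / blk), ceiling(W / blk))
    tex <- tex[rep(seq_len(nrow(tex)), each = blk)[seq_len(H)],
               rep(seq_len(ncol(tex)), each = blk)[seq_len(W)]]
    for (c in 1:3) img[, , c] <- pal$background[c] + tex
    # red-blood-cell-like distractors stay labeled background
    nd <- stats::rpois(1, spec$distractor_density * H * W)
    for (k in seq_len(nd)) {
      r <- stats::runif(1, 4, 9)
      cy <- stats::runif(1, 0, H - 1)
      cx <- stats::runif(1, 0, W - 1)
      ring <- ellipse_mask(H, W, cy, cx, r, r, 0) &
        !ellipse_mask(H, W, cy, cx, r * 0.45, r * 0.45, 0)
      col <- jitter_color(pal$distractor)
      for (c in 1:3) {
        pl <- img[, , c]
        pl[ring] <- 0.35 * pl[ring] + 0.65 * col[c]
        img[, , c] <- pl
      }
    }
    for (cl in cells) {
      cyto <- ellipse_mask(H, W, cl$cy, cl$cx, cl$a, cl$b, cl$theta)
      nuc <- ellipse_mask(H, W, cl$ncy, cl$ncx, cl$a * cl$frac,
                          cl$b * cl$frac, cl$theta)
      ccol <- jitter_color(pal$cytoplasm)
      ncol_ <- jitter_color(pal$nucleus)
      for (c in 1:3) {
        pl <- img[, , c]
        pl[cyto] <- ccol[c]
        pl[nuc] <- ncol_[c]
        img[, , c] <- pl
      }
    }
    img <- img + stats::runif(1, spec$brightness_jitter[1],
                              spec$brightness_jitter[2])
    sig <- stats::runif(1, spec$noise_sigma[1], spec$noise_sigma[2])
    img <- img + array(stats::rnorm(H * W * 3, 0, sig), c(H, W, 3))
    img <- clamp01(img)
    list(image = img, mask = mask, n_cells = n)
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Scene `i` uses seed `seed + i - 1`, so any element can be regenerated
#' independently.
#'
#' @param n Number of scenes.
#' @param spec A [scene_spec()].
#' @param seed Base seed.
#' @return A list of [generate_scene()] results.
#' @export
synth_dataset <- function(n, spec = scene_spec(), seed = 1L) {
  lapply(seq_len(n), function(i) generate_scene(spec, seed = seed + i - 1L))
}

#' Augmentation policy configuration
#'
#' Geometric operations (horizontal flip, vertical flip, rotation) apply
#' identically to image and mask; photometric operations (Gaussian noise,
#' brightness offset) apply to the image only.  Each operation fires
#' independently with its configured probability (all default 0.5).
#'
#' @param p_hflip,p_vflip,p_rotate,p_noise,p_brightness Firing
#'   probabilities in `[0, 1]`.
#' @param angles Rotation angle set in degrees; the default
#'   `c(90, 180, 270)` needs no mask interpolation.  Any other angle uses
#'   nearest-neighbor resampling for both image and mask.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param brightness_delta `(min, max)` additive brightness range.
#' @return A list of class `augmentation_config`.
#' @export
augmentation_config <- function(p_hflip = 0.5, p_vflip = 0.5, p_rotate = 0.5,
                                p_noise = 0.5, p_brightness = 0.5,
                                angles = c(90, 180, 270),
                                noise_sigma = 0.02,
                                brightness_delta = c(-0.15, 0.15)) {
  ps <- c(p_hflip, p_vflip, p_rotate, p_noise, p_brightness)
  if (any(ps < 0 | ps > 1)) stop("augmentation_config: probabilities must be in [0, 1]")
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip, p_rotate = p_rotate,
                 p_noise = p_noise, p_brightness = p_brightness,
                 angles = angles, noise_sigma = noise_sigma,
                 brightness_delta = brightness_delta),
            class = "augmentation_config")
}

rot90k <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) {
    m <- if (length(dim(m)) == 2L) t(m[nrow(m):1, , drop = FALSE])
    else aperm(m[nrow(m):1, , , drop = FALSE], c(2, 1, 3))
  }
  m
}

# Nearest-neighbor rotation about the image center; out-of-bounds pixels
# fall back to background (label 0 / value 0).
rotate_nn <- function(m, angle_deg) {
  H <- nrow(m); W <- ncol(m)
  th <- -angle_deg * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  ys <- matrix(seq_len(H) - 1, H, W) - cy
  xs <- matrix(rep(seq_len(W) - 1, each = H), H, W) - cx
  sy <- round(cy + ys * cos(th) - xs * sin(th)) + 1
  sx <- round(cx + ys * sin(th) + xs * cos(th)) + 1
  ok <- sy >= 1 & sy <= H & sx >= 1 & sx <= W
  idx <- cbind(as.vector(pmin(pmax(sy, 1), H)), as.vector(pmin(pmax(sx, 1), W)))
  if (length(dim(m)) == 2L) {
    out <- matrix(m[idx], H, W)
    out[!ok] <- 0
    out
  } else {
    out <- array(0, dim(m))
    for (c in seq_len(dim(m)[3])) {
      pl <- matrix(m[, , c][idx], H, W)
      pl[!ok] <- 0
      out[, , c] <- pl
    }
    out
  }
}

#' Apply the augmentation policy to an image/mask pair
#'
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param gt `(H, W)` integer label matrix.
#' @param cfg An [augmentation_config()].
#' @param seed Integer seed for the operation draws.
#' @return A list with the augmented `image` and `gt` plus `fired`, a named
#'   logical vector recording which operations fired.
#' @export
augment_pair <- function(image, gt, cfg = augmentation_config(), seed) {
  with_seed(seed, {
    fired <- c(hflip = stats::runif(1) < cfg$p_hflip,
               vflip = stats::runif(1) < cfg$p_vflip,
               rotate = stats::runif(1) < cfg$p_rotate,
               noise = stats::runif(1) < cfg$p_noise,
               brightness = stats::runif(1) < cfg$p_brightness)
    if (fired["hflip"]) {
      image <- image[, ncol(gt):1, , drop = FALSE]
      gt <- gt[, ncol(gt):1, drop = FALSE]
    }
    if (fired["vflip"]) {
      image <- image[nrow(gt):1, , , drop = FALSE]
      gt <- gt[nrow(gt):1, , drop = FALSE]
    }
    if (fired["rotate"]) {
      ang <- if (length(cfg$angles) == 1L) cfg$angles else sample(cfg$angles, 1)
      if (ang %% 90 == 0 && nrow(gt) == ncol(gt)) {
        k <- (ang %/% 90) %% 4
        image <- rot90k(image, k)
        gt <- rot90k(gt, k)
      } else {
        image <- rotate_nn(image, ang)
        gt <- rotate_nn(gt, ang)
      }
    }
    if (fired["noise"])
      image <- image + array(stats::rnorm(length(image), 0, cfg$noise_sigma),
                             dim(image))
    if (fired["brightness"])
      image <- image + stats::runif(1, cfg$brightness_delta[1],
                                    cfg$brightness_delta[2])
    list(image = clamp01(image), gt = gt, fired = fired)
  })
}
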