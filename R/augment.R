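#' Augmentation configuration
#'
#' Six stochastic transforms applied independently per image during training
#' (and never at inference): randomly applied histogram equalisation,
#' randomly applied saturation scaling, additive Gaussian noise, random
#' horizontal/vertical flips, random translation in x only (at most 20% of
#' the image width), and random zoom (at most 30%). Translation in y is
#' deliberately absent: the centre-crop layer removes x-translation
#' artefacts but would leave y artefacts in place. Zoom and translation
#' fill exposed regions by edge replication, to avoid introducing border
#' artefacts that a saliency analysis would latch onto.
#'
#' @param p_hist_equalise,p_saturation,p_flip_h,p_flip_v Per-image
#'   application probabilities.
#' @param saturation_range Saturation factor range (uniform draw).
#' @param noise_sigma SD of additive Gaussian noise (intensity units on
#'   `[0, 1]`); 0 disables.
#' @param max_x_translation Maximum |shift| as a fraction of width.
#' @param max_zoom Maximum zoom in/out fraction.
#' @param seed Integer seed, or `NULL` to use the ambient RNG stream.
#' @export
augmentation_config <- function(p_hist_equalise = 0.5, p_saturation = 0.5,
                                saturation_range = c(0.6, 1.4),
                                noise_sigma = 0.02,
                                p_flip_h = 0.5, p_flip_v = 0.5,
                                max_x_translation = 0.20, max_zoom = 0.30,
                                seed = NULL) {
  probs <- c(p_hist_equalise, p_saturation, p_flip_h, p_flip_v)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (max_x_translation < 0 || max_zoom < 0 || noise_sigma < 0) {
    stop("magnitudes must be non-negative")
  }
  structure(list(p_hist_equalise = p_hist_equalise,
                 p_saturation = p_saturation,
                 saturation_range = saturation_range,
                 noise_sigma = noise_sigma,
                 p_flip_h = p_flip_h, p_flip_v = p_flip_v,
                 max_x_translation = max_x_translation, max_zoom = max_zoom,
                 seed = seed),
            class = "augmentation_config")
}

# Bilinear sampling of one channel at fractional source coordinates, with
# edge clamping (replicates border pixels outside the frame). `xs`/`ys` are
# matrices of source column/row coordinates for each output pixel.
sample_bilinear <- function(m, ys, xs) {
  h <- nrow(m); w <- ncol(m)
  ys <- pmin(pmax(ys, 1), h)
  xs <- pmin(pmax(xs, 1), w)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  fy <- ys - y0; fx <- xs - x0
  v00 <- m[cbind(as.vector(y0), as.vector(x0))]
  v01 <- m[cbind(as.vector(y0), as.vector(x1))]
  v10 <- m[cbind(as.vector(y1), as.vector(x0))]
  v11 <- m[cbind(as.vector(y1), as.vector(x1))]
  out <- v00 * (1 - fy) * (1 - fx) + v01 * (1 - fy) * fx +
    v10 * fy * (1 - fx) + v11 * fy * fx
  matrix(out, nrow(ys), ncol(ys))
}

# Direct bilinear resize (centre-aligned). Identity when sizes match.
bilinear_resize <- function(m, out_h, out_w) {
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  ys <- matrix((seq_len(out_h) - 0.5) * nrow(m) / out_h + 0.5,
               out_h, out_w)
  xs <- matrix((seq_len(out_w) - 0.5) * ncol(m) / out_w + 0.5,
               out_h, out_w, byrow = TRUE)
  sample_bilinear(m, ys, xs)
}

equalise_channel <- function(v) {
  stats::ecdf(v)(v)
}

augment_one <- function(img, cfg) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  if (stats::runif(1) < cfg$p_hist_equalise) {
    for (c in seq_len(nc)) {
      img[, , c] <- equalise_channel(img[, , c])
    }
  }
  if (stats::runif(1) < cfg$p_saturation) {
    f <- stats::runif(1, cfg$saturation_range[1], cfg$saturation_range[2])
    gray <- apply(img, c(1, 2), mean)
    for (c in seq_len(nc)) {
      img[, , c] <- gray + f * (img[, , c] - gray)
    }
  }
  if (cfg$noise_sigma > 0) {
    img <- img + stats::rnorm(length(img), 0, cfg$noise_sigma)
  }
  if (stats::runif(1) < cfg$p_flip_h) {
    img <- img[, w:1, , drop = FALSE]
  }
  if (stats::runif(1) < cfg$p_flip_v) {
    img <- img[h:1, , , drop = FALSE]
  }
  if (cfg$max_x_translation > 0) {
    dx <- round(stats::runif(1, -1, 1) * cfg$max_x_translation * w)
    if (dx != 0) {
      src <- pmin(pmax(seq_len(w) - dx, 1), w)
      img <- img[, src, , drop = FALSE]
    }
  }
  if (cfg$max_zoom > 0) {
    s <- stats::runif(1, 1 - cfg$max_zoom, 1 + cfg$max_zoom)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ys <- matrix((seq_len(h) - cy) / s + cy, h, w)
    xs <- matrix((seq_len(w) - cx) / s + cx, h, w, byrow = TRUE)
    for (c in seq_len(nc)) {
      img[, , c] <- sample_bilinear(img[, , c], ys, xs)
    }
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Apply the training augmentation stack to a batch
#'
#' With `training = FALSE` the batch is returned bit-identical (the
#' augmentation layers are active for training only). With
#' `training = TRUE` each of the six transforms is applied independently
#' per image with its configured probability and magnitude, and the result
#' is clipped to `[0, 1]`.
#'
#' @param batch A `(H, W, C, N)` array with intensities in `[0, 1]`.
#' @param config An [augmentation_config()].
#' @param training Apply transforms? Default `TRUE`.
#' @param seed Seed for the transform draws; defaults to `config$seed`.
#'   `NULL` draws from the ambient RNG stream (used inside training loops
#'   that are themselves seeded).
#' @return The augmented batch, same shape.
#' @export
augment_batch <- function(batch, config, training = TRUE,
                          seed = config$seed) {
  stopifnot(inherits(config, "augmentation_config"), length(dim(batch)) == 4L)
  if (!training) return(batch)
  run <- function() {
    for (n in seq_len(dim(batch)[4])) {
      batch[, , , n] <- augment_one(batch[, , , n, drop = FALSE][, , , 1],
                                    config)
    }
    batch
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
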