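#' Transfer-learning specification
#'
#' Controls partial-freeze fine-tuning on a new site: layers are unfrozen
#' from the output end backwards, whole layers at a time, until the fraction
#' of trainable parameters reaches `target_retrained_fraction`. The default
#' learning rate is five times lower than the initial-training default, to
#' keep the model from converging too quickly to a local minimum.
#'
#' @param target_retrained_fraction Fraction of model parameters to retrain,
#'   in `(0, 1]` (the reference regimes use 0.23, 0.41 and 0.68).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Fine-tuning epochs (default 1200).
#' @param seed Integer seed.
#' @export
transfer_spec <- function(target_retrained_fraction, learning_rate = 1e-4,
                          epochs = 1200, seed = 1) {
  if (!is.numeric(target_retrained_fraction) ||
      target_retrained_fraction <= 0 || target_retrained_fraction > 1) {
    stop("target_retrained_fraction must be in (0, 1]")
  }
  structure(list(target_retrained_fraction = target_retrained_fraction,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "transfer_spec")
}

# Greedy whole-layer unfreezing from the output side: unfreeze layers until
# the cumulative trainable fraction first reaches the target.
plan_unfreeze <- function(param_layer_sizes, target) {
  total <- sum(param_layer_sizes)
  k <- length(param_layer_sizes)
  unfrozen <- logical(k)
  acc <- 0
  for (i in rev(seq_len(k))) {
    unfrozen[i] <- TRUE
    acc <- acc + param_layer_sizes[i]
    if (acc / total >= target) break
  }
  list(unfrozen = unfrozen, achieved = acc / total)
}

#' Fine-tune a trained model on new data with most parameters frozen
#'
#' Unfreezes the minimal set of whole layers (from the output backwards)
#' whose parameter count meets `spec$target_retrained_fraction`, then resumes
#' MSE training on `manifest`. Frozen parameters are bit-identical before
#' and after fine-tuning.
#'
#' @param model A trained `stage_model`.
#' @param manifest Plate manifest of the new site's training wells.
#' @param spec A [transfer_spec()].
#' @param val_manifest Optional validation manifest (wells disjoint from
#'   `manifest`).
#' @param augment Optional [augmentation_config()].
#' @param batch_size Minibatch size.
#' @param verbose Print per-epoch losses.
#' @return The fine-tuned model, with `model$transfer_report`: a one-row
#'   tibble giving the target and achieved retrained fractions and the
#'   retrained layer names.
#' @export
transfer_learn <- function(model, manifest, spec, val_manifest = NULL,
                           augment = NULL, batch_size = model$config$batch_size,
                           verbose = FALSE) {
  stopifnot(inherits(model, "stage_model"), inherits(spec, "transfer_spec"))
  pc <- param_counts(model)
  plan <- plan_unfreeze(pc$params, spec$target_retrained_fraction)
  param_li <- which(!purrr::map_lgl(model$layers, ~ is.null(.x$W)))
  for (j in seq_along(param_li)) {
    model$layers[[param_li[j]]]$trainable <- plan$unfrozen[j]
  }
  tuned <- train_stage_model(model, manifest, val_manifest, augment = augment,
                             epochs = spec$epochs,
                             learning_rate = spec$learning_rate,
                             batch_size = batch_size, seed = spec$seed,
                             verbose = verbose)
  tuned$transfer_report <- tibble::tibble(
    target_retrained_fraction = spec$target_retrained_fraction,
    actual_retrained_fraction = plan$achieved,
    retrained_layers = paste(pc$layer[plan$unfrozen], collapse = ","),
    n_retrained = sum(pc$params[plan$unfrozen]),
    n_total = sum(pc$params))
  tuned
}

#' DeconvNet-style saliency map
#'
#' Attributes the model's scalar hpf prediction to input pixels by a
#' modified backward pass: at every ReLU the backward signal keeps only its
#' positive part, independent of the forward activation sign (the DeconvNet
#' rule). The per-channel result is reduced by the maximum of absolute
#' values, so the map is everywhere non-negative.
#'
#' @param model A `stage_model`.
#' @param image A `(H, W)` matrix or `(H, W, C)` array matching the model's
#'   input size (before the crop).
#' @return A `saliency_map` matrix with the spatial shape of the cropped
#'   input.
#' @export
saliency_map <- function(model, image) {
  stopifnot(inherits(model, "stage_model"))
  d <- dim(image)
  if (length(d) == 2L) image <- array(rep(image, 3L), dim = c(d, 3L))
  d <- dim(image)
  if (d[1] != model$config$input_height || d[2] != model$config$input_width) {
    stop(sprintf("image is %dx%d but the model expects %dx%d",
                 d[1], d[2], model$config$input_height,
                 model$config$input_width))
  }
  x <- array(image, dim = c(d[1], d[2], d[3], 1L))
  fwd <- nn_forward(model, x, training = FALSE, keep_cache = TRUE)
  g <- array(1, dim = dim(fwd$out))
  bwd <- nn_backward(model, fwd$cache, g, deconv = TRUE)
  gi <- bwd$g_input # (H, crop_W, C, 1)
  sal <- apply(abs(gi[, , , 1, drop = FALSE]), c(1, 2), max)
  structure(sal, class = c("saliency_map", "matrix", "array"))
}
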