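#' Configuration of the staging CNN
#'
#' The network is a compact AlexNet-descendant regressor: an x-only centre
#' crop, a rescale layer, `n_conv_units` repeating units of (3x3 convolution,
#' ReLU, 2x2 max pooling), then flatten, one fully connected ReLU layer,
#' dropout, and a single linear output neuron that predicts hpf.
#'
#' @param input_height,input_width Image size fed to the network, in pixels
#'   (width > height; the crop removes the excess width).
#' @param crop_width Width after the centre crop; defaults to `input_height`
#'   (a square crop).
#' @param n_conv_units Number of conv/ReLU/pool units.
#' @param filters_per_unit Integer vector, one filter count per unit.
#' @param dense_width Width of the fully connected layer.
#' @param dropout_rate Dropout probability in `[0, 1)` before the output.
#' @param learning_rate Adam learning rate (default 5e-4).
#' @param epochs Training epochs (default 500).
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling weight initialisation, shuffling and
#'   dropout.
#' @return A `stage_model_config` list.
#' @export
stage_model_config <- function(input_height = 224, input_width = 320,
                               crop_width = input_height,
                               n_conv_units = 5,
                               filters_per_unit = c(16, 32, 64, 128, 256),
                               dense_width = 512, dropout_rate = 0.5,
                               learning_rate = 5e-4, epochs = 500,
                               batch_size = 32, seed = 42) {
  cfg <- list(input_height = as.integer(input_height),
              input_width = as.integer(input_width),
              crop_width = as.integer(crop_width),
              n_conv_units = as.integer(n_conv_units),
              filters_per_unit = as.integer(filters_per_unit),
              dense_width = as.integer(dense_width),
              dropout_rate = dropout_rate,
              learning_rate = learning_rate,
              epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              seed = as.integer(seed))
  validate_stage_config(cfg)
  structure(cfg, class = "stage_model_config")
}

#' Desk-scale preset of the staging CNN configuration
#'
#' Three conv units with (8, 16, 32) filters on 64x96 images (cropped to
#' 64x64), a 64-wide dense layer and light dropout — small enough to train
#' on a laptop CPU in minutes while preserving the full-scale architecture.
#'
#' @param ... Overrides passed to [stage_model_config()].
#' @export
scaled_stage_config <- function(...) {
  args <- list(input_height = 64, input_width = 96, n_conv_units = 3,
               filters_per_unit = c(8, 16, 32), dense_width = 64,
               dropout_rate = 0.2, epochs = 30, batch_size = 32)
  args[names(list(...))] <- list(...)
  do.call(stage_model_config, args)
}

validate_stage_config <- function(cfg) {
  if (length(cfg$filters_per_unit) != cfg$n_conv_units) {
    stop("filters_per_unit must have one entry per conv unit")
  }
  if (any(cfg$filters_per_unit < 1)) stop("filter counts must be >= 1")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (cfg$crop_width > cfg$input_width) {
    stop("crop_width cannot exceed input_width")
  }
  h <- cfg$input_height
  w <- cfg$crop_width
  for (u in seq_len(cfg$n_conv_units)) {
    h <- h %/% 2L
    w <- w %/% 2L
    if (h < 1L || w < 1L) {
      stop(sprintf(
        "architecture error: spatial size collapses to %dx%d after %d pooling steps",
        h, w, u))
    }
  }
  invisible(cfg)
}

he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

#' Build the staging CNN
#'
#' Instantiates the network described by a [stage_model_config()], with
#' He-normal initial weights drawn from the config seed. The returned model
#' reports per-layer parameter counts via [param_counts()].
#'
#' @param config A `stage_model_config`.
#' @return A `stage_model` object.
#' @export
build_stage_model <- function(config) {
  stopifnot(inherits(config, "stage_model_config"))
  validate_stage_config(config)
  layers <- list(
    list(type = "crop_x", target_width = config$crop_width),
    list(type = "rescale", scale = 2, offset = -1)
  )
  withr::with_seed(config$seed, {
    c_in <- 3L
    for (u in seq_len(config$n_conv_units)) {
      f <- config$filters_per_unit[u]
      layers[[length(layers) + 1L]] <- list(
        type = "conv_unit", name = sprintf("conv_%d", u),
        W = he_init(9 * c_in, c(3, 3, c_in, f)), b = numeric(f),
        trainable = TRUE)
      c_in <- f
    }
    layers[[length(layers) + 1L]] <- list(type = "flatten")
    feat <- (config$input_height %/% 2L^config$n_conv_units) *
      (config$crop_width %/% 2L^config$n_conv_units) * c_in
    layers[[length(layers) + 1L]] <- list(
      type = "dense", name = "dense_1", activation = "relu",
      W = he_init(feat, c(feat, config$dense_width)),
      b = numeric(config$dense_width), trainable = TRUE)
    layers[[length(layers) + 1L]] <- list(type = "dropout",
                                          rate = config$dropout_rate)
    layers[[length(layers) + 1L]] <- list(
      type = "dense", name = "output", activation = "linear",
      W = he_init(config$dense_width, c(config$dense_width, 1L)),
      b = numeric(1L), trainable = TRUE)
  })
  structure(list(config = config, layers = layers, history = NULL),
            class = "stage_model")
}

#' Per-layer parameter counts of a staging model
#'
#' @param model A `stage_model`.
#' @return A tibble with `layer`, `params` and `trainable` columns.
#' @export
param_counts <- function(model) {
  stopifnot(inherits(model, "stage_model"))
  rows <- purrr::map(model$layers, function(lay) {
    if (is.null(lay$W)) return(NULL)
    tibble::tibble(layer = lay$name,
                   params = length(lay$W) + length(lay$b),
                   trainable = isTRUE(lay$trainable))
  })
  dplyr::bind_rows(rows)
}

#' @export
print.stage_model <- function(x, ...) {
  pc <- param_counts(x)
  cat(sprintf("<stage_model> %dx%d -> crop %d -> %d conv units -> dense %d -> 1\n",
              x$config$input_height, x$config$input_width, x$config$crop_width,
              x$config$n_conv_units, x$config$dense_width))
  cat(sprintf("  parameters: %d total, %d trainable\n",
              sum(pc$params), sum(pc$params[pc$trainable])))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs (final train loss %.3f)\n",
                nrow(x$history), utils::tail(x$history$train_loss, 1)))
  }
  invisible(x)
}

#' @export
glance.stage_model <- function(x, ...) {
  pc <- param_counts(x)
  tibble::tibble(
    n_params = sum(pc$params),
    n_trainable = sum(pc$params[pc$trainable]),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_train_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$train_loss, 1),
    final_val_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$val_loss, 1))
}

#' Centre crop in x only
#'
#' Removes equal margins from the left and right of each image, leaving the
#' height untouched (the images are wider than tall, so only x-translation
#' artefacts need removing). With an odd total margin the extra column comes
#' off the right (floor left, ceil right). Retained pixels are bit-identical
#' to the source.
#'
#' @param batch A `(H, W, C, N)` array, `(H, W, C)` array or `(H, W)` matrix.
#' @param target_width Width to keep; must not exceed the image width.
#' @return The cropped batch with the same number of dimensions.
#' @export
center_crop_x <- function(batch, target_width) {
  d <- dim(batch)
  w <- d[2]
  if (target_width > w) {
    stop(sprintf("crop width %d exceeds image width %d", target_width, w))
  }
  if (target_width == w) return(batch)
  left <- (w - target_width) %/% 2L
  cols <- (left + 1L):(left + target_width)
  if (length(d) == 2L) batch[, cols, drop = FALSE]
  else if (length(d) == 3L) batch[, cols, , drop = FALSE]
  else batch[, cols, , , drop = FALSE]
}

train_core <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                       epochs, learning_rate, batch_size, seed,
                       augment = NULL, verbose = FALSE) {
  n <- dim(x_train)[4]
  state <- adam_init(model)
  step <- 0L
  hist <- vector("list", epochs)
  withr::with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      sse <- 0
      for (b0 in seq(1L, n, by = batch_size)) {
        sel <- ord[b0:min(b0 + batch_size - 1L, n)]
        xb <- x_train[, , , sel, drop = FALSE]
        yb <- y_train[sel]
        if (!is.null(augment)) {
          xb <- augment_batch(xb, augment, training = TRUE, seed = NULL)
        }
        fwd <- nn_forward(model, xb, training = TRUE, keep_cache = TRUE)
        pred <- as.numeric(fwd$out)
        err <- pred - yb
        sse <- sse + sum(err^2)
        g <- matrix(2 * err / length(err), nrow = 1)
        bwd <- nn_backward(model, fwd$cache, g)
        step <- step + 1L
        upd <- adam_step(model, bwd$grads, state, learning_rate, step)
        model <- upd$model
        state <- upd$state
      }
      val_loss <- NA_real_
      if (!is.null(x_val)) {
        pv <- as.numeric(nn_forward(model, x_val)$out)
        val_loss <- mean((pv - y_val)^2)
      }
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = sse / n,
                                   val_loss = val_loss)
      if (verbose) {
        message(sprintf("epoch %3d  train MSE %8.3f  val MSE %s", ep, sse / n,
                        ifelse(is.na(val_loss), "-", sprintf("%8.3f", val_loss))))
      }
    }
  })
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Train the staging CNN on a plate manifest
#'
#' Minimises the mean squared error between predicted and labelled hpf with
#' the Adam optimiser (learning rate 5e-4 by default). Augmentation, when
#' supplied, is applied to each minibatch and is active during training
#' only. Training and validation wells must be disjoint; overlap raises a
#' leakage error.
#'
#' @param model A freshly built or previously trained `stage_model`.
#' @param train_manifest,val_manifest Plate manifests (see
#'   [read_plate_manifest()]); `val_manifest` may be `NULL`.
#' @param augment An [augmentation_config()] or `NULL` for none.
#' @param epochs,learning_rate,batch_size,seed Overrides of the model
#'   config defaults.
#' @param checkpoint_path If non-`NULL`, the trained model is persisted
#'   there via [save_stage_model()].
#' @param verbose Print per-epoch losses.
#' @return The trained model; `model$history` holds one
#'   `(epoch, train_loss, val_loss)` row per epoch.
#' @export
train_stage_model <- function(model, train_manifest, val_manifest = NULL,
                              augment = NULL,
                              epochs = model$config$epochs,
                              learning_rate = model$config$learning_rate,
                              batch_size = model$config$batch_size,
                              seed = model$config$seed,
                              checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "stage_model"))
  if (!is.data.frame(train_manifest) || nrow(train_manifest) == 0L) {
    stop("empty training manifest")
  }
  if (!is.null(val_manifest)) {
    if (nrow(val_manifest) == 0L) stop("empty validation manifest")
    shared <- intersect(unique(train_manifest$well), unique(val_manifest$well))
    if (length(shared) > 0L) {
      stop("leakage: wells present in both training and validation sets: ",
           paste(shared, collapse = ", "))
    }
  }
  cfg <- model$config
  tr <- load_image_batch(train_manifest, cfg$input_height, cfg$input_width)
  va <- if (is.null(val_manifest)) list(x = NULL, y = NULL) else
    load_image_batch(val_manifest, cfg$input_height, cfg$input_width)
  model <- train_core(model, tr$x, tr$y, va$x, va$y,
                      epochs = epochs, learning_rate = learning_rate,
                      batch_size = batch_size, seed = seed,
                      augment = augment, verbose = verbose)
  if (!is.null(checkpoint_path)) save_stage_model(model, checkpoint_path)
  model
}

#' Predict developmental stage for every image in a manifest
#'
#' Inference is deterministic (dropout inactive, no augmentation). Row order
#' follows the manifest.
#'
#' @param object A trained `stage_model`.
#' @param manifest A plate manifest.
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return A `prediction_set` tibble with columns `path`, `well`, `time_h`,
#'   `temperature_c`, `true_hpf` (the manifest label) and `predicted_hpf`.
#' @export
predict.stage_model <- function(object, manifest, batch_size = 64, ...) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L) stop("empty manifest")
  cfg <- object$config
  loaded <- load_image_batch(manifest, cfg$input_height, cfg$input_width)
  n <- dim(loaded$x)[4]
  preds <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    sel <- b0:min(b0 + batch_size - 1L, n)
    preds[sel] <- as.numeric(
      nn_forward(object, loaded$x[, , , sel, drop = FALSE])$out)
  }
  out <- tibble::tibble(
    path = manifest$path, well = manifest$well, time_h = manifest$time_h,
    temperature_c = manifest$temperature_c, true_hpf = manifest$hpf,
    predicted_hpf = preds)
  class(out) <- c("prediction_set", class(out))
  out
}

#' Persist / restore a staging model
#'
#' The model (weights, config, history) is serialised to `path`; the
#' configuration is additionally written next to it as human-readable JSON
#' (`<path>.json`) and, when a training history exists, as
#' `<path>_history.csv` with columns `epoch,train_loss,val_loss`.
#'
#' @param model A `stage_model`.
#' @param path Destination file (conventionally `.rds`).
#' @export
save_stage_model <- function(model, path) {
  stopifnot(inherits(model, "stage_model"))
  saveRDS(model, path)
  jsonlite::write_json(unclass(model$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(model$history)) {
    readr::write_csv(model$history, paste0(path, "_history.csv"))
  }
  invisible(path)
}

#' @rdname save_stage_model
#' @export
load_stage_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "stage_model"))
  model
}
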