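# Internal forward/backward engine for the staging CNN.
#
# A model is a list of layer descriptors applied in order to batches stored
# as (H, W, C, N) arrays. Convolution units (3x3 same-padding conv + ReLU +
# 2x2 max pool) run through the compiled kernels; dense algebra stays in R.
# The backward pass supports two ReLU rules: the ordinary gradient (for
# training) and the DeconvNet rule (for saliency), which transmits only the
# positive part of the upstream signal regardless of the forward activation.

relu_bwd <- function(g, z, deconv = FALSE) {
  if (deconv) pmax(g, 0) else g * (z > 0)
}

nn_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    lay <- model$layers[[li]]
    switch(lay$type,
      crop_x = {
        x <- center_crop_x(x, lay$target_width)
      },
      rescale = {
        x <- x * lay$scale + lay$offset
      },
      conv_unit = {
        z <- cnn_conv_fwd(x, lay$W, lay$b)
        a <- z
        a[a < 0] <- 0
        pooled <- cnn_pool_fwd(a)
        if (keep_cache) {
          cache[[li]] <- list(x = x, z = z, a_dim = dim(a), idx = pooled$idx)
        }
        x <- pooled$y
      },
      flatten = {
        if (keep_cache) cache[[li]] <- list(in_dim = dim(x))
        d <- dim(x)
        dim(x) <- c(prod(d[1:3]), d[4])
      },
      dense = {
        z <- crossprod(lay$W, x) + lay$b
        if (keep_cache) cache[[li]] <- list(x = x, z = z)
        x <- if (identical(lay$activation, "relu")) pmax(z, 0) else z
      },
      dropout = {
        if (training && lay$rate > 0) {
          mask <- (stats::runif(length(x)) >= lay$rate) / (1 - lay$rate)
          dim(mask) <- dim(x)
          if (keep_cache) cache[[li]] <- list(mask = mask)
          x <- x * mask
        }
      },
      stop("unknown layer type: ", lay$type)
    )
  }
  list(out = x, cache = cache)
}

# Backpropagate `g` (same shape as the model output) down to the input of
# the rescale layer, i.e. the cropped image. Returns per-layer parameter
# gradients and the input gradient.
nn_backward <- function(model, cache, g, deconv = FALSE) {
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    lay <- model$layers[[li]]
    switch(lay$type,
      crop_x = {
        # crop precedes all parameters; stop here
      },
      rescale = {
        g <- g * lay$scale
      },
      conv_unit = {
        cc <- cache[[li]]
        ga <- cnn_pool_bwd(g, cc$idx, cc$a_dim)
        gz <- relu_bwd(ga, cc$z, deconv)
        bw <- cnn_conv_bwd(cc$x, lay$W, gz)
        grads[[li]] <- list(W = bw$gw, b = bw$gb)
        g <- bw$gx
      },
      flatten = {
        dim(g) <- cache[[li]]$in_dim
      },
      dense = {
        cc <- cache[[li]]
        gz <- if (identical(lay$activation, "relu")) relu_bwd(g, cc$z, deconv) else g
        grads[[li]] <- list(W = cc$x %*% t(gz), b = rowSums(gz))
        g <- lay$W %*% gz
      },
      dropout = {
        if (!is.null(cache[[li]])) g <- g * cache[[li]]$mask
      }
    )
  }
  list(grads = grads, g_input = g)
}

# One Adam step over the trainable layers. `state` holds first/second moment
# estimates per layer; `t` is the global step count (for bias correction).
adam_step <- function(model, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (li in seq_along(model$layers)) {
    lay <- model$layers[[li]]
    if (is.null(lay$W) || !isTRUE(lay$trainable) || is.null(grads[[li]])) next
    for (p in c("W", "b")) {
      gp <- grads[[li]][[p]]
      st <- state[[li]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * gp
      st$v <- beta2 * st$v + (1 - beta2) * gp^2
      upd <- lr * (st$m / b1t) / (sqrt(st$v / b2t) + eps)
      model$layers[[li]][[p]] <- lay[[p]] - upd
      state[[li]][[p]] <- st
      lay <- model$layers[[li]]
    }
  }
  list(model = model, state = state)
}

adam_init <- function(model) {
  lapply(model$layers, function(lay) {
    if (is.null(lay$W)) return(NULL)
    list(W = list(m = array(0, dim(lay$W)), v = array(0, dim(lay$W))),
         b = list(m = numeric(length(lay$b)), v = numeric(length(lay$b))))
  })
}
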