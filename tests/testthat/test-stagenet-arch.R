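test_that("the network maps image batches to scalar hpf predictions", {
  m <- tiny_model()
  x <- array(stats::runif(32 * 48 * 3 * 5), dim = c(32, 48, 3, 5))
  out <- embryostage:::nn_forward(m, x)$out
  expect_equal(dim(out), c(1L, 5L))
})

test_that("parameter counts match the hand-derived layer formulas", {
  cfg <- stage_model_config(input_height = 64, input_width = 96,
                            n_conv_units = 1, filters_per_unit = 4,
                            dense_width = 8, dropout_rate = 0)
  pc <- param_counts(build_stage_model(cfg))
  expect_equal(pc$params[pc$layer == "conv_1"], 4 * (3 * 3 * 3 + 1)) # 112

  set.seed(14)
  for (i in 1:20) {
    n_units <- sample(1:4, 1)
    filters <- sample(1:12, n_units, replace = TRUE)
    h <- sample(c(16, 24, 32, 48), 1)
    w <- h + sample(c(8, 16, 32), 1)
    dw <- sample(c(4, 8, 16, 32), 1)
    cfg <- stage_model_config(input_height = h, input_width = w,
                              n_conv_units = n_units,
                              filters_per_unit = filters, dense_width = dw,
                              dropout_rate = 0.3, seed = i)
    pc <- param_counts(build_stage_model(cfg))
    c_in <- c(3, filters[-n_units])
    expect_equal(pc$params[seq_len(n_units)], filters * (9 * c_in + 1))
    feat <- (h %/% 2^n_units) * (h %/% 2^n_units) * filters[n_units]
    expect_equal(pc$params[pc$layer == "dense_1"], feat * dw + dw)
    expect_equal(pc$params[pc$layer == "output"], dw + 1)
  }
})

test_that("configurations that collapse the spatial grid are rejected", {
  expect_error(stage_model_config(input_height = 16, input_width = 24,
                                  n_conv_units = 5,
                                  filters_per_unit = rep(4, 5)),
               "architecture error")
  expect_error(stage_model_config(n_conv_units = 2, filters_per_unit = c(4, 8, 16)),
               "one entry per")
  expect_error(stage_model_config(dropout_rate = 1), "dropout")
})

test_that("the centre crop removes symmetric x margins only", {
  x <- array(stats::runif(4 * 240 * 3 * 2), dim = c(4, 240, 3, 2))
  cr <- center_crop_x(x, 180)
  expect_equal(dim(cr), c(4L, 180L, 3L, 2L))
  expect_identical(cr, x[, 31:210, , , drop = FALSE]) # columns [30, 210)

  expect_identical(center_crop_x(x, 240), x)

  # odd total margin: floor on the left, ceil on the right
  m <- matrix(1:(3 * 9), 3, 9)
  cr2 <- center_crop_x(m, 4)
  expect_identical(cr2, m[, 3:6, drop = FALSE])

  expect_error(center_crop_x(m, 10), "exceeds")
})

test_that("model checkpoints round-trip with config sidecar and history", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 2, n_frames = 2)
  m <- tiny_model()
  m <- train_stage_model(m, man, epochs = 1, verbose = FALSE)
  ckpt <- file.path(dir, "model.rds")
  save_stage_model(m, ckpt)
  expect_true(file.exists(paste0(ckpt, ".json")))
  hist <- readr::read_csv(paste0(ckpt, "_history.csv"), show_col_types = FALSE)
  expect_named(hist, c("epoch", "train_loss", "val_loss"))
  back <- load_stage_model(ckpt)
  expect_equal(back$layers, m$layers)
})
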