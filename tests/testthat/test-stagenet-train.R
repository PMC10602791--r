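test_that("a constant-label dataset is fit by the bias pathway", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 3, n_frames = 3, height = 16, width = 24)
  man$hpf <- 10 # constant label, images vary
  m <- build_stage_model(stage_model_config(
    input_height = 16, input_width = 24, n_conv_units = 1,
    filters_per_unit = 4, dense_width = 8, dropout_rate = 0,
    batch_size = 4, seed = 2))
  m <- train_stage_model(m, man, epochs = 60, verbose = FALSE)
  h <- m$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  pred <- predict(m, man)
  expect_equal(mean(pred$predicted_hpf), 10, tolerance = 1)
})

test_that("training reduces the MSE loss on a simulated plate", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 6, n_frames = 6, interval = 6)
  p <- partition_by_well(man, 0.5, seed = 3)
  m <- tiny_model()
  m <- train_stage_model(m, p$train, p$test, epochs = 12, verbose = FALSE)
  h <- m$history
  expect_equal(nrow(h), 12L)
  expect_named(h, c("epoch", "train_loss", "val_loss"))
  expect_lt(tail(h$train_loss, 1), 0.5 * h$train_loss[1])
  expect_false(anyNA(h$val_loss))
})

test_that("well leakage between train and validation is refused", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 4, n_frames = 2)
  p <- partition_by_well(man, 0.5, seed = 1)
  m <- tiny_model()
  leaky_val <- dplyr::bind_rows(p$test, p$train[1, ])
  expect_error(train_stage_model(m, p$train, leaky_val, epochs = 1),
               "leakage")
  expect_error(train_stage_model(m, man[0, ], epochs = 1), "empty")
})

test_that("prediction is deterministic, order-preserving and complete", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 3, n_frames = 4)
  m <- tiny_model()

  pred <- predict(m, man)
  expect_equal(nrow(pred), nrow(man))
  expect_equal(pred$path, man$path)
  expect_equal(pred$true_hpf, man$hpf)

  # duplicate records give identical predictions (dropout inactive)
  dup <- man[c(1, 1, 2), ]
  dup$frame <- c(1L, 99L, 2L)
  pd <- predict(m, dup)
  expect_identical(pd$predicted_hpf[1], pd$predicted_hpf[2])

  # permuted manifest gives the same multiset of pairs
  perm <- man[rev(seq_len(nrow(man))), ]
  pp <- predict(m, perm)
  expect_equal(pp$predicted_hpf, rev(pred$predicted_hpf))
})

test_that("prediction rejects inputs that mismatch the model size", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 2, n_frames = 2)
  m <- tiny_model()
  # images are resized on load, so any readable image works; a missing
  # image is the I/O failure mode
  bad <- man
  bad$path[1] <- file.path(dir, "gone.tif")
  expect_error(predict(m, bad), "gone.tif")
})

test_that("training is reproducible from its seed", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 3, n_frames = 3, height = 16, width = 24)
  mk <- function() {
    m <- build_stage_model(stage_model_config(
      input_height = 16, input_width = 24, n_conv_units = 1,
      filters_per_unit = 4, dense_width = 8, dropout_rate = 0.2,
      batch_size = 4, seed = 11))
    train_stage_model(m, man, epochs = 3, verbose = FALSE)
  }
  m1 <- mk(); m2 <- mk()
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$history, m2$history)
})
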