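test_that("manifests round-trip through CSV unchanged", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 3, n_frames = 4)
  back <- read_plate_manifest(file.path(dir, "manifest.csv"))
  expect_equal(as.data.frame(back), as.data.frame(man))
})

test_that("rows with missing images are dropped with a warning", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 2, n_frames = 3)
  file.remove(man$path[4])
  expect_warning(back <- read_plate_manifest(file.path(dir, "manifest.csv")),
                 "missing image")
  expect_equal(nrow(back), 5L)
})

test_that("schema violations are format errors", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 2, n_frames = 2)
  bad <- file.path(dir, "bad.csv")
  readr::write_csv(dplyr::rename(man, hours = hpf), bad)
  expect_error(read_plate_manifest(bad), "malformed")

  empty <- file.path(dir, "empty.csv")
  readr::write_csv(man[0, ], empty)
  expect_error(read_plate_manifest(empty), "empty")

  dup <- file.path(dir, "dup.csv")
  readr::write_csv(dplyr::bind_rows(man, man[1, ]), dup)
  expect_error(read_plate_manifest(dup), "duplicate")
})

test_that("well-based partitioning keeps each embryo on one side", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 10, n_frames = 2)
  p <- partition_by_well(man, 0.5, seed = 1)
  expect_length(unique(p$train$well), 5L)
  expect_length(unique(p$test$well), 5L)
  expect_length(intersect(p$train$well, p$test$well), 0L)

  excl <- c("W001", "W002")
  p2 <- partition_by_well(man, 0.5, excluded_wells = excl, seed = 1)
  expect_length(unique(p2$train$well), 4L)
  expect_length(unique(p2$test$well), 4L)
  expect_false(any(excl %in% c(p2$train$well, p2$test$well)))

  expect_identical(partition_by_well(man, 0.5, seed = 9)$train,
                   partition_by_well(man, 0.5, seed = 9)$train)
  seeds_differ <- !identical(
    sort(unique(partition_by_well(man, 0.5, seed = 1)$train$well)),
    sort(unique(partition_by_well(man, 0.5, seed = 2)$train$well)))
  expect_true(seeds_differ ||
    !identical(sort(unique(partition_by_well(man, 0.5, seed = 1)$train$well)),
               sort(unique(partition_by_well(man, 0.5, seed = 3)$train$well))))
})

test_that("partitioning is a set partition for many random split specs", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 9, n_frames = 1)
  wells <- unique(man$well)
  set.seed(99)
  for (i in 1:1000) {
    frac <- stats::runif(1, 0.05, 0.95)
    excl <- sample(wells, sample(0:6, 1))
    if (length(setdiff(wells, excl)) < 2) next
    p <- partition_by_well(man, frac, excluded_wells = excl,
                           seed = sample.int(1e6, 1))
    got <- sort(c(unique(p$train$well), unique(p$test$well)))
    expect_identical(got, sort(setdiff(wells, excl)))
    expect_length(intersect(p$train$well, p$test$well), 0L)
    expect_gte(length(unique(p$train$well)), 1L)
    expect_gte(length(unique(p$test$well)), 1L)
  }
  expect_error(partition_by_well(man, 0.5, excluded_wells = wells[-1]),
               "fewer than 2")
  expect_error(partition_by_well(man, 1.2), "train_fraction")
})

test_that("partitioning never mutates records", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 4, n_frames = 2)
  p <- partition_by_well(man, 0.5, seed = 4)
  both <- dplyr::arrange(dplyr::bind_rows(p$train, p$test), well, frame)
  expect_equal(as.data.frame(both), as.data.frame(man))
})

test_that("image batches have the promised shape, scale and order", {
  dir <- withr::local_tempdir()
  man <- tiny_plate(dir, n_wells = 2, n_frames = 4)
  b <- load_image_batch(man[1:8, ], 32, 48)
  expect_equal(dim(b$x), c(32L, 48L, 3L, 8L))
  expect_equal(b$y, man$hpf[1:8])
  expect_true(all(b$x >= 0 & b$x <= 1))
  # grayscale replicated to three identical channels
  expect_equal(b$x[, , 1, 1], b$x[, , 3, 1])

  bad <- man[1:2, ]
  bad$path[2] <- file.path(dir, "nope.tif")
  expect_error(load_image_batch(bad, 32, 48), "nope.tif")
})

test_that("8-bit and 16-bit encodings of one scene load identically", {
  dir <- withr::local_tempdir()
  # values on the 8-bit grid are exactly representable at both depths
  img <- matrix(sample(0:255, 32 * 48, replace = TRUE) / 255, 32, 48)
  p8 <- file.path(dir, "img8.tif"); p16 <- file.path(dir, "img16.tif")
  tiff::writeTIFF(img, p8, bits.per.sample = 8L)
  tiff::writeTIFF(img, p16, bits.per.sample = 16L)
  man <- tibble::tibble(path = c(p8, p16), well = c("a", "b"),
                        frame = c(1L, 1L), time_h = 0, temperature_c = 28.5,
                        hpf = c(1, 1))
  b <- load_image_batch(man, 32, 48)
  expect_identical(b$x[, , , 1], b$x[, , , 2])
  # constant image stays constant and in range
  const <- file.path(dir, "const.png")
  png::writePNG(matrix(0.5, 16, 24), const)
  man2 <- tibble::tibble(path = const, well = "c", frame = 1L, time_h = 0,
                         temperature_c = 28.5, hpf = 1)
  b2 <- load_image_batch(man2, 16, 24)
  expect_equal(max(b2$x) - min(b2$x), 0)
  expect_true(all(b2$x >= 0 & b2$x <= 1))
})

test_that("exclusion lists read one well per line with comments skipped", {
  f <- withr::local_tempfile(lines = c("W001", "", "# dead embryo", "W007 "))
  expect_equal(read_exclusion_list(f), c("W001", "W007"))
})
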