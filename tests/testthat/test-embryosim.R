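test_that("rendering is deterministic and stage-monotone", {
  r1 <- render_embryo(20, height = 48, width = 64, seed = 9)
  r2 <- render_embryo(20, height = 48, width = 64, seed = 9)
  expect_identical(r1$image, r2$image)
  r3 <- render_embryo(20, height = 48, width = 64, seed = 10)
  expect_false(identical(r1$image, r3$image))
  expect_true(all(r1$image >= 0 & r1$image <= 1))

  p5 <- render_embryo(5, height = 48, width = 64, seed = 1)$phenotype
  p40 <- render_embryo(40, height = 48, width = 64, seed = 1)$phenotype
  expect_gt(p40$tail_length, p5$tail_length)

  stages <- seq(2, 55, by = 1.5)
  ph <- dplyr::bind_rows(lapply(stages, embryo_phenotype, frame_min_dim = 48))
  expect_true(all(diff(ph$body_arc_degrees) >= 0))
  expect_true(all(diff(ph$tail_length) >= 0))
  expect_true(all(diff(ph$stripe_count) >= 0))
  expect_true(all(diff(ph$pigment_level) >= 0))
  # geometry stays inside the frame at every stage (chorion is outermost)
  expect_true(all(2.1 * ph$yolk_radius + 1.2 < 48 * (0.5 - 0.1)))
})

test_that("the eye appears exactly at its onset stage", {
  below <- render_embryo(23.9, height = 48, width = 64, seed = 2)$phenotype
  above <- render_embryo(24.1, height = 48, width = 64, seed = 2)$phenotype
  expect_false(below$eye_present)
  expect_true(above$eye_present)
})

test_that("stages outside the supported range are rejected", {
  expect_error(render_embryo(1, height = 48, width = 64), "outside")
  expect_error(render_embryo(60, height = 48, width = 64), "outside")
})

test_that("simulate_plate writes the promised files and labels", {
  dir <- withr::local_tempdir()
  spec <- sim_plate_spec(n_wells = 4, temperature = 28.5, t_start = 4,
                         interval = 4, n_frames = 10, image_height = 32,
                         image_width = 48, seed = 21)
  man <- simulate_plate(spec, dir)
  expect_equal(nrow(man), 40L)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))

  # labels affine in frame index with slope interval * rate
  rate <- relative_rate(28.5)
  for (w in unique(man$well)) {
    h <- man$hpf[man$well == w]
    expect_equal(diff(h), rep(4 * rate, 9), tolerance = 1e-10)
  }
})

test_that("labels scale across temperature exactly as the rate model says", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  mk <- function(temp, dir) {
    simulate_plate(sim_plate_spec(
      n_wells = 3, temperature = temp, t_start = 5, interval = 4,
      n_frames = 8, image_height = 32, image_width = 48,
      jitter_window = 0, seed = 5), dir)
  }
  m28 <- mk(28.5, d1)
  m25 <- mk(25.0, d2)
  expect_equal(mean(m25$hpf) / mean(m28$hpf), 0.805 / 0.9975,
               tolerance = 1e-10)
})

test_that("temperatures below the rate-model zero are rejected", {
  dir <- withr::local_tempdir()
  spec <- sim_plate_spec(n_wells = 2, temperature = 10.0, n_frames = 2,
                         image_height = 32, image_width = 48)
  expect_error(simulate_plate(spec, dir), "nonpositive")
})

test_that("plates are bit-reproducible from their seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- sim_plate_spec(n_wells = 2, temperature = 28.5, t_start = 4,
                         interval = 6, n_frames = 3, image_height = 32,
                         image_width = 48, seed = 77)
  m1 <- simulate_plate(spec, d1)
  m2 <- simulate_plate(spec, d2)
  expect_equal(m1[setdiff(names(m1), "path")], m2[setdiff(names(m2), "path")])
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$path[i], "raw", 1e6),
                     readBin(m2$path[i], "raw", 1e6))
  }
})

test_that("a trivial intensity regressor can read stage off the images", {
  dir <- withr::local_tempdir()
  man <- simulate_plate(sim_plate_spec(
    n_wells = 6, temperature = 28.5, t_start = 4, interval = 5,
    n_frames = 9, image_height = 48, image_width = 64, seed = 31), dir)
  b <- load_image_batch(man, 48, 64)
  mean_int <- apply(b$x[, , 1, ], 3, mean)
  # darker with stage: strong monotone association
  expect_gt(abs(stats::cor(mean_int, man$hpf, method = "spearman")), 0.9)
})
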