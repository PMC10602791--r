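#' Specification of a synthetic multi-well plate time-lapse
#'
#' Describes a simulated experiment: one embryo per well, imaged at fixed
#' intervals (15 min by default, mirroring typical live-imaging protocols)
#' from shortly after fertilisation, at a single incubation temperature.
#' Each well receives a random fertilisation-time jitter within
#' `jitter_window` hours, emulating a clutch laid over ~30 minutes.
#'
#' @param n_wells Number of wells (>= 1).
#' @param temperature Incubation temperature in degC; must exceed the
#'   rate-model zero (~10.36 degC for the default constants).
#' @param t_start Hours post fertilisation at the first frame.
#' @param interval Hours between frames (default 0.25).
#' @param n_frames Frames per well (>= 1).
#' @param image_height,image_width Frame size in pixels; width must exceed
#'   height (the downstream crop is x-only).
#' @param noise_sigma SD of additive Gaussian background noise.
#' @param background Background intensity in `[0, 1]`.
#' @param illum_strength Amplitude of the mild linear illumination gradient.
#' @param jitter_window Width (hours) of the per-well uniform
#'   fertilisation-time jitter; 0 disables.
#' @param seed Integer seed; every image is reproducible from it.
#' @param format `"tiff"` or `"png"`.
#' @return A `sim_plate_spec` list.
#' @export
sim_plate_spec <- function(n_wells, temperature = 28.5, t_start = 3,
                           interval = 0.25, n_frames = 40,
                           image_height = 180, image_width = 240,
                           noise_sigma = 0.02, background = 0.88,
                           illum_strength = 0.06, jitter_window = 0.5,
                           seed = 1, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (n_wells < 1 || n_frames < 1) stop("n_wells and n_frames must be >= 1")
  if (interval <= 0) stop("interval must be positive")
  if (image_width <= image_height) {
    stop("image_width must exceed image_height (x-only crop convention)")
  }
  structure(list(n_wells = as.integer(n_wells), temperature = temperature,
                 t_start = t_start, interval = interval,
                 n_frames = as.integer(n_frames),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 noise_sigma = noise_sigma, background = background,
                 illum_strength = illum_strength,
                 jitter_window = jitter_window, seed = as.integer(seed),
                 format = format),
            class = "sim_plate_spec")
}

#' Morphological phenotype of a simulated embryo at a given stage
#'
#' The synthetic morphology echoes the landmarks that staging guides rely
#' on: the body axis wraps further around the yolk as development proceeds,
#' the tail extends, somite-like stripes accumulate (one per ~1.5 h, capped
#' at 30), pigmentation darkens, and an eye disc appears from
#' `eye_onset_stage` onwards. Body arc, tail length, stripe count and
#' pigment level are nondecreasing in stage by construction.
#'
#' @param stage Developmental stage in reference-equivalent hpf.
#' @param frame_min_dim Smaller frame dimension in pixels (sets the scale).
#' @param eye_onset_stage Stage at which the eye appears (default 24).
#' @return A one-row tibble: `yolk_radius`, `body_arc_degrees`,
#'   `tail_length`, `eye_present`, `stripe_count`, `pigment_level`.
#' @export
embryo_phenotype <- function(stage, frame_min_dim = 180, eye_onset_stage = 24) {
  sfrac <- pmin(pmax((stage - 2) / (55 - 2), 0), 1)
  yolk0 <- 0.14 * frame_min_dim
  body_radius <- 1.35 * yolk0
  body_arc <- pmin(300, stage * 6)
  tail_arc <- pmin(50, stage)
  tibble::tibble(
    yolk_radius = yolk0 * (1 - 0.15 * sfrac),
    body_arc_degrees = body_arc,
    tail_length = body_radius * tail_arc * pi / 180,
    eye_present = stage >= eye_onset_stage,
    stripe_count = pmin(30, floor(stage / 1.5)),
    pigment_level = pmin(1, stage / 55))
}

#' Render one synthetic embryo image
#'
#' Draws an embryo at the given developmental stage into a brightfield-like
#' frame: a chorion ring, an elliptical yolk, a circular-arc body axis with
#' somite-like stripes, a tapering tail and (late) an eye disc, over a
#' background with a mild illumination gradient and additive Gaussian
#' noise. Position (within a central region) and orientation are random but
#' fully determined by `seed`; the same `(stage, seed)` always yields a
#' bit-identical image.
#'
#' @param stage Stage in reference-equivalent hpf; must lie in
#'   `stage_range`.
#' @param height,width Frame size in pixels.
#' @param seed Integer seed.
#' @param noise_sigma,background,illum_strength Background model; see
#'   [sim_plate_spec()].
#' @param eye_onset_stage Stage at which the eye appears.
#' @param stage_range Supported stage range (default 2-55 hpf).
#' @return A list with `image` (`height x width` matrix in `[0, 1]`) and
#'   `phenotype` (one-row tibble from [embryo_phenotype()]).
#' @export
render_embryo <- function(stage, height = 180, width = 240, seed = 1,
                          noise_sigma = 0.02, background = 0.88,
                          illum_strength = 0.06, eye_onset_stage = 24,
                          stage_range = c(2, 55)) {
  if (stage < stage_range[1] || stage > stage_range[2]) {
    stop(sprintf("stage %.2f outside supported range [%g, %g]",
                 stage, stage_range[1], stage_range[2]))
  }
  ph <- embryo_phenotype(stage, min(height, width), eye_onset_stage)
  withr::with_seed(seed, {
    cx <- width / 2 + stats::runif(1, -0.1, 0.1) * width
    cy <- height / 2 + stats::runif(1, -0.1, 0.1) * height
    alpha <- stats::runif(1, 0, 2 * pi)
    gdir <- stats::runif(1, 0, 2 * pi)
    noise <- stats::rnorm(height * width, 0, noise_sigma)
  })

  yolk0 <- 0.14 * min(height, width)
  body_radius <- 1.35 * yolk0
  sfrac <- pmin(pmax((stage - 2) / (55 - 2), 0), 1)
  body_halfwidth <- 0.30 * yolk0 * (1 + 0.4 * sfrac)
  body_arc_rad <- ph$body_arc_degrees * pi / 180
  tail_arc_rad <- ph$tail_length / body_radius
  pig <- ph$pigment_level

  xg <- matrix(seq_len(width), height, width, byrow = TRUE)
  yg <- matrix(seq_len(height), height, width)
  dx <- xg - cx
  dy <- yg - cy
  # rotate into the embryo frame
  xr <- cos(alpha) * dx + sin(alpha) * dy
  yr <- -sin(alpha) * dx + cos(alpha) * dy
  r <- sqrt(xr^2 + yr^2)
  psi <- atan2(yr, xr) %% (2 * pi)

  img <- matrix(background, height, width) +
    illum_strength * ((xg / width - 0.5) * cos(gdir) +
                      (yg / height - 0.5) * sin(gdir))

  # chorion
  chor <- abs(r - 2.1 * yolk0) <= 1.2
  img[chor] <- 0.78

  # body arc with somite stripes
  in_ring <- abs(r - body_radius) <= body_halfwidth
  body <- in_ring & psi <= body_arc_rad
  body_int <- 0.55 - 0.35 * pig
  img[body] <- body_int
  if (ph$stripe_count > 0) {
    phase <- sin(pi * ph$stripe_count * psi / body_arc_rad)^2
    stripes <- body & phase > 0.5
    img[stripes] <- body_int - 0.15
  }

  # tapering tail continues the arc
  if (tail_arc_rad > 0) {
    tpos <- (psi - body_arc_rad) / tail_arc_rad
    tail <- psi > body_arc_rad & tpos <= 1 &
      abs(r - body_radius) <= body_halfwidth * (0.6 - 0.35 * tpos)
    img[tail] <- body_int + 0.10
  }

  # yolk (ellipse, slightly elongated along the body axis)
  yolk <- (xr / (1.1 * ph$yolk_radius))^2 + (yr / (0.95 * ph$yolk_radius))^2 <= 1
  img[yolk] <- 0.62 - 0.10 * pig

  # eye disc near the head end of the body axis
  if (ph$eye_present) {
    a_e <- 0.1 * body_arc_rad
    ex <- body_radius * cos(a_e)
    ey <- body_radius * sin(a_e)
    eye <- (xr - ex)^2 + (yr - ey)^2 <= (0.25 * yolk0)^2
    img[eye] <- 0.15
  }

  img <- img + matrix(noise, height, width)
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(image = img, phenotype = ph)
}

write_embryo_image <- function(img, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  if (format == "tiff") {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  } else {
    png::writePNG(img, path)
  }
  invisible(path)
}

#' Simulate a multi-well plate time-lapse to disk
#'
#' Writes `n_wells * n_frames` single-channel 16-bit images plus a manifest
#' CSV (`manifest.csv`, schema `path,well,frame,time_h,temperature_c,hpf`)
#' into `out_dir`. The hpf label of each image is the temperature-scaled
#' standard-equivalent stage at its acquisition time, so within one well
#' labels are an affine function of frame index with slope
#' `interval * (0.055*T - c)`.
#'
#' @param spec A [sim_plate_spec()].
#' @param out_dir Output directory (created if absent).
#' @param model A [rate_model()].
#' @return The plate manifest as a tibble (also written to
#'   `out_dir/manifest.csv`).
#' @export
simulate_plate <- function(spec, out_dir, model = rate_model()) {
  stopifnot(inherits(spec, "sim_plate_spec"))
  rate <- relative_rate(spec$temperature, model) # errors if nonpositive
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  n_img <- spec$n_wells * spec$n_frames
  draws <- withr::with_seed(spec$seed, list(
    jitter = stats::runif(spec$n_wells, 0, spec$jitter_window),
    img_seeds = matrix(sample.int(.Machine$integer.max - 1L, n_img),
                       spec$n_wells, spec$n_frames)))

  ext <- if (spec$format == "tiff") "tif" else "png"
  rows <- vector("list", n_img)
  i <- 0L
  for (w in seq_len(spec$n_wells)) {
    well_id <- sprintf("W%03d", w)
    for (k in seq_len(spec$n_frames)) {
      t_h <- spec$t_start + draws$jitter[w] + (k - 1L) * spec$interval
      hpf <- t_h * rate
      fname <- sprintf("%s_f%04d.%s", well_id, k, ext)
      path <- file.path(out_dir, fname)
      rend <- render_embryo(hpf, spec$image_height, spec$image_width,
                            seed = draws$img_seeds[w, k],
                            noise_sigma = spec$noise_sigma,
                            background = spec$background,
                            illum_strength = spec$illum_strength)
      write_embryo_image(rend$image, path, spec$format)
      i <- i + 1L
      rows[[i]] <- tibble::tibble(path = path, well = well_id, frame = k,
                                  time_h = t_h,
                                  temperature_c = spec$temperature, hpf = hpf)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write_plate_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
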