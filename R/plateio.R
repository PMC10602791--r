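manifest_schema <- c("path", "well", "frame", "time_h", "temperature_c", "hpf")

#' Read a plate manifest CSV
#'
#' The manifest is the unit of truth for labels and partitioning: one row
#' per image with columns `path,well,frame,time_h,temperature_c,hpf`
#' (`hpf` is the training label). Rows whose image file is missing are
#' dropped with a warning. `(well, frame)` pairs must be unique.
#'
#' @param path Manifest CSV path.
#' @param check_images Verify that each image file exists (default `TRUE`).
#' @return A tibble with the schema above.
#' @export
read_plate_manifest <- function(path, check_images = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(header, manifest_schema)) {
    stop("malformed manifest header: expected '",
         paste(manifest_schema, collapse = ","), "' but found '",
         paste(header, collapse = ","), "'")
  }
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         path = "c", well = "c", frame = "i",
                         time_h = "d", temperature_c = "d", hpf = "d"))
  if (nrow(m) == 0L) stop("empty manifest: ", path)
  validate_manifest(m)
  if (check_images) {
    # relative paths resolve against the manifest's own directory
    resolved <- ifelse(file.exists(m$path), m$path,
                       file.path(dirname(path), m$path))
    ok <- file.exists(resolved)
    if (any(!ok)) {
      warning(sprintf("dropping %d manifest row(s) with missing image files: %s",
                      sum(!ok),
                      paste(utils::head(m$path[!ok], 5), collapse = ", ")))
      m <- m[ok, ]
      resolved <- resolved[ok]
    }
    m$path <- resolved
    if (nrow(m) == 0L) stop("no manifest rows with readable images remain")
  }
  m
}

validate_manifest <- function(m) {
  if (any(m$hpf < 0, na.rm = TRUE)) stop("negative hpf label in manifest")
  if (any(!nzchar(m$well))) stop("empty well id in manifest")
  if (anyDuplicated(m[, c("well", "frame")])) {
    stop("duplicate (well, frame) pairs in manifest")
  }
  invisible(m)
}

#' @rdname read_plate_manifest
#' @param manifest A manifest tibble.
#' @export
write_plate_manifest <- function(manifest, path) {
  stopifnot(all(manifest_schema %in% names(manifest)))
  readr::write_csv(manifest[manifest_schema], path)
  invisible(path)
}

#' Read a well exclusion list
#'
#' Plain text, one well id per line; blank lines and `#` comments ignored.
#' Mirrors the manual exclusion of wells where embryos died or drifted out
#' of view.
#'
#' @param path Text file path.
#' @return Character vector of well ids.
#' @export
read_exclusion_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Split a plate manifest into train and test sets, well by well
#'
#' Every well's images land entirely in the training or entirely in the
#' test set, so no embryo contributes frames to both sides. Excluded wells
#' appear in neither. `round(train_fraction * n_wells)` wells (at least one
#' on each side) are assigned to training, deterministically for a given
#' seed.
#'
#' @param manifest A plate manifest tibble.
#' @param train_fraction Fraction of (non-excluded) wells used for
#'   training, in (0, 1).
#' @param excluded_wells Character vector of well ids to drop.
#' @param seed Integer seed.
#' @return A list with `train` and `test` manifest tibbles.
#' @export
partition_by_well <- function(manifest, train_fraction = 0.5,
                              excluded_wells = character(), seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  keep <- !(manifest$well %in% excluded_wells)
  wells <- sort(unique(manifest$well[keep]))
  if (length(wells) < 2L) {
    stop("fewer than 2 wells remain after exclusions; cannot partition")
  }
  n_train <- round(train_fraction * length(wells))
  n_train <- min(max(n_train, 1L), length(wells) - 1L)
  train_wells <- withr::with_seed(seed, sample(wells, n_train))
  list(train = manifest[manifest$well %in% train_wells, ],
       test = manifest[keep & !(manifest$well %in% train_wells), ])
}

read_image_gray3 <- function(path) {
  lower <- tolower(path)
  img <- if (grepl("\\.tiff?$", lower)) {
    tiff::readTIFF(path)
  } else if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else {
    stop("unsupported image format: ", path)
  }
  d <- dim(img)
  if (length(d) == 2L) {
    array(rep(img, 3L), dim = c(d, 3L))
  } else if (d[3] >= 3L) {
    img[, , 1:3, drop = FALSE]
  } else {
    array(rep(img[, , 1], 3L), dim = c(d[1], d[2], 3L))
  }
}

#' Load a batch of images and labels from manifest records
#'
#' Images are read (TIFF or PNG; readers scale intensities by the dtype
#' maximum into `[0, 1]`), resized by direct bilinear interpolation to the
#' target size, replicated to 3 channels when grayscale, and stacked in
#' manifest order.
#'
#' @param manifest Manifest tibble (or a subset of its rows).
#' @param height,width Target size in pixels.
#' @return A list with `x`, a `(height, width, 3, N)` array, and `y`, the
#'   hpf label vector.
#' @export
load_image_batch <- function(manifest, height, width) {
  n <- nrow(manifest)
  if (n == 0L) stop("empty manifest")
  x <- array(0, dim = c(height, width, 3L, n))
  for (i in seq_len(n)) {
    p <- manifest$path[i]
    if (!file.exists(p)) stop("cannot read image: ", p)
    img <- read_image_gray3(p)
    for (c in 1:3) {
      x[, , c, i] <- bilinear_resize(img[, , c], height, width)
    }
  }
  list(x = x, y = manifest$hpf)
}
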