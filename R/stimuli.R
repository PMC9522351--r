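#' Generate a deterministic synthetic digit-glyph stimulus set
#'
#' Renders greyscale two-class digit glyphs on a 28 x 28 canvas (the MNIST
#' shape, so the downstream resize path is identical for both sources):
#' class `0` as an elliptic stroke, class `1` as a near-vertical stroke.
#' Each image is drawn with random translation, rotation and stroke-thickness
#' jitter, making the set a stand-in for handwritten digits that needs no
#' download. The generator is a pure function of its arguments and `seed`.
#'
#' @param classes Integer vector of digit classes to render; `0` and `1` are
#'   supported.
#' @param n_per_class Number of images per class (>= 1).
#' @param jitter A list as produced by [jitter_params()].
#' @param seed Integer seed; the same seed always yields bitwise-identical
#'   images.
#' @return A tibble of class `stimulus_set` with columns `image_id`, `label`,
#'   `source` and a list-column `pixels` of 28 x 28 matrices with intensities
#'   in `[0, 1]`.
#' @examples
#' digits <- generate_synthetic_digits(0:1, n_per_class = 3, seed = 1)
#' digits
#' @export
generate_synthetic_digits <- function(classes = 0:1, n_per_class = 100,
                                      jitter = jitter_params(), seed = 1L) {
  classes <- as.integer(classes)
  bad <- setdiff(classes, c(0L, 1L))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("No glyph defined for class ", paste(bad, collapse = ", "),
             "; supported classes are 0 and 1."),
      class = "gnwsim_unsupported_class"
    )
  }
  stopifnot(n_per_class >= 1)
  withr::with_seed(seed, {
    labels <- rep(classes, each = n_per_class)
    pixels <- lapply(labels, function(lab) {
      render_glyph(
        lab,
        dx = runif(1, -jitter$translate_px, jitter$translate_px),
        dy = runif(1, -jitter$translate_px, jitter$translate_px),
        rot = runif(1, -jitter$rotate_rad, jitter$rotate_rad),
        thick = runif(1, jitter$thickness_range[1], jitter$thickness_range[2])
      )
    })
    new_stimulus_set(tibble::tibble(
      image_id = seq_along(labels),
      label = labels,
      source = "synthetic",
      pixels = pixels
    ))
  })
}

#' Jitter parameters for the synthetic glyph generator
#'
#' @param translate_px Maximum absolute translation, pixels.
#' @param rotate_deg Maximum absolute rotation, degrees.
#' @param thickness_range Multiplicative stroke-thickness range.
#' @return A named list.
#' @export
jitter_params <- function(translate_px = 1, rotate_deg = 8,
                          thickness_range = c(0.9, 1.15)) {
  stopifnot(translate_px >= 0, rotate_deg >= 0,
            length(thickness_range) == 2, all(thickness_range > 0))
  list(translate_px = translate_px,
       rotate_rad = rotate_deg * pi / 180,
       thickness_range = thickness_range)
}

new_stimulus_set <- function(x) {
  class(x) <- c("stimulus_set", class(x))
  x
}

# Render one 28x28 glyph. Intensity is an anti-aliased distance field around
# the stroke skeleton; all values clipped to [0, 1].
render_glyph <- function(label, dx = 0, dy = 0, rot = 0, thick = 1) {
  n <- 28L
  cx <- (n + 1) / 2
  cy <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  # inverse-transform pixel coordinates into canonical glyph frame
  x0 <- xs - cx - dx
  y0 <- ys - cy - dy
  xr <- cos(-rot) * x0 - sin(-rot) * y0
  yr <- sin(-rot) * x0 + cos(-rot) * y0
  if (label == 0L) {
    a <- 6; b <- 8.5
    f <- sqrt((xr / a)^2 + (yr / b)^2)
    g <- sqrt((xr / a^2)^2 + (yr / b^2)^2) / pmax(f, 1e-9)
    dist <- abs(f - 1) / pmax(g, 1e-9)
  } else {
    # near-vertical stroke with a slight canonical slant
    p1 <- c(-1.2, -9); p2 <- c(1.2, 9)
    vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
    tt <- ((xr - p1[1]) * vx + (yr - p1[2]) * vy) / (vx^2 + vy^2)
    tt <- pmin(pmax(tt, 0), 1)
    dist <- sqrt((xr - (p1[1] + tt * vx))^2 + (yr - (p1[2] + tt * vy))^2)
  }
  half <- 1.4 * thick
  img <- pmin(pmax(1 - (dist - half), 0), 1)
  matrix(img, n, n)
}

#' Read MNIST-style IDX image/label files
#'
#' Parses the big-endian IDX dialect used by the MNIST handwritten-digit
#' dataset (unsigned-byte images, magic `0x00000803`; labels, magic
#' `0x00000801`). Both raw and gzip-compressed files are accepted. Pixel
#' intensities are rescaled to `[0, 1]` and images are paired with labels in
#' file order.
#'
#' @param images_path,labels_path Paths to the IDX image and label files.
#' @param digit_filter Integer vector of digit classes to keep (default all).
#' @return A `stimulus_set` tibble (see [generate_synthetic_digits()]) with
#'   `source = "mnist"`.
#' @export
load_mnist_idx <- function(images_path, labels_path, digit_filter = 0:9) {
  for (p in c(images_path, labels_path)) {
    if (!file.exists(p)) {
      rlang::abort(paste0("File not found: ", p), class = "gnwsim_format_error")
    }
  }
  imgs <- read_idx(images_path)
  labs <- read_idx(labels_path)
  if (imgs$magic != 2051L) {
    rlang::abort("Bad magic number in image file (expected 0x00000803).",
                 class = "gnwsim_format_error")
  }
  if (labs$magic != 2049L) {
    rlang::abort("Bad magic number in label file (expected 0x00000801).",
                 class = "gnwsim_format_error")
  }
  if (imgs$dims[1] != labs$dims[1]) {
    rlang::abort(
      sprintf("Image/label count mismatch: %d images vs %d labels.",
              imgs$dims[1], labs$dims[1]),
      class = "gnwsim_consistency_error"
    )
  }
  n <- imgs$dims[1]; nr <- imgs$dims[2]; nc <- imgs$dims[3]
  keep <- which(labs$data %in% as.integer(digit_filter))
  pixels <- lapply(keep, function(i) {
    off <- (i - 1) * nr * nc
    # IDX stores rows of each image consecutively
    matrix(imgs$data[(off + 1):(off + nr * nc)] / 255, nr, nc, byrow = TRUE)
  })
  new_stimulus_set(tibble::tibble(
    image_id = keep,
    label = as.integer(labs$data[keep]),
    source = "mnist",
    pixels = pixels
  ))
}

read_idx <- function(path) {
  con <- if (is_gzip(path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 1, size = 4, endian = "big")
  n_dim <- bitwAnd(magic, 0xFFL)
  if (bitwAnd(bitwShiftR(magic, 8), 0xFFL) != 0x08L || n_dim < 1 || n_dim > 3) {
    rlang::abort("Unsupported IDX type (only unsigned-byte rank 1-3 data).",
                 class = "gnwsim_format_error")
  }
  dims <- readBin(con, "integer", n = n_dim, size = 4, endian = "big")
  data <- readBin(con, "integer", n = prod(dims), size = 1, signed = FALSE)
  if (length(data) != prod(dims)) {
    rlang::abort("Truncated IDX file.", class = "gnwsim_format_error")
  }
  list(magic = magic, dims = dims, data = data)
}

is_gzip <- function(path) {
  hdr <- readBin(path, "raw", n = 2)
  length(hdr) == 2 && hdr[1] == as.raw(0x1f) && hdr[2] == as.raw(0x8b)
}

#' Build a presentation schedule for a stimulus set
#'
#' Assigns each image an onset so that presentations abut exactly: entry `k`
#' starts at `(k - 1) * (stimulus_ms + relaxation_ms)`. With the defaults
#' (250 ms stimulus, 250 ms relaxation) one image is shown every 500 ms; the
#' relaxation period lets membrane potentials and plasticity traces return to
#' rest between images.
#'
#' @param images A `stimulus_set` tibble.
#' @param stimulus_ms,relaxation_ms Durations in milliseconds (> 0).
#' @return A tibble with columns `image_id`, `onset_ms`, `stimulus_ms`,
#'   `relaxation_ms`.
#' @export
build_presentation_schedule <- function(images, stimulus_ms = 250,
                                        relaxation_ms = 250) {
  stopifnot(stimulus_ms > 0, relaxation_ms > 0)
  if (nrow(images) == 0) {
    rlang::abort("Cannot build a schedule from an empty image set.",
                 class = "gnwsim_empty_schedule")
  }
  tibble::tibble(
    image_id = images$image_id,
    onset_ms = (seq_len(nrow(images)) - 1) * (stimulus_ms + relaxation_ms),
    stimulus_ms = stimulus_ms,
    relaxation_ms = relaxation_ms
  )
}

#' Split a stimulus set into training and held-out images
#'
#' Seed-stable shuffling; the held-out fraction defaults to 20%.
#'
#' @param images A `stimulus_set` tibble.
#' @param test_fraction Fraction held out, in `(0, 1)`.
#' @param seed Integer seed for the shuffle.
#' @return A list with elements `train` and `test`.
#' @export
split_stimuli <- function(images, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  withr::with_seed(seed, {
    idx <- sample.int(nrow(images))
    n_test <- max(1L, floor(nrow(images) * test_fraction))
    list(
      test = images[sort(idx[seq_len(n_test)]), , drop = FALSE],
      train = images[sort(idx[-seq_len(n_test)]), , drop = FALSE]
    )
  })
}
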