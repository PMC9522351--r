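#' Build the orientation-selective Gabor filter bank
#'
#' Six 7 x 7 Gabor kernels at a single scale, with spatial frequency 0.1
#' cycles/pixel and an isotropic Gaussian envelope of SD 1 pixel. Orientations
#' start at `pi/8` and advance in steps of `pi/6`; the offset avoids locking
#' onto pure vertical/horizontal axes, which carry little class information.
#' Kernels are mean-subtracted so a constant image yields zero response.
#'
#' @param frequency Carrier spatial frequency, cycles per pixel.
#' @param sd Gaussian envelope SD, pixels.
#' @param size Kernel side length, pixels (odd).
#' @param n_orient Number of orientations.
#' @param offset,step First angle and angular step, radians.
#' @return An object of class `gabor_bank`: a list with `kernels` (list of
#'   matrices) and `angles` (radians).
#' @export
build_gabor_bank <- function(frequency = 0.1, sd = 1, size = 7L,
                             n_orient = 6L, offset = pi / 8, step = pi / 6) {
  stopifnot(size %% 2 == 1, n_orient >= 1)
  angles <- offset + (seq_len(n_orient) - 1) * step
  half <- (size - 1) / 2
  xs <- matrix(rep(-half:half, each = size), size, size)  # column offset
  ys <- matrix(rep(-half:half, times = size), size, size) # row offset
  kernels <- lapply(angles, function(a) {
    # carrier varies across the stroke: a bar whose long axis lies at angle
    # `a` (measured from the column axis) produces the maximal response
    xp <- -xs * sin(a) + ys * cos(a)
    k <- exp(-(xs^2 + ys^2) / (2 * sd^2)) * cos(2 * pi * frequency * xp)
    k - mean(k)
  })
  structure(list(kernels = kernels, angles = angles, frequency = frequency,
                 sd = sd, size = size),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat("<gabor_bank>", length(x$kernels), "kernels of", x$size, "x", x$size,
      "| f =", x$frequency, "cycles/px | sd =", x$sd, "px\n")
  cat(" angles (deg):", paste(round(x$angles * 180 / pi, 1), collapse = ", "),
      "\n")
  invisible(x)
}

#' Simple-cell (S1) stage: oriented Gabor responses
#'
#' Upscales the image to `size x size` pixels (bilinear), convolves it with
#' each kernel of the bank (borders handled by replicating edge pixels) and
#' rectifies responses to their magnitude, yielding an
#' `size x size x n_orient` response array.
#'
#' @param pixels A greyscale matrix with intensities in `[0, 1]`.
#' @param bank A [build_gabor_bank()] object.
#' @param size Side length of the S1 grid (default 128).
#' @return A numeric array `size x size x n_orient` of non-negative responses.
#' @export
s1_convolve <- function(pixels, bank = build_gabor_bank(), size = 128L) {
  if (!all(is.finite(pixels))) {
    rlang::abort("Image contains non-finite pixel values.",
                 class = "gnwsim_input_error")
  }
  big <- EBImage::imageData(EBImage::resize(EBImage::Image(pixels),
                                            w = size, h = size))
  half <- (bank$size - 1L) %/% 2L
  pad_size <- size + 2L * half
  fft_size <- next_composite(pad_size)
  kf <- gabor_kernel_ffts(bank, fft_size)
  # replicate-pad the image, zero-extend to the FFT grid
  padded <- matrix(0, fft_size, fft_size)
  ridx <- c(rep(1L, half), seq_len(size), rep(size, half))
  padded[seq_len(pad_size), seq_len(pad_size)] <- big[ridx, ridx]
  ff <- stats::fft(padded)
  out <- array(0, dim = c(size, size, length(bank$kernels)))
  keep <- half + seq_len(size)
  for (k in seq_along(bank$kernels)) {
    conv <- Re(stats::fft(ff * kf[[k]], inverse = TRUE)) / fft_size^2
    out[, , k] <- abs(conv[keep, keep])
  }
  out
}

# smallest 2^a * 3^b size >= n (keeps the FFT fast)
next_composite <- function(n) {
  m <- n
  repeat {
    r <- m
    while (r %% 2 == 0) r <- r / 2
    while (r %% 3 == 0) r <- r / 3
    if (r == 1) return(m)
    m <- m + 1
  }
}

# cache of kernel spectra keyed by bank geometry and FFT size
.gabor_fft_cache <- new.env(parent = emptyenv())

gabor_kernel_ffts <- function(bank, fft_size) {
  key <- paste(fft_size, bank$size, bank$frequency, bank$sd,
               paste(signif(bank$angles, 10), collapse = ","), sep = "|")
  cached <- .gabor_fft_cache[[key]]
  if (!is.null(cached)) return(cached)
  half <- (bank$size - 1L) %/% 2L
  kf <- lapply(bank$kernels, function(k) {
    km <- matrix(0, fft_size, fft_size)
    idx <- ((-half:half) %% fft_size) + 1L
    km[idx, idx] <- k
    stats::fft(km)
  })
  .gabor_fft_cache[[key]] <- kf
  kf
}

#' Complex-cell (C1) stage: pooling and winner-take-all over orientations
#'
#' Each C1 cell pools the maximum S1 response over a `field x field` receptive
#' field; adjacent fields are shifted by `stride` pixels (7 and 6 by default,
#' so neighbouring fields overlap by one pixel row). At every grid location
#' only the strongest orientation channel survives (winner-take-all); ties are
#' broken toward the lowest channel index, deterministically.
#'
#' @param s1 An S1 response array from [s1_convolve()].
#' @param field Receptive-field side length in S1 pixels.
#' @param stride Shift between adjacent receptive fields.
#' @return An object of class `c1_map`: list with `grid` (G x G x K array,
#'   zero except at winning channels), `winner` (G x G integer matrix of
#'   winning channel indices, `NA` where all channels are silent), and
#'   `angles`-compatible channel count `k`.
#' @export
c1_pool <- function(s1, field = 7L, stride = 6L) {
  size <- dim(s1)[1]
  k <- dim(s1)[3]
  starts <- seq(1L, size - field + 1L, by = stride)
  g <- length(starts)
  pooled <- array(0, dim = c(g, g, k))
  for (ch in seq_len(k)) {
    m <- s1[, , ch]
    # block max as iterated pmax over the field's offsets
    acc <- matrix(-Inf, g, g)
    for (di in 0:(field - 1L)) {
      for (dj in 0:(field - 1L)) {
        acc <- pmax(acc, m[starts + di, starts + dj])
      }
    }
    pooled[, , ch] <- acc
  }
  winner <- matrix(NA_integer_, g, g)
  grid <- array(0, dim = c(g, g, k))
  flat <- matrix(pooled, g * g, k)
  best <- max.col(flat, ties.method = "first")
  bestval <- flat[cbind(seq_len(g * g), best)]
  active <- bestval > 0
  winner[active] <- best[active]
  idx <- which(active)
  grid[cbind((idx - 1L) %% g + 1L, (idx - 1L) %/% g + 1L, best[active])] <-
    bestval[active]
  structure(list(grid = grid, winner = winner, g = g, k = k,
                 field = field, stride = stride),
            class = "c1_map")
}

#' Latency coding of C1 activations into input spikes
#'
#' Each winning C1 cell emits a single spike at
#' `t = onset + window_ms * (1 - a / a_max)`, where `a` is its activation and
#' `a_max` the maximum over the image: stronger activations fire earlier.
#' Silent cells emit nothing. Optional lateral inhibition processes spikes in
#' time order and suppresses not-yet-fired cells within a Chebyshev
#' neighbourhood of each firing cell for the remainder of the presentation.
#'
#' @param c1 A [c1_pool()] result.
#' @param window_ms Encoding window (default 250 ms).
#' @param onset_ms Absolute onset added to every spike time.
#' @param lateral_radius Neighbourhood radius for lateral inhibition in C1
#'   grid cells; `0` disables it.
#' @return A tibble with columns `cell` (1-based flat C1 index over
#'   row, column, channel), `row`, `col`, `channel`, `t_ms`, sorted by time.
#' @export
encode_latencies <- function(c1, window_ms = 250, onset_ms = 0,
                             lateral_radius = 1L) {
  stopifnot(window_ms > 0)
  g <- c1$g
  act <- c1$winner
  idx <- which(!is.na(act))
  if (length(idx) == 0) {
    return(empty_spike_plan())
  }
  rows <- (idx - 1L) %% g + 1L
  cols <- (idx - 1L) %/% g + 1L
  ch <- c1$winner[idx]
  a <- c1$grid[cbind(rows, cols, ch)]
  a_max <- max(a)
  if (a_max <= 0) {
    return(empty_spike_plan())
  }
  t <- window_ms * (1 - a / a_max)
  ord <- order(t, rows, cols)
  rows <- rows[ord]; cols <- cols[ord]; ch <- ch[ord]; t <- t[ord]
  if (lateral_radius > 0) {
    suppressed <- matrix(FALSE, g, g)
    keep <- logical(length(t))
    for (s in seq_along(t)) {
      if (suppressed[rows[s], cols[s]]) next
      keep[s] <- TRUE
      ri <- max(1L, rows[s] - lateral_radius):min(g, rows[s] + lateral_radius)
      ci <- max(1L, cols[s] - lateral_radius):min(g, cols[s] + lateral_radius)
      suppressed[ri, ci] <- TRUE
    }
    rows <- rows[keep]; cols <- cols[keep]; ch <- ch[keep]; t <- t[keep]
  }
  tibble::tibble(
    cell = rows + (cols - 1L) * g + (ch - 1L) * g * g,
    row = rows, col = cols, channel = ch,
    t_ms = onset_ms + t
  )
}

empty_spike_plan <- function() {
  tibble::tibble(cell = integer(), row = integer(), col = integer(),
                 channel = integer(), t_ms = numeric())
}

#' Encode a stimulus set into input spike plans
#'
#' Runs the deterministic front-end (S1 convolution, C1 pooling, latency
#' coding with lateral inhibition) over every image of a stimulus set.
#'
#' @param images A `stimulus_set` tibble.
#' @param bank A [build_gabor_bank()] object.
#' @param window_ms Latency-coding window per image.
#' @param s1_size S1 grid side length.
#' @param lateral_radius See [encode_latencies()].
#' @return The input tibble with an added list-column `plan` of spike-plan
#'   tibbles (times relative to each image's own onset) and attribute
#'   `c1_geometry` describing the C1 grid.
#' @export
frontend_encode <- function(images, bank = build_gabor_bank(),
                            window_ms = 250, s1_size = 128L,
                            lateral_radius = 1L) {
  geom <- NULL
  plans <- purrr::map(images$pixels, function(px) {
    c1 <- c1_pool(s1_convolve(px, bank, size = s1_size))
    if (is.null(geom)) geom <<- list(g = c1$g, k = c1$k)
    encode_latencies(c1, window_ms = window_ms, onset_ms = 0,
                     lateral_radius = lateral_radius)
  })
  out <- dplyr::mutate(images, plan = plans)
  attr(out, "c1_geometry") <- geom
  attr(out, "window_ms") <- window_ms
  out
}
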