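test_that("the Gabor bank has the prescribed geometry", {
  b <- build_gabor_bank()
  expect_length(b$kernels, 6)
  expect_equal(b$angles[1], pi / 8)
  expect_equal(b$angles[4], pi / 8 + pi / 2)
  expect_equal(diff(b$angles), rep(pi / 6, 5))
  expect_true(all(vapply(b$kernels, function(k) all(dim(k) == c(7, 7)),
                         logical(1))))
  # zero-mean construction
  for (k in b$kernels) expect_lt(abs(mean(k)), 1e-12)
  # kernel energy is rotation-invariant within tolerance
  e <- vapply(b$kernels, function(k) sum(k^2), numeric(1))
  expect_lt(max(abs(e - e[1])) / e[1], 0.05)
})

test_that("a constant image produces zero S1 response", {
  s1 <- s1_convolve(matrix(0.5, 28, 28))
  expect_equal(dim(s1), c(128, 128, 6))
  expect_lt(max(s1), 1e-10)
})

test_that("oriented bars drive the matching orientation channel", {
  b <- build_gabor_bank()
  bar_image <- function(angle) {
    n <- 28
    xs <- matrix(rep(1:n, each = n), n, n) - (n + 1) / 2
    ys <- matrix(rep(1:n, times = n), n, n) - (n + 1) / 2
    d <- abs(-xs * sin(angle) + ys * cos(angle))
    matrix(pmin(pmax(1.5 - d, 0), 1), n, n)
  }
  dominant <- function(img) {
    c1 <- c1_pool(s1_convolve(img, b))
    which.max(tabulate(c1$winner[!is.na(c1$winner)], nbins = 6))
  }
  # near-vertical bar: nearest of the six angles to pi/2 is channel 3
  vert <- matrix(0, 28, 28); vert[6:23, 14:15] <- 1
  expect_equal(dominant(vert), 3)
  # rotation covariance: a bar at each filter angle wins its own channel
  # (pixelation on the 28-px canvas allows a one-step boundary tolerance)
  hits <- vapply(1:6, function(k) dominant(bar_image(b$angles[k])), 1)
  d <- abs(hits - 1:6)
  expect_true(all(pmin(d, 6 - d) <= 1))  # exact or neighbouring channel
  expect_gte(sum(hits == 1:6), 4)
})

test_that("C1 pooling is winner-take-all with deterministic ties", {
  s1 <- array(0, dim = c(128, 128, 6))
  c0 <- c1_pool(s1)
  expect_equal(c0$g, 21)
  expect_true(all(is.na(c0$winner)))
  expect_equal(max(abs(c0$grid)), 0)
  # a single source in channel 2 activates exactly the covering cell(s)
  s1[10, 10, 2] <- 1
  c1 <- c1_pool(s1)
  act <- which(!is.na(c1$winner), arr.ind = TRUE)
  expect_gte(nrow(act), 1)
  expect_true(all(c1$winner[act] == 2))
  # pixel (10,10) is covered by C1 cells with start <= 10 <= start+6
  starts <- seq(1, 122, by = 6)
  covering <- which(starts <= 10 & starts + 6 >= 10)
  expect_setequal(unique(act[, 1]), covering)
  # tie across channels 1 and 4 resolves to the lowest index
  s1[10, 10, ] <- 0
  s1[10, 10, 4] <- 0.7
  s1[10, 10, 1] <- 0.7
  expect_true(all(c1_pool(s1)$winner[act] == 1, na.rm = TRUE))
  # at most one active channel anywhere
  cc <- c1_pool(array(runif(128 * 128 * 6), c(128, 128, 6)))
  per_cell <- apply(cc$grid > 0, c(1, 2), sum)
  expect_true(all(per_cell <= 1))
})

test_that("latency coding maps activation linearly onto the window", {
  g <- 21
  c1 <- list(grid = array(0, c(g, g, 6)), winner = matrix(NA_integer_, g, g),
             g = g, k = 6)
  class(c1) <- "c1_map"
  c1$grid[1, 1, 2] <- 1; c1$winner[1, 1] <- 2L
  c1$grid[5, 5, 3] <- 0.5; c1$winner[5, 5] <- 3L
  plan <- encode_latencies(c1, window_ms = 250, lateral_radius = 0)
  expect_equal(nrow(plan), 2)
  expect_equal(plan$t_ms[plan$channel == 2], 0)        # a = a_max
  expect_equal(plan$t_ms[plan$channel == 3], 125)      # a = a_max / 2
  # latency order is the reverse of activation order
  c1$grid[9, 9, 1] <- 0.8; c1$winner[9, 9] <- 1L
  plan <- encode_latencies(c1, window_ms = 250, lateral_radius = 0)
  acts <- c1$grid[cbind(plan$row, plan$col, plan$channel)]
  expect_equal(order(plan$t_ms), order(-acts))
  # spike count equals number of nonzero winners
  cc <- c1_pool(s1_convolve(fixture_digits$pixels[[1]]))
  p2 <- encode_latencies(cc, lateral_radius = 0)
  expect_equal(nrow(p2), sum(!is.na(cc$winner)))
  expect_true(all(p2$t_ms >= 0 & p2$t_ms <= 250))
  # all-zero map: empty plan, no error
  c1$grid[] <- 0; c1$winner[] <- NA_integer_
  expect_equal(nrow(encode_latencies(c1)), 0)
})

test_that("lateral inhibition suppresses later spikes within the radius", {
  cc <- c1_pool(s1_convolve(fixture_digits$pixels[[1]]))
  plan <- encode_latencies(cc, lateral_radius = 1)
  plan0 <- encode_latencies(cc, lateral_radius = 0)
  expect_lt(nrow(plan), nrow(plan0))
  # no two surviving spikes within Chebyshev distance 1 of each other
  if (nrow(plan) > 1) {
    d <- outer(plan$row, plan$row, function(a, b) abs(a - b))
    dc <- outer(plan$col, plan$col, function(a, b) abs(a - b))
    cheb <- pmax(d, dc)
    expect_true(all(cheb[upper.tri(cheb)] >= 2))
  }
})

test_that("non-finite pixels are rejected", {
  bad <- matrix(0.5, 28, 28); bad[3, 3] <- NA
  expect_error(s1_convolve(bad), class = "gnwsim_input_error")
})
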