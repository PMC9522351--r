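# Shared fixtures, built once per test run. Sizes are kept small: unit tests
# assert structure and invariants; the acceptance tests run the full-size
# protocols.

fixture_digits <- generate_synthetic_digits(0:1, n_per_class = 30, seed = 99)

fixture_frontend <- precompute_frontend(fixture_digits, local_config(),
                                        window_ms = 250)

# a minimal matured + labelled local network used by full-network tests;
# training length is short, enough for coarse class structure
fixture_local <- local({
  sp <- split_stimuli(fixture_digits, 0.2, seed = 5)
  net <- train_local_network(sp$train, n_presentations = 600,
                             frontend = fixture_frontend, seed = 3)
  net <- assign_s2_labels(net, sp$train, frontend = fixture_frontend,
                          seed = 4)
  list(net = net, train = sp$train, test = sp$test)
})

fixture_frontend150 <- precompute_frontend(fixture_digits, local_config(),
                                           window_ms = 150)

# write a tiny IDX image/label pair with an independent byte-level writer
write_idx_fixture <- function(dir = tempfile("idx")) {
  dir.create(dir)
  n <- 4L; h <- 5L; w <- 5L
  set.seed(11)
  pixels <- array(sample(0:255, n * h * w, replace = TRUE), c(n, h, w))
  labels <- c(0L, 1L, 7L, 1L)
  img_path <- file.path(dir, "images.idx3-ubyte")
  con <- file(img_path, "wb")
  writeBin(c(2051L, n, h, w), con, size = 4, endian = "big")
  for (i in seq_len(n)) {
    # row-major pixel order, as in the MNIST files
    writeBin(as.integer(t(pixels[i, , ])), con, size = 1)
  }
  close(con)
  lab_path <- file.path(dir, "labels.idx1-ubyte")
  con <- file(lab_path, "wb")
  writeBin(c(2049L, n), con, size = 4, endian = "big")
  writeBin(labels, con, size = 1)
  close(con)
  list(images = img_path, labels = lab_path, pixels = pixels,
       labels_true = labels, n = n, h = h, w = w)
}
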