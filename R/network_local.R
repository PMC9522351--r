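#' Configuration of the visual-cortex local network
#'
#' Collects every tunable constant of the S1-C1-S2 pathway. Defaults: 20 S2
#' cells; C1-S2 weights bounded by `w_max = 1` and initialized from
#' `Normal(0.7 w_max, 0.02 w_max)`; classical STDP with a slight depression
#' bias; latency coding over a 250 ms window followed by 250 ms relaxation;
#' alpha-like input-gain modulation with the period of one presentation and a
#' `pi/8` phase shift; spontaneous activity at each C1 cell at `rate_hz`.
#'
#' @param n_s2 Number of S2 cells (10 or 20 in the reference setup).
#' @param w_max Weight bound of the C1-S2 population.
#' @param init_mean,init_sd Initial weight distribution, fractions of `w_max`.
#' @param stdp A [classical_stdp_params()] object.
#' @param lif A [lif_params()] object for the S2 cells.
#' @param input_gain Scale of one synaptic event relative to threshold.
#' @param alpha An [alpha_modulation()] object.
#' @param rate_hz Spontaneous activity rate per C1 cell, Hz.
#' @param stimulus_ms,relaxation_ms Presentation timing.
#' @param s1_size,lateral_radius Front-end geometry (see [s1_convolve()],
#'   [encode_latencies()]).
#' @param snapshot_every Weight-snapshot cadence, presentations.
#' @return A list of class `local_config`.
#' @export
local_config <- function(n_s2 = 20L, w_max = 1,
                         init_mean = 0.7, init_sd = 0.02,
                         stdp = classical_stdp_params(dA_post = -0.018,
                                                      tau_pre = 100,
                                                      tau_post = 100,
                                                      w_max = w_max),
                         lif = lif_params(tau_m = 150),
                         input_gain = 0.007,
                         alpha = alpha_modulation(period_ms = 500),
                         rate_hz = 0.1,
                         stimulus_ms = 250, relaxation_ms = 250,
                         s1_size = 128L, lateral_radius = 0L,
                         snapshot_every = 10L) {
  stopifnot(n_s2 >= 2, rate_hz >= 0)
  structure(list(n_s2 = as.integer(n_s2), w_max = w_max,
                 init_mean = init_mean, init_sd = init_sd,
                 stdp = stdp, lif = lif, input_gain = input_gain,
                 alpha = alpha, rate_hz = rate_hz,
                 stimulus_ms = stimulus_ms, relaxation_ms = relaxation_ms,
                 s1_size = s1_size, lateral_radius = lateral_radius,
                 snapshot_every = as.integer(snapshot_every)),
            class = "local_config")
}

# Expand a presentation schedule into per-presentation spike plans, encoding
# each distinct image once (or reusing a precomputed frontend cache).
encode_schedule <- function(images, schedule, config, window_ms = NULL,
                            frontend = NULL) {
  window_ms <- window_ms %||% config$stimulus_ms
  if (is.null(frontend)) {
    frontend <- precompute_frontend(images, config, window_ms = window_ms)
  }
  plans <- frontend$plans[as.character(schedule$image_id)]
  if (anyNA(names(plans)) || any(vapply(plans, is.null, logical(1)))) {
    rlang::abort("Schedule references images absent from the frontend cache.",
                 class = "gnwsim_consistency_error")
  }
  list(plans = plans, geometry = frontend$geometry)
}

flatten_plans <- function(plans) {
  list(
    cell = as.integer(unlist(purrr::map(plans, ~ .x$cell - 1L),
                             use.names = FALSE)),
    time = as.numeric(unlist(purrr::map(plans, "t_ms"), use.names = FALSE)),
    offset = c(0L, cumsum(vapply(plans, nrow, integer(1))))
  )
}

#' Train the local network by classical STDP
#'
#' Presents the scheduled images to the S1-C1-S2 pathway with plasticity
#' enabled on the C1-S2 synapses, first-spike winner-take-all competition
#' among S2 cells, alpha-modulated input gain, and Poisson spontaneous
#' activity at the C1 cells. Weights start from a homogeneous
#' `Normal(0.7 w_max, 0.02 w_max)` state; periodic snapshots record the
#' synaptic epigenesis. The returned network is matured: its weights are
#' frozen and further stimulation never changes them.
#'
#' @param images A `stimulus_set` tibble.
#' @param schedule A presentation schedule (default: one presentation per
#'   image, in order, via [build_presentation_schedule()]).
#' @param n_presentations When no schedule is given, cycle the images to this
#'   many presentations (default: one pass over the images).
#' @param config A [local_config()] object.
#' @param seed Integer seed for all randomness (initial weights, spontaneous
#'   activity).
#' @return An object of class `local_network` with elements `w` (C1 x S2
#'   weight matrix), `geometry`, `angles`, `trajectory` (an
#'   `epigenesis_trajectory`), `training` (per-presentation winners), and the
#'   configuration.
#' @export
train_local_network <- function(images, schedule = NULL,
                                n_presentations = NULL,
                                config = local_config(), frontend = NULL,
                                seed = 1L) {
  if (is.null(schedule)) {
    pool <- images
    if (!is.null(n_presentations)) {
      reps <- rep(seq_len(nrow(images)),
                  length.out = as.integer(n_presentations))
      pool <- images[reps, , drop = FALSE]
    }
    schedule <- build_presentation_schedule(pool, config$stimulus_ms,
                                            config$relaxation_ms)
  }
  enc <- encode_schedule(images, schedule, config, frontend = frontend)
  g <- enc$geometry$g
  n_c1 <- g * g * enc$geometry$k
  n_syn <- n_c1 * config$n_s2
  if (n_syn == 0) {
    rlang::abort("Local network has no plastic synapses.",
                 class = "gnwsim_config_error")
  }
  fp <- flatten_plans(enc$plans)
  withr::with_seed(seed, {
    w0 <- clip_w(stats::rnorm(n_syn, config$init_mean * config$w_max,
                              config$init_sd * config$w_max), config$w_max)
    res <- cpp_local_run(
      fp$cell, fp$time, fp$offset,
      n_c1, config$n_s2, w0, config$w_max,
      config$stdp$dA_pre, config$stdp$dA_post,
      config$stdp$tau_pre, config$stdp$tau_post,
      config$lif$tau_m, config$lif$v_thresh, config$lif$refractory_ms,
      config$input_gain,
      config$alpha$amplitude, config$alpha$period_ms,
      config$alpha$phase_offset,
      config$stimulus_ms, config$relaxation_ms,
      config$rate_hz,
      TRUE, TRUE, TRUE, config$snapshot_every, FALSE)
  })
  snaps <- rbind(matrix(w0, 1), res$snapshots)
  traj <- new_epigenesis_trajectory(
    presentations = c(0L, res$snap_pres),
    snapshots = snaps, w_max = config$w_max)
  structure(list(
    w = matrix(res$w, n_c1, config$n_s2),
    w_max = config$w_max,
    geometry = enc$geometry,
    angles = build_gabor_bank()$angles,
    config = config,
    trajectory = traj,
    training = tibble::tibble(
      presentation = seq_len(nrow(schedule)),
      image_id = schedule$image_id,
      winner = ifelse(res$winner < 0, NA_integer_, res$winner + 1L),
      first_latency_ms = res$first_latency
    ),
    label_assignment = NULL,
    frozen = TRUE,
    seed = seed
  ), class = "local_network")
}

#' @export
print.local_network <- function(x, ...) {
  cat("<local_network>", nrow(x$w), "C1 cells ->", ncol(x$w), "S2 cells",
      if (x$frozen) "(frozen)" else "(plastic)", "\n")
  if (!is.null(x$label_assignment)) {
    cat(" label assignment:",
        paste(ifelse(is.na(x$label_assignment), ".", x$label_assignment),
              collapse = " "), "\n")
  }
  invisible(x)
}

# Frozen evaluation of a set of presentations; returns winners, latencies and
# S2 spike trains. `plans` entries must use times relative to each onset.
eval_local_cpp <- function(net, plans, stimulus_ms, relaxation_ms, rate_hz) {
  fp <- flatten_plans(plans)
  cfg <- net$config
  cpp_local_run(
    fp$cell, fp$time, fp$offset,
    nrow(net$w), ncol(net$w), as.numeric(net$w), net$w_max,
    cfg$stdp$dA_pre, cfg$stdp$dA_post, cfg$stdp$tau_pre, cfg$stdp$tau_post,
    cfg$lif$tau_m, cfg$lif$v_thresh, cfg$lif$refractory_ms,
    cfg$input_gain,
    cfg$alpha$amplitude, cfg$alpha$period_ms, cfg$alpha$phase_offset,
    stimulus_ms, relaxation_ms, rate_hz,
    FALSE, TRUE, FALSE, 0L, TRUE)
}

#' Assign digit labels to matured S2 cells
#'
#' Presents a labelled test set to the frozen network; per image, the
#' first-firing S2 cell is the responder, and each cell receives the majority
#' label of the images it won. Cells that never fire remain unassigned and
#' are excluded from classification.
#'
#' @param net A matured [train_local_network()] object.
#' @param test_images A `stimulus_set` tibble.
#' @param rate_hz Spontaneous rate during the assignment run (defaults to the
#'   training rate).
#' @param seed Integer seed.
#' @return The network with `label_assignment` (integer per S2 cell, `NA`
#'   when unassigned) and an `assignment` tibble of win counts.
#' @export
assign_s2_labels <- function(net, test_images, rate_hz = NULL,
                             frontend = NULL, seed = 1L) {
  stopifnot(inherits(net, "local_network"), net$frozen)
  rate_hz <- rate_hz %||% net$config$rate_hz
  cfg <- net$config
  enc <- encode_schedule(test_images,
                         tibble::tibble(image_id = test_images$image_id),
                         cfg, frontend = frontend)
  res <- withr::with_seed(seed, {
    eval_local_cpp(net, enc$plans, cfg$stimulus_ms, cfg$relaxation_ms,
                   rate_hz)
  })
  winner <- ifelse(res$winner < 0, NA_integer_, res$winner + 1L)
  tab <- tibble::tibble(cell = winner, label = test_images$label) |>
    dplyr::filter(!is.na(.data$cell)) |>
    dplyr::count(.data$cell, .data$label)
  assignment <- rep(NA_integer_, cfg$n_s2)
  if (nrow(tab) > 0) {
    best <- tab |>
      dplyr::group_by(.data$cell) |>
      dplyr::slice_max(.data$n, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    assignment[best$cell] <- best$label
  }
  net$label_assignment <- assignment
  net$assignment <- tab
  net
}

#' HSV reconstruction of S2 receptive fields
#'
#' For every S2 cell and C1 grid location, the six orientation-tagged weights
#' are mapped to the complex plane (`w -> w exp(i phi)`) and summed; the
#' magnitude of the sum is the saturation (connection strength) and its
#' argument the hue (dominant orientation), with value fixed at 100%.
#'
#' @param net A `local_network`.
#' @return A tibble with columns `cell`, `row`, `col`, `hue` (radians in
#'   `[0, 2 pi)`), `saturation`.
#' @export
hsv_reconstruction <- function(net) {
  g <- net$geometry$g
  k <- net$geometry$k
  n_cells <- ncol(net$w)
  phases <- exp(1i * net$angles)
  purrr::map_dfr(seq_len(n_cells), function(cell) {
    wz <- array(net$w[, cell], dim = c(g, g, k))
    z <- matrix(0 + 0i, g, g)
    for (ch in seq_len(k)) z <- z + wz[, , ch] * phases[ch]
    tibble::tibble(
      cell = cell,
      row = rep(seq_len(g), times = g),
      col = rep(seq_len(g), each = g),
      hue = as.vector(Arg(z) %% (2 * pi)),
      saturation = as.vector(Mod(z))
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
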