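#' Evaluate digit recognition of a matured local network
#'
#' Presents held-out images to the frozen, labelled network. Per image the
#' first-firing S2 cell is the responder; the prediction is that cell's
#' assigned label. Images with no S2 spike, or won by an unassigned cell,
#' count as errors.
#'
#' @param net A labelled `local_network` (see [assign_s2_labels()]).
#' @param test_images A `stimulus_set` tibble.
#' @param rate_hz Spontaneous activity rate during evaluation (defaults to
#'   the training rate).
#' @param seed Integer seed.
#' @return An object of class `recognition_eval`: list with `accuracy` and a
#'   per-image `results` tibble.
#' @export
run_recognition_eval <- function(net, test_images, rate_hz = NULL,
                                 frontend = NULL, seed = 1L) {
  stopifnot(inherits(net, "local_network"))
  if (is.null(net$label_assignment) || all(is.na(net$label_assignment))) {
    rlang::abort("No labelled S2 cells; run assign_s2_labels() first.",
                 class = "gnwsim_evaluation_error")
  }
  rate_hz <- rate_hz %||% net$config$rate_hz
  cfg <- net$config
  enc <- encode_schedule(test_images,
                         tibble::tibble(image_id = test_images$image_id), cfg,
                         frontend = frontend)
  res <- withr::with_seed(seed, {
    eval_local_cpp(net, enc$plans, cfg$stimulus_ms, cfg$relaxation_ms,
                   rate_hz)
  })
  winner <- ifelse(res$winner < 0, NA_integer_, res$winner + 1L)
  predicted <- ifelse(is.na(winner), NA_integer_,
                      net$label_assignment[pmax(winner, 1L)])
  results <- tibble::tibble(
    image_id = test_images$image_id,
    label = test_images$label,
    winner = winner,
    predicted = predicted,
    latency_ms = res$first_latency,
    correct = !is.na(predicted) & predicted == test_images$label
  )
  structure(list(accuracy = mean(results$correct), results = results,
                 rate_hz = rate_hz),
            class = "recognition_eval")
}

#' @export
print.recognition_eval <- function(x, ...) {
  cat(sprintf("<recognition_eval> accuracy %.1f%% over %d images (rate %.2g Hz, %d unclassified)\n",
              100 * x$accuracy, nrow(x$results), x$rate_hz,
              sum(is.na(x$results$predicted))))
  invisible(x)
}

#' Precompute the front-end encoding of a stimulus pool
#'
#' Runs the deterministic S1/C1/latency stages once over a pool of images so
#' repeated conditioning runs and sweeps can reuse the spike plans instead of
#' re-convolving every image per run.
#'
#' @param images A `stimulus_set` tibble.
#' @param config The `local_config` of the attached visual cortex.
#' @param window_ms Latency-coding window (the conditioning stimulus length).
#' @return A list of class `frontend_cache`.
#' @export
precompute_frontend <- function(images, config, window_ms = 150) {
  enc <- frontend_encode(images[!duplicated(images$image_id), , drop = FALSE],
                         window_ms = window_ms, s1_size = config$s1_size,
                         lateral_radius = config$lateral_radius)
  structure(list(
    plans = stats::setNames(enc$plan, as.character(enc$image_id)),
    geometry = attr(enc, "c1_geometry"),
    window_ms = window_ms
  ), class = "frontend_cache")
}

# Per-trial front-end pass: run the frozen local network on each trial image
# and return the responder cell, its selective group and its spike train.
frontend_trials <- function(net, images, trial_idx, stimulus_ms, trial_ms,
                            frontend = NULL, rate_hz = NULL) {
  cfg <- net$local$config
  readout <- net$config$s2_readout_gain
  if (!is.null(readout)) cfg$input_gain <- readout
  rate_hz <- rate_hz %||% cfg$rate_hz
  if (is.null(frontend)) {
    frontend <- precompute_frontend(images, cfg, window_ms = stimulus_ms)
  }
  plans <- frontend$plans[as.character(images$image_id[trial_idx])]
  vc <- net$local
  vc$config <- cfg
  res <- eval_local_cpp(vc, plans, stimulus_ms,
                        trial_ms - stimulus_ms, rate_hz)
  n_tr <- length(trial_idx)
  winner <- ifelse(res$winner < 0, NA_integer_, res$winner + 1L)
  spikes <- vector("list", n_tr)
  for (k in seq_len(n_tr)) {
    if (res$s2_offset[k + 1] > res$s2_offset[k]) {
      rng <- (res$s2_offset[k] + 1):res$s2_offset[k + 1]
      keep <- (res$s2_cell[rng] + 1L) == winner[k] &
        res$s2_t[rng] <= stimulus_ms
      spikes[[k]] <- res$s2_t[rng][keep]
    } else {
      spikes[[k]] <- numeric()
    }
  }
  group <- ifelse(is.na(winner), -1L, net$s2_group[pmax(winner, 1L)])
  group[is.na(group)] <- -1L
  list(winner = winner, group = as.integer(group), spikes = spikes,
       responder_label = ifelse(is.na(winner), NA_integer_,
                                net$local$label_assignment[pmax(winner, 1L)]))
}

#' Run a conditioning task on the full network
#'
#' Presents a sequence of digit trials with the task's exact timing, routes
#' each image through the frozen visual cortex to its selective GNW group,
#' applies the nonselective trigger drive, reads the motor-cortex decision
#' ("press" when motor spikes in the response window reach the threshold),
#' and delivers the signed reward through the striatal dopamine neuron at the
#' next image onset (with the 0-31.25 ms striatal jitter). Dopamine-modulated
#' STDP trains the GNW-to-motor synapses while classical/symmetric STDP shape
#' the internal workspace throughout.
#'
#' @param net A [assemble_full_network()] object.
#' @param task `"delay"` or `"trace"`.
#' @param images Stimulus pool the trial digits are drawn from.
#' @param n_trials Number of trials.
#' @param rate_hz Spontaneous rate for the GNW neurons (defaults to the
#'   configuration value).
#' @param plastic Set `FALSE` for an evaluation run: the reward pathway is
#'   frozen (no dopamine, no reward delivery, motor weights fixed) while the
#'   network's intrinsic Hebbian dynamics keep running — internal plasticity
#'   is part of the workspace physiology that sustains held representations.
#' @param record_raster Record the workspace spike raster.
#' @param seed Integer seed for all randomness in the run.
#' @return An object of class `conditioning_run`: `trials` tibble (decision,
#'   correctness, reward sign, motor spike count, per-window group spike
#'   counts), `net` (with updated weights), `weight_log`, and optionally
#'   `raster`.
#' @export
run_conditioning <- function(net, task = c("delay", "trace"), images,
                             n_trials = 100L, rate_hz = NULL,
                             plastic = TRUE, record_raster = FALSE,
                             frontend = NULL, seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(net, "full_network"))
  if (is.null(net$local)) {
    rlang::abort("This network has no visual cortex attached; use run_conditioning on an assembled network.",
                 class = "gnwsim_config_error")
  }
  spec <- trial_spec(task)
  cfg <- net$config
  rate_hz <- rate_hz %||% cfg$rate_hz
  withr::with_seed(seed, {
    trial_idx <- sample.int(nrow(images), n_trials, replace = TRUE)
    fe <- frontend_trials(net, images, trial_idx, spec$stimulus_ms,
                          spec$trial_ms, frontend = frontend)
    labels <- images$label[trial_idx]
    res <- gnw_simulate(net, labels, fe$group, fe$spikes, spec,
                        rate_hz = rate_hz, plastic = plastic,
                        record_raster = record_raster)
  })
  wc <- res$win_counts
  colnames(wc) <- c("g0_stim", "g1_stim", "inh_stim",
                    "g0_gap", "g1_gap", "inh_gap",
                    "g0_trig", "g1_trig", "inh_trig")
  trials <- dplyr::bind_cols(
    tibble::tibble(
      trial = seq_len(n_trials),
      image_id = images$image_id[trial_idx],
      label = labels,
      responder = fe$winner,
      responder_label = fe$responder_label,
      input_group = fe$group,
      pressed = res$pressed == 1L,
      correct = res$correct == 1L,
      reward_sign = res$reward_sign,
      mc_spikes = res$mc_spikes,
      latency_ms = res$latency
    ),
    tibble::as_tibble(wc)
  )
  net$W <- res$w_gnw
  net$w_mc <- as.numeric(res$w_mc)
  weight_log <- NULL
  if (length(res$snap_trial) > 0) {
    ee <- res$ee_snapshots
    colnames(ee) <- c("ee_g0", "ee_g1", "ee_cross", "exc_to_inh",
                      "inh_to_exc")
    weight_log <- dplyr::bind_cols(
      tibble::tibble(trial = res$snap_trial,
                     mc_w = lapply(seq_len(nrow(res$mc_snapshots)),
                                   function(i) res$mc_snapshots[i, ])),
      tibble::as_tibble(ee)
    )
  }
  out <- structure(list(
    task = task, trials = trials, net = net, weight_log = weight_log,
    rate_hz = rate_hz, plastic = plastic, spec = spec, seed = seed
  ), class = "conditioning_run")
  if (record_raster) {
    out$raster <- spike_raster(res$raster_neuron + 1L, res$raster_t,
                               n_trials * spec$trial_ms)
  }
  out
}

#' @export
print.conditioning_run <- function(x, ...) {
  cat(sprintf("<conditioning_run> %s | %d trials | accuracy %.1f%% | %s\n",
              x$task, nrow(x$trials), 100 * mean(x$trials$correct),
              if (x$plastic) "plastic" else "frozen"))
  invisible(x)
}

#' Trials needed to learn a conditioning task
#'
#' The smallest 0-based trial index `t` such that the fraction of correct
#' decisions over the window of trials `t + 1, ..., t + window` (1-based)
#' reaches the criterion; `Inf` if no window qualifies. With `sustain > 1`,
#' the criterion must hold for that many consecutive window positions —
#' "stable correct responding" rather than a single lucky window (a 20-trial
#' window crosses high thresholds spuriously well before learning has
#' stabilized).
#'
#' @param results A `conditioning_run` or anything with a logical `correct`
#'   column/vector.
#' @param window Sliding-window length, trials.
#' @param criterion Required window accuracy.
#' @param sustain Number of consecutive qualifying windows required.
#' @return A number of presentations (possibly `Inf`).
#' @export
trials_to_learn <- function(results, window = 20L, criterion = 0.9,
                            sustain = 1L) {
  correct <- if (inherits(results, "conditioning_run")) {
    results$trials$correct
  } else if (is.data.frame(results)) {
    results$correct
  } else {
    results
  }
  n <- length(correct)
  if (n == 0) {
    rlang::abort("Empty trial results.", class = "gnwsim_evaluation_error")
  }
  if (window > n) {
    rlang::abort("Window longer than the number of trials.",
                 class = "gnwsim_evaluation_error")
  }
  cs <- cumsum(as.numeric(correct))
  acc <- (cs[window:n] - c(0, cs[seq_len(n - window)])) / window
  ok <- acc >= criterion
  if (sustain > 1L) {
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    idx <- which(runs$values & runs$lengths >= sustain)
    if (length(idx) == 0) return(Inf)
    return(ends[idx[1]] - runs$lengths[idx[1]])  # 0-based start of the run
  }
  hit <- which(ok)
  if (length(hit) == 0) return(Inf)
  hit[1] - 1
}

#' Held-out accuracy of a conditioning network
#'
#' Freezes all plasticity and runs evaluation trials.
#'
#' @inheritParams run_conditioning
#' @return The frozen `conditioning_run` (accuracy via
#'   `mean(x$trials$correct)` or [glance()]).
#' @export
evaluate_conditioning <- function(net, task, images, n_trials = 100L,
                                  rate_hz = NULL, frontend = NULL,
                                  seed = 1L) {
  run_conditioning(net, task, images, n_trials = n_trials, rate_hz = rate_hz,
                   plastic = FALSE, frontend = frontend, seed = seed)
}

#' Sweep spontaneous rate and excitatory fraction
#'
#' For every grid cell and seed: assemble a fresh full network on the given
#' matured local network (interneurons present whenever the excitatory
#' fraction is below 1), train it with `n_train` conditioning trials at the
#' cell's spontaneous rate, then measure held-out accuracy over `n_eval`
#' frozen trials. Results are reproducible per (cell, seed).
#'
#' @param local A labelled, frozen `local_network`.
#' @param images Stimulus pool for the trials.
#' @param task `"delay"` or `"trace"`.
#' @param rates Spontaneous rates (Hz) to sweep.
#' @param fractions Excitatory fractions to sweep.
#' @param n_seeds Seeds per cell.
#' @param n_train,n_eval Training and evaluation trials per run.
#' @param config A [full_config()] object (rate is overridden per cell).
#' @param seed Base seed; run seeds are derived deterministically.
#' @param verbose Print one line per completed cell.
#' @return An object of class `sweep_result`: `grid` tibble with one row per
#'   (rate, fraction, seed) and a `summary` tibble of cell means.
#' @export
run_sweep <- function(local, images, task = "trace",
                      rates = c(6, 8, 10, 12, 14, 16),
                      fractions = c(0.6, 0.7, 0.8, 0.9, 1.0),
                      n_seeds = 3L, n_train = 250L, n_eval = 100L,
                      config = full_config(), seed = 1L, verbose = FALSE) {
  stopifnot(length(rates) > 0, length(fractions) > 0)
  cells <- tidyr::expand_grid(rate_hz = sort(rates),
                              excitatory_fraction = sort(fractions),
                              seed_rep = seq_len(n_seeds))
  frontend <- precompute_frontend(images, local$config,
                                  window_ms = trial_spec(task)$stimulus_ms)
  rows <- purrr::pmap(cells, function(rate_hz, excitatory_fraction,
                                      seed_rep) {
    run_seed <- (seed * 10007L + seed_rep * 211L +
                   match(rate_hz, sort(rates)) * 17L +
                   match(excitatory_fraction, sort(fractions)) * 3L) %%
      .Machine$integer.max
    net <- assemble_full_network(
      local, with_interneurons = excitatory_fraction < 1,
      excitatory_fraction = excitatory_fraction, config = config,
      seed = run_seed)
    trained <- run_conditioning(net, task, images, n_trials = n_train,
                                rate_hz = rate_hz, frontend = frontend,
                                seed = run_seed)
    eval <- evaluate_conditioning(trained$net, task, images,
                                  n_trials = n_eval, rate_hz = rate_hz,
                                  frontend = frontend, seed = run_seed + 1L)
    if (verbose) {
      message(sprintf("rate %4.1f Hz, fraction %.2f, seed %d: accuracy %.2f",
                      rate_hz, excitatory_fraction, seed_rep,
                      mean(eval$trials$correct)))
    }
    tibble::tibble(
      rate_hz = rate_hz, excitatory_fraction = excitatory_fraction,
      seed = seed_rep,
      accuracy = mean(eval$trials$correct),
      train_accuracy = mean(trained$trials$correct),
      trials_to_learn = trials_to_learn(trained)
    )
  })
  grid <- dplyr::bind_rows(rows)
  summary <- grid |>
    dplyr::group_by(.data$rate_hz, .data$excitatory_fraction) |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     n_seeds = dplyr::n(), .groups = "drop")
  structure(list(grid = grid, summary = summary, task = task,
                 n_train = n_train, n_eval = n_eval),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  best <- x$summary[which.max(x$summary$accuracy), ]
  cat(sprintf("<sweep_result> %s | %d cells x %d seeds | best %.1f%% at %g Hz, fraction %g\n",
              x$task, nrow(x$summary), max(x$grid$seed),
              100 * best$accuracy, best$rate_hz, best$excitatory_fraction))
  invisible(x)
}
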