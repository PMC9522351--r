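#' Configuration of the full network (GNW + motor cortex + striatum)
#'
#' Tunable constants for the global level. Synaptic bounds are expressed in
#' threshold units (a weight of `w` depolarizes the target by `w` of the
#' distance from rest to threshold per presynaptic spike). Initial internal
#' GNW weights sit at 1% of their bound; GNW-to-motor weights start at 50%.
#' The trigger stimulus is a nonselective subthreshold depolarizing drive to
#' all excitatory GNW neurons.
#'
#' @param n_gnw Total number of GNW neurons.
#' @param w_max_ee Bound of internal excitatory-excitatory weights.
#' @param w_max_ei Bound of excitatory-to-interneuron weights (large enough
#'   that the 1%-of-bound initial weights already let interneurons follow
#'   the excitatory population).
#' @param w_max_ie Bound of interneuron-sourced (inhibitory) weights.
#' @param init_inh_frac Initial interneuron-endpoint weights as a fraction of
#'   their bound. Excitatory-internal and long-range weights start at the 1%
#'   and 50% initial states of the delay-network description; the inhibitory
#'   scaffold starts functional (inhibition matures early in development) and
#'   is then fine-tuned by the symmetric rule.
#' @param w_mc_max Bound of GNW-to-motor-cortex weights.
#' @param vc_w Mean fixed weight of the S2-to-GNW connections.
#' @param vc_spread Half-width of the fixed, per-neuron uniform jitter of the
#'   S2-to-GNW weight (relative to `vc_w`); heterogeneous input weights
#'   desynchronize the selective-group response so the population can
#'   reverberate instead of firing in lockstep volleys.
#' @param s2_readout_gain Input gain of the matured visual cortex while it
#'   feeds the workspace (the matured network operates at a higher
#'   excitability than during its own maturation, so the responder fires
#'   throughout the stimulus rather than once at the window end).
#' @param trigger_amp Asymptotic depolarization of the trigger drive,
#'   threshold units (subthreshold: < 1).
#' @param kick Potential increment of one spontaneous background event.
#' @param rate_hz Default spontaneous rate per GNW neuron, Hz.
#' @param lif A [lif_params()] object shared by GNW and motor neurons.
#' @param ee_stdp,sym_stdp,da_stdp The three plasticity rules.
#' @param reward_magnitude Dopamine pulse size per reward.
#' @param da_jitter_ms Striatal firing delay range after image onset (1/32 s).
#' @param mc_threshold Motor spikes in the response window needed to "press".
#' @param mc_syn_tau Decay constant of the motor neuron's synaptic current,
#'   ms (exponential-current synapse so motor firing grades with drive).
#' @param tau_syn_vc Decay constant of the sensory (S2-to-GNW) synaptic
#'   current, ms; fast, so the stimulus drive vanishes soon after the image.
#' @param tau_syn_e,tau_syn_i Decay constants of the recurrent excitatory and
#'   inhibitory synaptic currents in the GNW, ms. Slow recurrent excitation
#'   is what lets a selective group hold a stimulus representation as
#'   asynchronous persistent activity across the trace gap.
#' @param decision_x Comparison threshold of the task ("is the digit > x?").
#' @param noinh_ee_scale Scale applied to the internal excitatory bound (and
#'   its STDP increments) when the network is assembled without
#'   interneurons: with no inhibition anywhere, internal excitation must stay
#'   too weak for constant feedback firing, so stimulus representations exist
#'   only while the input is present.
#' @param snapshot_every Weight-log cadence, trials.
#' @return A list of class `full_config`.
#' @export
full_config <- function(n_gnw = 100L,
                        w_max_ee = 0.06, w_max_ei = 0.02, w_max_ie = 0.4,
                        w_mc_max = 0.5, init_inh_frac = 0.75,
                        vc_w = 1.2, vc_spread = 0.5, s2_readout_gain = 0.02,
                        trigger_amp = 0.4,
                        kick = 0.38, rate_hz = 12,
                        lif = lif_params(refractory_ms = 2),
                        ee_stdp = classical_stdp_params(dA_pre = 0.1,
                                                        dA_post = -0.11,
                                                        w_max = w_max_ee),
                        sym_stdp = symmetric_stdp_params(dA_pre = 0.0002, dA_post = 0.0002,
                                                        w_max = w_max_ie),
                        da_stdp = dopamine_stdp_params(dA_post = -0.001,
                                                       tau_c = 250,
                                                       tau_d = 15,
                                                       w_max = w_mc_max),
                        reward_magnitude = 0.8, da_jitter_ms = 1000 / 32,
                        mc_threshold = 3L, decision_x = 0,
                        mc_syn_tau = 20,
                        tau_syn_e = 60, tau_syn_i = 10,
                        tau_syn_vc = 20,
                        noinh_ee_scale = 0.08,
                        snapshot_every = 5L) {
  stopifnot(n_gnw >= 2, rate_hz >= 0, trigger_amp >= 0)
  structure(list(n_gnw = as.integer(n_gnw), w_max_ee = w_max_ee,
                 w_max_ei = w_max_ei, w_max_ie = w_max_ie,
                 w_mc_max = w_mc_max, init_inh_frac = init_inh_frac,
                 vc_w = vc_w, vc_spread = vc_spread,
                 s2_readout_gain = s2_readout_gain,
                 trigger_amp = trigger_amp, kick = kick,
                 rate_hz = rate_hz, lif = lif,
                 ee_stdp = ee_stdp, sym_stdp = sym_stdp, da_stdp = da_stdp,
                 reward_magnitude = reward_magnitude,
                 da_jitter_ms = da_jitter_ms,
                 mc_threshold = as.integer(mc_threshold),
                 decision_x = decision_x, mc_syn_tau = mc_syn_tau,
                 tau_syn_e = tau_syn_e, tau_syn_i = tau_syn_i,
                 tau_syn_vc = tau_syn_vc,
                 noinh_ee_scale = noinh_ee_scale,
                 snapshot_every = as.integer(snapshot_every)),
            class = "full_config")
}

#' Trial timing of the three tasks
#'
#' Recognition: 250 ms stimulus + 250 ms relaxation. Delay conditioning:
#' 150 ms stimulus with the 50 ms trigger coinciding with its last 50 ms.
#' Trace conditioning: 150 ms stimulus, 200 ms silent gap, then the 50 ms
#' trigger. The response window opens at trigger onset and extends 50 ms
#' (delay) or 100 ms (trace) past trigger offset.
#'
#' @param task `"recognition"`, `"delay"` or `"trace"`.
#' @return A list of class `trial_spec` with fields `task`, `stimulus_ms`,
#'   `trace_gap_ms`, `trigger_ms`, `response_extra_ms`, `trial_ms`,
#'   `trigger_onset_ms`.
#' @export
trial_spec <- function(task = c("delay", "trace", "recognition")) {
  task <- match.arg(task)
  spec <- switch(task,
    recognition = list(stimulus_ms = 250, trace_gap_ms = 0, trigger_ms = 0,
                       response_extra_ms = 0, trial_ms = 500),
    delay = list(stimulus_ms = 150, trace_gap_ms = -50, trigger_ms = 50,
                 response_extra_ms = 50, trial_ms = 500),
    trace = list(stimulus_ms = 150, trace_gap_ms = 200, trigger_ms = 50,
                 response_extra_ms = 100, trial_ms = 700)
  )
  spec$task <- task
  spec$trigger_onset_ms <- spec$stimulus_ms + spec$trace_gap_ms
  structure(spec, class = "trial_spec")
}

#' Assemble the full network on top of a matured local network
#'
#' Wires the frozen visual cortex into a global neuronal workspace: each S2
#' cell is connected, with fixed weights, to the selective excitatory group
#' matching its assigned digit; excitatory neurons are split equally between
#' the digit groups; internal GNW connectivity is all-to-all (1% of the
#' bound); the single motor neuron reads only the excitatory population
#' (50% of the bound); the single striatal neuron gates dopamine. Raw pixels
#' are inaccessible: the assembly accepts only a frozen, labelled
#' `local_network`.
#'
#' @param local A frozen [assign_s2_labels()]-labelled `local_network`.
#' @param with_interneurons If `FALSE`, no interneuron population (and hence
#'   no inhibitory synapse) exists anywhere in the GNW — the delay-
#'   conditioning variant.
#' @param excitatory_fraction Fraction of `n_gnw` that is excitatory.
#' @param config A [full_config()] object.
#' @param seed Integer seed for the fixed wiring jitter of the S2-to-GNW
#'   weights.
#' @return An object of class `full_network`.
#' @export
assemble_full_network <- function(local, with_interneurons = TRUE,
                                  excitatory_fraction = 0.8,
                                  config = full_config(), seed = 1L) {
  stopifnot(inherits(local, "local_network"))
  if (!local$frozen) {
    rlang::abort("The local network must be frozen before assembly.",
                 class = "gnwsim_config_error")
  }
  if (is.null(local$label_assignment)) {
    rlang::abort("Assign S2 labels (assign_s2_labels) before assembly.",
                 class = "gnwsim_config_error")
  }
  if (excitatory_fraction <= 0 || excitatory_fraction > 1) {
    rlang::abort("excitatory_fraction must be in (0, 1].",
                 class = "gnwsim_config_error")
  }
  classes <- sort(unique(stats::na.omit(local$label_assignment)))
  if (length(classes) != 2) {
    rlang::abort("Exactly two digit classes must be represented among the S2 labels.",
                 class = "gnwsim_config_error")
  }
  if (!with_interneurons) {
    sc <- config$noinh_ee_scale
    config$w_max_ee <- config$w_max_ee * sc
    config$ee_stdp$dA_pre <- config$ee_stdp$dA_pre * sc
    config$ee_stdp$dA_post <- config$ee_stdp$dA_post * sc
  }
  n_exc <- round(config$n_gnw * excitatory_fraction)
  n_inh <- if (with_interneurons) config$n_gnw - n_exc else 0L
  n_tot <- n_exc + n_inh
  # equal split of the excitatory population into the two selective groups
  group <- rep(c(0L, 1L), c(ceiling(n_exc / 2), floor(n_exc / 2)))
  W <- matrix(0, n_tot, n_tot)
  if (n_tot > 1) {
    ee <- seq_len(n_exc)
    W[ee, ee] <- 0.01 * config$w_max_ee
    if (n_inh > 0) {
      ii <- (n_exc + 1):n_tot
      W[ii, ] <- config$init_inh_frac * config$w_max_ie
      W[, ii] <- config$init_inh_frac * config$w_max_ei
      W[ii, ii] <- config$init_inh_frac * config$w_max_ie
    }
    diag(W) <- 0
  }
  w_mc <- rep(0.5 * config$w_mc_max, n_exc)
  vc_w <- withr::with_seed(seed, {
    config$vc_w * stats::runif(n_exc, 1 - config$vc_spread,
                               1 + config$vc_spread)
  })
  s2_group <- rep(NA_integer_, length(local$label_assignment))
  for (k in seq_along(classes)) {
    s2_group[local$label_assignment == classes[k]] <- k - 1L
  }
  structure(list(
    n_exc = n_exc, n_inh = n_inh, group = group,
    W = W, w_mc = w_mc, vc_w = vc_w,
    classes = classes, s2_group = s2_group,
    local = local, config = config,
    excitatory_fraction = excitatory_fraction
  ), class = "full_network")
}

#' @export
print.full_network <- function(x, ...) {
  cat("<full_network>", x$n_exc, "excitatory +", x$n_inh,
      "interneurons | classes:", paste(x$classes, collapse = "/"),
      "| MC + striatum\n")
  invisible(x)
}

#' Build a deterministic miniature workspace network for validation
#'
#' A hand-wired toy GNW (no visual cortex attached): selective-group
#' membership, every internal weight and the motor weights are set
#' explicitly, so unit tests can probe reward routing, recurrent
#' self-sustainment and inhibitory termination in isolation.
#'
#' @param n_exc,n_inh Population sizes (`n_exc >= 2`).
#' @param groups Integer vector (0/1) of group membership, length `n_exc`.
#' @param w_ee,w_ei,w_ie,w_ii Uniform initial weights per connection class.
#' @param w_mc Uniform GNW-to-motor weight.
#' @param overrides Optional list of `list(from, to, w)` single-synapse
#'   overrides (1-based indices into the GNW), applied verbatim.
#' @param config A [full_config()] object.
#' @return A `full_network` without a local network attached.
#' @export
make_toy_gnw <- function(n_exc, n_inh = 0L,
                         groups = rep(0L, n_exc),
                         w_ee = 0, w_ei = 0, w_ie = 0, w_ii = 0,
                         w_mc = 0.25, overrides = list(),
                         config = full_config(n_gnw = n_exc + n_inh)) {
  stopifnot(n_exc >= 2, length(groups) == n_exc)
  n_tot <- n_exc + n_inh
  W <- matrix(0, n_tot, n_tot)
  ee <- seq_len(n_exc)
  W[ee, ee] <- w_ee
  if (n_inh > 0) {
    ii <- (n_exc + 1):n_tot
    W[ee, ii] <- w_ei
    W[ii, ee] <- w_ie
    W[ii, ii] <- w_ii
  }
  diag(W) <- 0
  for (ov in overrides) W[ov$from, ov$to] <- ov$w
  structure(list(
    n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
    group = as.integer(groups),
    W = W, w_mc = rep(w_mc, n_exc),
    vc_w = rep(config$vc_w, n_exc),
    classes = c(0L, 1L), s2_group = NULL,
    local = NULL, config = config,
    excitatory_fraction = n_exc / n_tot
  ), class = "full_network")
}

# Low-level clock-driven run of a full network on explicit trial inputs.
# `input_spikes` is a list (one numeric vector per trial) of S2 spike times
# relative to trial onset; `trial_group` routes them to a selective group.
gnw_simulate <- function(net, trial_label, trial_group, input_spikes,
                         spec, rate_hz = NULL, plastic = TRUE,
                         plastic_internal = TRUE,
                         record_raster = FALSE, raster_max = 2e6) {
  cfg <- net$config
  rate_hz <- rate_hz %||% cfg$rate_hz
  in_t <- as.numeric(unlist(input_spikes, use.names = FALSE))
  in_off <- c(0L, cumsum(vapply(input_spikes, length, integer(1))))
  res <- cpp_gnw_run(
    net$n_exc, net$n_inh, net$group, net$W, net$w_mc,
    cfg$w_max_ee, cfg$w_max_ei, cfg$w_max_ie, cfg$w_mc_max, net$vc_w,
    as.integer(trial_label), as.integer(trial_group), in_t, in_off,
    spec$stimulus_ms, spec$trace_gap_ms, spec$trigger_ms,
    spec$response_extra_ms, spec$trial_ms, cfg$trigger_amp,
    cfg$lif$tau_m, cfg$lif$v_thresh, cfg$lif$refractory_ms, cfg$lif$dt_ms,
    rate_hz, cfg$kick,
    cfg$ee_stdp$dA_pre, cfg$ee_stdp$dA_post,
    cfg$ee_stdp$tau_pre, cfg$ee_stdp$tau_post,
    cfg$sym_stdp$dA_pre, cfg$sym_stdp$dA_post,
    cfg$sym_stdp$tau_pre, cfg$sym_stdp$tau_post, cfg$sym_stdp$divisor,
    cfg$da_stdp$dA_pre, cfg$da_stdp$dA_post,
    cfg$da_stdp$tau_pre, cfg$da_stdp$tau_post,
    cfg$da_stdp$tau_c, cfg$da_stdp$tau_d, cfg$da_stdp$tau_s,
    cfg$reward_magnitude, cfg$da_jitter_ms,
    cfg$mc_threshold, cfg$decision_x, cfg$mc_syn_tau,
    cfg$tau_syn_e, cfg$tau_syn_i, cfg$tau_syn_vc,
    plastic_internal, plastic,
    cfg$snapshot_every, record_raster, as.integer(raster_max))
  res
}
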