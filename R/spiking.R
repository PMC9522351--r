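#' Leaky integrate-and-fire neuron parameters
#'
#' Normalized-unit LIF constants: resting potential 0, threshold 1. The
#' membrane decays exponentially toward `v_rest + drive` with time constant
#' `tau_m`; a threshold crossing emits a spike, resets the potential to
#' `v_reset` and opens an absolute refractory period.
#'
#' @param tau_m Membrane time constant, ms.
#' @param v_rest,v_reset,v_thresh Potentials in normalized units
#'   (`v_reset <= v_rest < v_thresh`).
#' @param refractory_ms Absolute refractory period, ms.
#' @param dt_ms Simulation step, ms (clock-driven mode).
#' @return A list of class `lif_params`.
#' @export
lif_params <- function(tau_m = 10, v_rest = 0, v_reset = 0, v_thresh = 1,
                       refractory_ms = 1, dt_ms = 0.1) {
  stopifnot(tau_m > 0, dt_ms > 0, v_reset <= v_rest, v_rest < v_thresh)
  if (dt_ms > tau_m / 10) {
    rlang::abort("dt_ms must be at most tau_m / 10 for a stable simulation.",
                 class = "gnwsim_config_error")
  }
  structure(list(tau_m = tau_m, v_rest = v_rest, v_reset = v_reset,
                 v_thresh = v_thresh, refractory_ms = refractory_ms,
                 dt_ms = dt_ms),
            class = "lif_params")
}

#' Initialize the state of an LIF population
#'
#' @param n Number of neurons.
#' @param params A [lif_params()] object.
#' @param role Population role label.
#' @return A list with `v`, `last_spike`, `role`, `t`.
#' @export
init_population <- function(n, params = lif_params(),
                            role = c("excitatory", "inhibitory", "input",
                                     "motor", "dopamine")) {
  role <- match.arg(role)
  list(v = rep(params$v_rest, n), last_spike = rep(-Inf, n),
       role = role, t = 0)
}

#' Advance an LIF population by one time step
#'
#' Exact exponential integration: over the step the membrane relaxes toward
#' `v_rest + drive` with constant drive, then instantaneous `input` increments
#' (synaptic or background kicks) are applied. Neurons at or above threshold
#' spike, reset, and enter the refractory period; refractory neurons ignore
#' input and stay at `v_reset`.
#'
#' @param state A population state from [init_population()].
#' @param params A [lif_params()] object.
#' @param input Instantaneous potential increments this step (scalar or
#'   vector).
#' @param drive Constant depolarizing drive in threshold units (asymptotic
#'   depolarization if held forever); scalar or vector.
#' @return A list with the updated `state` and an integer vector `spikes` of
#'   neuron indices that fired during this step.
#' @export
step_population <- function(state, params, input = 0, drive = 0) {
  if (!all(is.finite(input)) || !all(is.finite(drive))) {
    rlang::abort("Non-finite input to step_population().",
                 class = "gnwsim_numeric_error")
  }
  dt <- params$dt_ms
  t_new <- state$t + dt
  decay <- exp(-dt / params$tau_m)
  target <- params$v_rest + drive
  v <- target + (state$v - target) * decay
  refr <- (t_new - state$last_spike) <= params$refractory_ms
  v <- v + ifelse(refr, 0, input)
  v[refr] <- params$v_reset
  spikes <- which(v >= params$v_thresh & !refr)
  v[spikes] <- params$v_reset
  state$last_spike[spikes] <- t_new
  state$v <- v
  state$t <- t_new
  list(state = state, spikes = spikes)
}

#' Sample background (spontaneous) activity events
#'
#' Independent homogeneous Poisson processes, one per neuron, emulating the
#' spontaneous intrinsic activity injected into the network. Events are
#' applied by the simulators as fixed-size potential kicks.
#'
#' @param rate_hz Per-neuron event rate, Hz (>= 0).
#' @param n_neurons Number of neurons.
#' @param duration_ms Window length, ms.
#' @return A tibble with columns `neuron`, `t_ms`, sorted by time.
#' @export
sample_background <- function(rate_hz, n_neurons, duration_ms) {
  stopifnot(rate_hz >= 0, n_neurons >= 1, duration_ms > 0)
  if (rate_hz == 0) {
    return(tibble::tibble(neuron = integer(), t_ms = numeric()))
  }
  counts <- stats::rpois(n_neurons, rate_hz * duration_ms / 1000)
  neuron <- rep(seq_len(n_neurons), counts)
  t_ms <- stats::runif(sum(counts), 0, duration_ms)
  ord <- order(t_ms)
  tibble::tibble(neuron = neuron[ord], t_ms = t_ms[ord])
}

#' Sinusoidal (alpha-like) gain modulation
#'
#' Multiplicative gain applied to the input drive of S2 cells:
#' `gain(t) = 1 + m * sin(2 * pi * t / period + phase)`. The default phase
#' offset of `pi/8` keeps the wave slightly out of phase with the image
#' presentations; troughs fall inside relaxation windows and clear residual
#' spontaneous activity while crests amplify the stimulus-driven signal.
#'
#' @param amplitude Modulation depth `m` (0 disables modulation).
#' @param period_ms Modulation period, ms.
#' @param phase_offset Phase, radians.
#' @return A list of class `alpha_modulation`.
#' @export
alpha_modulation <- function(amplitude = 0.5, period_ms = 500,
                             phase_offset = pi / 8) {
  stopifnot(period_ms > 0, amplitude >= 0)
  structure(list(amplitude = amplitude, period_ms = period_ms,
                 phase_offset = phase_offset),
            class = "alpha_modulation")
}

#' @rdname alpha_modulation
#' @param t_ms Time(s) in ms.
#' @param mod An `alpha_modulation` object.
#' @export
alpha_gain <- function(t_ms, mod = alpha_modulation()) {
  1 + mod$amplitude * sin(2 * pi * t_ms / mod$period_ms + mod$phase_offset)
}

#' Construct a spike raster
#'
#' @param neuron Integer neuron ids.
#' @param t_ms Spike times, ms.
#' @param duration_ms Total duration covered by the raster.
#' @return A tibble of class `spike_raster`, sorted by time.
#' @export
spike_raster <- function(neuron, t_ms, duration_ms) {
  stopifnot(length(neuron) == length(t_ms),
            all(t_ms >= 0), all(t_ms <= duration_ms))
  ord <- order(t_ms, neuron)
  out <- tibble::tibble(neuron = as.integer(neuron[ord]), t_ms = t_ms[ord])
  attr(out, "duration_ms") <- duration_ms
  class(out) <- c("spike_raster", class(out))
  out
}
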