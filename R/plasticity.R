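#' Synapse population
#'
#' Bounded synaptic weights between a presynaptic and a postsynaptic
#' population. Weights are hard-clipped to `[0, w_max]` after every plasticity
#' update; populations marked non-plastic are never modified.
#'
#' @param w Numeric matrix `n_pre x n_post` of initial weights.
#' @param w_max Upper weight bound.
#' @param plastic Logical; frozen populations ignore all updates.
#' @param orientation Optional per-presynaptic-cell orientation tag, radians
#'   (used by the visual-cortex reconstruction).
#' @return A list of class `synapse_population`.
#' @export
synapse_population <- function(w, w_max = 1, plastic = TRUE,
                               orientation = NULL) {
  w <- as.matrix(w)
  stopifnot(w_max > 0, all(w >= 0), all(w <= w_max))
  structure(list(w = w, w_max = w_max, plastic = plastic,
                 orientation = orientation),
            class = "synapse_population")
}

#' Parameters of the classical (asymmetric) STDP rule
#'
#' Pre- and postsynaptic traces decay exponentially
#' (`tau dA/dt = -A`). A presynaptic spike adds `dA_pre > 0` to its trace and
#' changes the weight by the current postsynaptic trace (depression, since
#' `dA_post < 0`); a postsynaptic spike adds `dA_post` to its trace and
#' changes the weight by the presynaptic trace (potentiation). The slight
#' depression bias of the defaults (`|dA_post| > dA_pre`) prunes synapses
#' carrying uncorrelated input, driving the elimination dynamics of synaptic
#' epigenesis.
#'
#' @param dA_pre Positive presynaptic trace increment (fraction of `w_max`).
#' @param dA_post Negative postsynaptic trace increment.
#' @param tau_pre,tau_post Trace time constants, ms.
#' @param w_max Weight bound the increments are scaled against.
#' @return A list of class `classical_stdp`.
#' @export
classical_stdp_params <- function(dA_pre = 0.01, dA_post = -0.012,
                                  tau_pre = 20, tau_post = 20, w_max = 1) {
  stopifnot(dA_pre > 0, dA_post < 0, tau_pre > 0, tau_post > 0)
  structure(list(dA_pre = dA_pre * w_max, dA_post = dA_post * w_max,
                 tau_pre = tau_pre, tau_post = tau_post),
            class = c("classical_stdp", "stdp_params"))
}

#' Parameters of the symmetric (GABAergic) STDP rule
#'
#' Both trace increments are positive, but the traces relax toward the
#' negative fixed point `-dA/divisor` (`tau dA/dt = -A - dA/divisor`): a pair
#' of spikes with short temporal distance potentiates (the partner trace is
#' still positive), while distant pairs pick up the negative resting trace
#' and depress. Used for every synapse with an interneuron endpoint.
#'
#' @param dA_pre,dA_post Positive trace increments (fractions of `w_max`).
#' @param tau_pre,tau_post Trace time constants, ms.
#' @param divisor Resting-trace divisor (fixed point `-dA/divisor`).
#' @param w_max Weight bound the increments are scaled against.
#' @return A list of class `symmetric_stdp`.
#' @export
symmetric_stdp_params <- function(dA_pre = 0.01, dA_post = 0.01,
                                  tau_pre = 20, tau_post = 20,
                                  divisor = 15, w_max = 1) {
  stopifnot(dA_pre > 0, dA_post > 0, divisor > 0)
  structure(list(dA_pre = dA_pre * w_max, dA_post = dA_post * w_max,
                 tau_pre = tau_pre, tau_post = tau_post, divisor = divisor),
            class = c("symmetric_stdp", "stdp_params"))
}

#' Parameters of the dopamine-modulated STDP rule
#'
#' Spike timing writes an eligibility trace `c` exactly as classical STDP
#' would write the weight; the weight itself changes only in the presence of
#' a dopamine deviation `d` from baseline, through the increment variable
#' `s`: `tau_s ds/dt = -s + c d`, `dw/dt = s`. `d` relaxes exponentially back
#' to baseline (0) with `tau_d`; `c` decays with `tau_c`, bridging the gap
#' between an action and its delayed reward.
#'
#' @param dA_pre,dA_post Trace increments as in [classical_stdp_params()].
#' @param tau_pre,tau_post Trace time constants, ms.
#' @param tau_c Eligibility-trace time constant, ms.
#' @param tau_d Dopamine relaxation time constant, ms.
#' @param tau_s Weight-increment time constant, ms.
#' @param w_max Weight bound the increments are scaled against.
#' @return A list of class `dopamine_stdp`.
#' @export
dopamine_stdp_params <- function(dA_pre = 0.01, dA_post = -0.012,
                                 tau_pre = 20, tau_post = 20,
                                 tau_c = 1000, tau_d = 200, tau_s = 1,
                                 w_max = 1) {
  stopifnot(dA_pre > 0, dA_post < 0, tau_c > 0, tau_d > 0, tau_s > 0)
  structure(list(dA_pre = dA_pre * w_max, dA_post = dA_post * w_max,
                 tau_pre = tau_pre, tau_post = tau_post,
                 tau_c = tau_c, tau_d = tau_d, tau_s = tau_s),
            class = c("dopamine_stdp", "stdp_params"))
}

#' Initialize a plasticity state for a synapse population
#'
#' Traces are kept per neuron (one presynaptic trace per source neuron, one
#' postsynaptic trace per target neuron), which is mathematically identical
#' to per-synapse traces for these rules but linear in memory. Decay is
#' applied lazily and analytically at event times.
#'
#' @param n_pre,n_post Population sizes.
#' @param params An `stdp_params` object.
#' @return A list of class `plasticity_state`.
#' @export
plasticity_state <- function(n_pre, n_post, params) {
  st <- list(
    A_pre = numeric(n_pre), A_post = numeric(n_post),
    t_pre = numeric(n_pre), t_post = numeric(n_post),
    params = params
  )
  if (inherits(params, "dopamine_stdp")) {
    st$c <- matrix(0, n_pre, n_post)
    st$d <- 0
    st$s <- matrix(0, n_pre, n_post)
    st$t <- 0
  }
  structure(st, class = "plasticity_state")
}

# analytic decay of a trace vector toward `rest` from its own last-event time
decay_trace <- function(A, t_last, t, tau, rest = 0) {
  rest + (A - rest) * exp(-(t - t_last) / tau)
}

trace_rest <- function(params, side) {
  if (inherits(params, "symmetric_stdp")) {
    -params[[paste0("dA_", side)]] / params$divisor
  } else {
    0
  }
}

clip_w <- function(w, w_max) pmin(pmax(w, 0), w_max)

#' Classical STDP event updates
#'
#' `classical_on_pre()` processes a presynaptic spike at time `t`: the
#' synapse weights out of `pre_id` are changed by the (decayed) postsynaptic
#' traces, then the presynaptic trace is incremented. `classical_on_post()`
#' is the mirror image for a postsynaptic spike. At coincident events the
#' presynaptic event is processed first (tie rule).
#'
#' @param syn A [synapse_population()].
#' @param state A [plasticity_state()] built with [classical_stdp_params()].
#' @param t Event time, ms (non-decreasing across calls).
#' @param pre_id,post_id 1-based neuron index of the spiking neuron.
#' @return A list with updated `syn` and `state`.
#' @export
classical_on_pre <- function(syn, state, t, pre_id) {
  stdp_on_event(syn, state, t, pre_id, side = "pre")
}

#' @rdname classical_on_pre
#' @export
classical_on_post <- function(syn, state, t, post_id) {
  stdp_on_event(syn, state, t, post_id, side = "post")
}

#' Symmetric STDP event update
#'
#' One entry point for either event kind; the own trace is incremented by its
#' (positive) `dA`, and the partner trace value — possibly negative, having
#' relaxed toward `-dA/divisor` — is added to the weight.
#'
#' @inheritParams classical_on_pre
#' @param event_kind `"pre"` or `"post"`.
#' @param id 1-based index of the spiking neuron on that side.
#' @return A list with updated `syn` and `state`.
#' @export
symmetric_update <- function(syn, state, t, event_kind = c("pre", "post"),
                             id) {
  side <- match.arg(event_kind)
  stdp_on_event(syn, state, t, id, side = side)
}

# shared event machinery: works for classical, symmetric and the eligibility
# trace of the dopamine rule (which targets `c` instead of `w`)
stdp_on_event <- function(syn, state, t, id, side) {
  p <- state$params
  dopa <- inherits(p, "dopamine_stdp")
  target <- if (dopa) state$c else syn$w
  if (side == "pre") {
    rest_post <- trace_rest(p, "post")
    state$A_post <- decay_trace(state$A_post, state$t_post, t, p$tau_post,
                                rest_post)
    state$t_post[] <- t
    if (syn$plastic) {
      target[id, ] <- target[id, ] + state$A_post
    }
    state$A_pre[id] <- decay_trace(state$A_pre[id], state$t_pre[id], t,
                                   p$tau_pre, trace_rest(p, "pre")) + p$dA_pre
    state$t_pre[id] <- t
  } else {
    rest_pre <- trace_rest(p, "pre")
    state$A_pre <- decay_trace(state$A_pre, state$t_pre, t, p$tau_pre,
                               rest_pre)
    state$t_pre[] <- t
    if (syn$plastic) {
      target[, id] <- target[, id] + state$A_pre
    }
    state$A_post[id] <- decay_trace(state$A_post[id], state$t_post[id], t,
                                    p$tau_post, trace_rest(p, "post")) +
      p$dA_post
    state$t_post[id] <- t
  }
  if (syn$plastic) {
    if (dopa) {
      state$c <- target
    } else {
      syn$w <- clip_w(target, syn$w_max)
    }
  }
  list(syn = syn, state = state)
}

#' Dopamine-modulated STDP event and step updates
#'
#' `dopamine_on_pre()`/`dopamine_on_post()` update the eligibility trace `c`
#' exactly as classical STDP would update the weight. `dopamine_update()`
#' advances the continuous variables by one step `dt`: the dopamine deviation
#' `d` and eligibility `c` decay exponentially, the increment variable `s`
#' relaxes toward `c d`, and the weight integrates `s` (clipped to bounds).
#' With `d = 0` throughout, weights never change.
#'
#' @inheritParams classical_on_pre
#' @param dt Step length, ms.
#' @return A list with updated `syn` and `state`.
#' @export
dopamine_on_pre <- function(syn, state, t, pre_id) {
  stdp_on_event(syn, state, t, pre_id, side = "pre")
}

#' @rdname dopamine_on_pre
#' @export
dopamine_on_post <- function(syn, state, t, post_id) {
  stdp_on_event(syn, state, t, post_id, side = "post")
}

#' @rdname dopamine_on_pre
#' @export
dopamine_update <- function(syn, state, dt) {
  p <- state$params
  state$d <- state$d * exp(-dt / p$tau_d)
  state$c <- state$c * exp(-dt / p$tau_c)
  cd <- state$c * state$d
  state$s <- cd + (state$s - cd) * exp(-dt / p$tau_s)
  if (syn$plastic) {
    syn$w <- clip_w(syn$w + dt * state$s, syn$w_max)
  }
  state$t <- state$t + dt
  list(syn = syn, state = state)
}

#' Deliver a reward through the dopamine pathway
#'
#' Adds a signed pulse to the extracellular dopamine deviation `d` (positive
#' reward raises the concentration above baseline, negative reward lowers
#' it); `d` subsequently relaxes exponentially back to baseline.
#'
#' @param state A dopamine [plasticity_state()].
#' @param sign `+1` or `-1`.
#' @param magnitude Pulse size (>= 0).
#' @return The updated state.
#' @export
apply_reward <- function(state, sign, magnitude) {
  stopifnot(sign %in% c(-1, 1), magnitude >= 0)
  state$d <- state$d + sign * magnitude
  state
}
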