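#' Closed-form / dense-integration oracle for an isolated STDP spike pair
#'
#' Predicts the total weight change produced by one isolated presynaptic /
#' postsynaptic spike pair with temporal offset `delta_t` (post minus pre;
#' positive means pre leads), starting from fully rested traces. The
#' classical rule is evaluated in closed form
#' (`dA_pre * exp(-dt/tau_pre)` for `delta_t > 0`,
#' `dA_post * exp(-|dt|/tau_post)` for `delta_t < 0`; at `delta_t = 0` the
#' presynaptic event is processed first by convention). The symmetric rule is
#' integrated densely with an independent explicit-Euler discretization at a
#' 100-fold finer step than the simulators use.
#'
#' @param rule `"classical"` or `"symmetric"`.
#' @param params A matching `stdp_params` object.
#' @param delta_t Temporal offsets, ms (vectorized).
#' @param rest_ms Silent interval before the pair (symmetric rule only);
#'   defaults to ten time constants so traces sit at their fixed point.
#' @param dt_fine Euler step of the dense integration, ms.
#' @return Numeric vector of predicted weight changes.
#' @export
stdp_pair_oracle <- function(rule = c("classical", "symmetric"), params,
                             delta_t, rest_ms = NULL, dt_fine = 0.001) {
  rule <- match.arg(rule)
  if (rule == "classical") {
    return(vapply(delta_t, function(dt) {
      if (dt > 0) {
        params$dA_pre * exp(-dt / params$tau_pre)
      } else if (dt < 0) {
        params$dA_post * exp(dt / params$tau_post)
      } else {
        params$dA_pre  # tie rule: pre processed first, post picks up dA_pre
      }
    }, numeric(1)))
  }
  rest_ms <- rest_ms %||% (10 * max(params$tau_pre, params$tau_post))
  vapply(delta_t, function(dtt) {
    t_pre <- if (dtt >= 0) rest_ms else rest_ms - dtt
    t_post <- if (dtt >= 0) rest_ms + dtt else rest_ms
    n_steps <- ceiling(max(t_pre, t_post) / dt_fine) + 1L
    a_pre <- 0; a_post <- 0; dw <- 0
    pre_done <- FALSE; post_done <- FALSE
    for (k in 0:n_steps) {
      t <- k * dt_fine
      if (!pre_done && t >= t_pre - dt_fine / 2) {
        pre_done <- TRUE
        dw <- dw + a_post       # partner trace potentiates/depresses
        a_pre <- a_pre + params$dA_pre
      }
      if (!post_done && t >= t_post - dt_fine / 2) {
        post_done <- TRUE
        dw <- dw + a_pre
        a_post <- a_post + params$dA_post
      }
      a_pre <- a_pre + dt_fine *
        (-a_pre - params$dA_pre / params$divisor) / params$tau_pre
      a_post <- a_post + dt_fine *
        (-a_post - params$dA_post / params$divisor) / params$tau_post
    }
    dw
  }, numeric(1))
}

#' Run an isolated pair protocol through the event-driven plasticity rules
#'
#' Drives a single synapse of the package's own event-driven implementation
#' with one pre/post spike pair per `delta_t` (pairs separated by a long
#' rest) and reports the weight change per pair. Used to validate the
#' implementation against [stdp_pair_oracle()].
#'
#' @param rule `"classical"` or `"symmetric"`.
#' @param params A matching `stdp_params` object.
#' @param delta_t Temporal offsets, ms.
#' @param w0 Initial weight (mid-range by default so changes never clip).
#' @param w_max Weight bound.
#' @return Numeric vector of measured weight changes, one per `delta_t`.
#' @export
stdp_pair_measure <- function(rule = c("classical", "symmetric"), params,
                              delta_t, w0 = 0.5, w_max = 1) {
  rule <- match.arg(rule)
  rest <- 20 * max(params$tau_pre, params$tau_post)
  vapply(delta_t, function(dtt) {
    syn <- synapse_population(matrix(w0, 1, 1), w_max = w_max)
    st <- plasticity_state(1, 1, params)
    t_pre <- if (dtt >= 0) rest else rest - dtt
    t_post <- if (dtt >= 0) rest + dtt else rest
    events <- tibble::tibble(t = c(t_pre, t_post), side = c("pre", "post"))
    events <- events[order(events$t, events$side != "pre"), ]
    for (k in seq_len(nrow(events))) {
      up <- if (rule == "classical") {
        if (events$side[k] == "pre") {
          classical_on_pre(syn, st, events$t[k], 1)
        } else {
          classical_on_post(syn, st, events$t[k], 1)
        }
      } else {
        symmetric_update(syn, st, events$t[k], events$side[k], 1)
      }
      syn <- up$syn; st <- up$state
    }
    syn$w[1, 1] - w0
  }, numeric(1))
}
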