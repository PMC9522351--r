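#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a conditioning run
#'
#' @param x A `conditioning_run`.
#' @param ... Unused.
#' @return The per-trial tibble.
#' @export
tidy.conditioning_run <- function(x, ...) x$trials

#' @rdname tidy.conditioning_run
#' @export
glance.conditioning_run <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    n_trials = nrow(x$trials),
    accuracy = mean(x$trials$correct),
    press_rate = mean(x$trials$pressed),
    trials_to_learn = trials_to_learn(x, window = min(20L, nrow(x$trials))),
    rate_hz = x$rate_hz,
    plastic = x$plastic
  )
}

#' Tidy a sweep result
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return One row per (rate, fraction, seed).
#' @export
tidy.sweep_result <- function(x, ...) x$grid

#' @rdname tidy.sweep_result
#' @export
glance.sweep_result <- function(x, ...) {
  best <- x$summary[which.max(x$summary$accuracy), ]
  tibble::tibble(
    task = x$task,
    n_cells = nrow(x$summary),
    best_accuracy = best$accuracy,
    best_rate_hz = best$rate_hz,
    best_fraction = best$excitatory_fraction
  )
}

#' Tidy a recognition evaluation
#'
#' @param x A `recognition_eval`.
#' @param ... Unused.
#' @return The per-image tibble.
#' @export
tidy.recognition_eval <- function(x, ...) x$results

#' @rdname tidy.recognition_eval
#' @export
glance.recognition_eval <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    n_images = nrow(x$results),
    n_unclassified = sum(is.na(x$results$predicted)),
    rate_hz = x$rate_hz
  )
}

#' Tidy a local network
#'
#' @param x A `local_network`.
#' @param ... Unused.
#' @return The state-fraction table of its epigenesis trajectory.
#' @export
tidy.local_network <- function(x, ...) state_fractions(x$trajectory)

#' @rdname tidy.local_network
#' @export
glance.local_network <- function(x, ...) {
  sf <- state_fractions(x$trajectory)
  last <- sf[nrow(sf), ]
  tibble::tibble(
    n_synapses = ncol(x$trajectory$snapshots),
    n_s2 = ncol(x$w),
    presentations = max(x$trajectory$presentations),
    eliminated = last$eliminated,
    selected = last$selected,
    n_labelled = sum(!is.na(x$label_assignment %||% NA))
  )
}
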