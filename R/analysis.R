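#' Epigenesis trajectory of a synaptic population
#'
#' Periodic snapshots of every synaptic weight during learning, plus the
#' selection thresholds: synapses below 25% of the bound count as eliminated,
#' above 75% as selected, everything between as undetermined.
#'
#' @param presentations Integer vector of presentation counts, increasing.
#' @param snapshots Numeric matrix, one row per snapshot, one column per
#'   synapse; values within `[0, w_max]`.
#' @param w_max Weight bound.
#' @param thresholds Low/high thresholds as fractions of `w_max`.
#' @return An object of class `epigenesis_trajectory`.
#' @export
new_epigenesis_trajectory <- function(presentations, snapshots, w_max = 1,
                                      thresholds = c(low = 0.25,
                                                     high = 0.75)) {
  snapshots <- as.matrix(snapshots)
  stopifnot(length(presentations) == nrow(snapshots),
            !is.unsorted(presentations),
            thresholds[1] > 0, thresholds[1] < thresholds[2],
            thresholds[2] < 1)
  structure(list(presentations = as.integer(presentations),
                 snapshots = snapshots, w_max = w_max,
                 thresholds = thresholds),
            class = "epigenesis_trajectory")
}

#' @export
print.epigenesis_trajectory <- function(x, ...) {
  cat("<epigenesis_trajectory>", ncol(x$snapshots), "synapses x",
      nrow(x$snapshots), "snapshots (0 to",
      max(x$presentations), "presentations)\n")
  invisible(x)
}

as_trajectory <- function(x) {
  if (inherits(x, "local_network")) x$trajectory else x
}

#' Percentile trajectories of the synaptic weight distribution
#'
#' Empirical percentiles (linear interpolation between order statistics) of
#' the whole weight population at every snapshot; the default steps run from
#' the 0th to the 100th percentile in steps of 10.
#'
#' @param traj An `epigenesis_trajectory` (or a `local_network`).
#' @param percentiles Percentile ranks in `[0, 100]`.
#' @return A tibble with columns `presentations`, `percentile`, `weight`.
#' @export
percentile_trajectories <- function(traj, percentiles = seq(0, 100, 10)) {
  traj <- as_trajectory(traj)
  if (ncol(traj$snapshots) == 0) {
    rlang::abort("Trajectory has no synapses.",
                 class = "gnwsim_evaluation_error")
  }
  purrr::map_dfr(seq_along(traj$presentations), function(i) {
    q <- stats::quantile(traj$snapshots[i, ], probs = percentiles / 100,
                         names = FALSE, type = 7)
    tibble::tibble(presentations = traj$presentations[i],
                   percentile = percentiles, weight = q)
  })
}

#' Selected / undetermined / eliminated fractions over learning
#'
#' Partitions the synaptic population at every snapshot: eliminated below
#' the low threshold, selected above the high threshold, undetermined in
#' between. The three fractions sum to one exactly.
#'
#' @param traj An `epigenesis_trajectory` (or a `local_network`).
#' @return A tibble with columns `presentations`, `eliminated`,
#'   `undetermined`, `selected`.
#' @export
state_fractions <- function(traj) {
  traj <- as_trajectory(traj)
  low <- traj$thresholds[1] * traj$w_max
  high <- traj$thresholds[2] * traj$w_max
  purrr::map_dfr(seq_along(traj$presentations), function(i) {
    w <- traj$snapshots[i, ]
    el <- mean(w < low)
    se <- mean(w > high)
    tibble::tibble(presentations = traj$presentations[i],
                   eliminated = el, undetermined = 1 - el - se,
                   selected = se)
  })
}

#' Two-stage growth-rate statistics of synaptic selection
#'
#' Learning proceeds in two stages: a rapid reorganization over roughly the
#' first 200 presentations, then slow consolidation. For the selected and the
#' eliminated group separately, the per-interval growth rate of the group
#' fraction (first difference per snapshot interval) is compared before vs
#' after the stage boundary with Welch's t test; the effect size is Cohen's d
#' with pooled SD.
#'
#' @param traj An `epigenesis_trajectory` (or a `local_network`).
#' @param boundary Presentation count separating the stages.
#' @return A tibble with one row per group: `group`, `n_before`, `n_after`,
#'   `mean_before`, `mean_after`, `t`, `p_value`, `cohens_d`, `boundary`.
#' @export
stage_statistics <- function(traj, boundary = 200) {
  traj <- as_trajectory(traj)
  fr <- state_fractions(traj)
  if (boundary <= min(fr$presentations) || boundary >= max(fr$presentations)) {
    rlang::abort("Stage boundary must lie inside the snapshot range.",
                 class = "gnwsim_evaluation_error")
  }
  mids <- (fr$presentations[-1] + fr$presentations[-nrow(fr)]) / 2
  out <- lapply(c("selected", "eliminated"), function(grp) {
    rate <- diff(fr[[grp]])
    before <- rate[mids <= boundary]
    after <- rate[mids > boundary]
    if (length(before) < 3 || length(after) < 3) {
      rlang::abort("Need at least 3 snapshot intervals on each side of the boundary.",
                   class = "gnwsim_evaluation_error")
    }
    n1 <- length(before); n2 <- length(after)
    sp <- sqrt(((n1 - 1) * stats::var(before) + (n2 - 1) * stats::var(after)) /
                 (n1 + n2 - 2))
    if (sp == 0) {
      rlang::abort("Zero pooled SD: degenerate growth-rate samples.",
                   class = "gnwsim_degenerate_statistics")
    }
    tt <- stats::t.test(before, after)  # Welch
    tibble::tibble(
      group = grp, n_before = n1, n_after = n2,
      mean_before = mean(before), mean_after = mean(after),
      t = unname(tt$statistic), p_value = tt$p.value,
      cohens_d = abs(mean(before) - mean(after)) / sp,
      boundary = boundary
    )
  })
  dplyr::bind_rows(out)
}

#' Write the analysis tables of a training run to a directory
#'
#' Emits tidy CSV tables (percentiles, state fractions, stage statistics)
#' and, when the `yaml` package is available, the run configuration.
#'
#' @param traj An `epigenesis_trajectory` (or a `local_network`).
#' @param dir Output directory (created if needed).
#' @param boundary Stage boundary for [stage_statistics()].
#' @return Invisibly, the vector of files written.
#' @export
write_epigenesis_tables <- function(traj, dir, boundary = 200) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    percentiles = file.path(dir, "percentile_trajectories.csv"),
    states = file.path(dir, "state_fractions.csv"),
    stages = file.path(dir, "stage_statistics.csv")
  )
  utils::write.csv(percentile_trajectories(traj), files["percentiles"],
                   row.names = FALSE)
  utils::write.csv(state_fractions(traj), files["states"],
                   row.names = FALSE)
  st <- try(stage_statistics(traj, boundary), silent = TRUE)
  if (!inherits(st, "try-error")) {
    utils::write.csv(st, files["stages"], row.names = FALSE)
  }
  invisible(files)
}
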