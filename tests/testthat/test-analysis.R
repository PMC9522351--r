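make_traj <- function(snapshots, presentations = NULL, w_max = 1) {
  snapshots <- as.matrix(snapshots)
  presentations <- presentations %||% ((seq_len(nrow(snapshots)) - 1) * 10)
  gnwsim::new_epigenesis_trajectory(presentations, snapshots, w_max)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("percentile trajectories follow the empirical quantiles", {
  tr <- make_traj(rbind(rep(0.4, 50), rep(0.9, 50)))
  pt <- percentile_trajectories(tr)
  expect_true(all(pt$weight[pt$presentations == 0] == 0.4))
  expect_true(all(pt$weight[pt$presentations == 10] == 0.9))
  # half zeros, half w_max: median by linear interpolation
  w <- c(rep(0, 10), rep(1, 10))
  pt2 <- percentile_trajectories(make_traj(rbind(w)), percentiles = 50)
  expect_equal(pt2$weight, unname(stats::quantile(w, 0.5)))
  # monotone in percentile rank at every snapshot
  tr3 <- make_traj(rbind(runif(100), runif(100)))
  pt3 <- percentile_trajectories(tr3)
  for (p in unique(pt3$presentations)) {
    expect_false(is.unsorted(pt3$weight[pt3$presentations == p]))
  }
})

test_that("state fractions partition the population exactly", {
  tr <- make_traj(rbind(c(0.1, 0.5, 0.9)))
  sf <- state_fractions(tr)
  expect_equal(unlist(sf[1, c("eliminated", "undetermined", "selected")]),
               c(eliminated = 1 / 3, undetermined = 1 / 3, selected = 1 / 3))
  # initial normal(70%, 2%) population is almost entirely undetermined
  withr::with_seed(1, {
    w0 <- pmin(pmax(rnorm(52920, 0.7, 0.02), 0), 1)
  })
  sf0 <- state_fractions(make_traj(rbind(w0)))
  expect_equal(sf0$undetermined, 0.994, tolerance = 0.002)
  # partition conservation on arbitrary snapshots
  tr2 <- make_traj(matrix(runif(500), 5, 100))
  sf2 <- state_fractions(tr2)
  expect_equal(sf2$eliminated + sf2$undetermined + sf2$selected,
               rep(1, 5))
})

test_that("stage statistics compare growth rates across the boundary", {
  # construct fractions with a sharp rate change at the boundary:
  # selected fraction grows 0.05/interval before, 0.005/interval after
  n_syn <- 1000
  pres <- seq(0, 400, by = 10)
  two_stage <- function(p, fast, slow, knee = 200) {
    if (p <= knee) fast * (p / 10) else fast * knee / 10 + slow * ((p - knee) / 10)
  }
  withr::with_seed(8, {
    sel <- vapply(pres, two_stage, numeric(1), fast = 0.005, slow = 5e-4) +
      c(0, cumsum(runif(length(pres) - 1, 0, 2e-4)))
    eli <- vapply(pres, two_stage, numeric(1), fast = 0.008, slow = 8e-4) +
      c(0, cumsum(runif(length(pres) - 1, 0, 2e-4)))
  })
  snaps <- t(mapply(function(fs, fe) {
    ns <- round(fs * n_syn); ne <- round(fe * n_syn)
    c(rep(0.9, ns), rep(0.1, ne), rep(0.5, n_syn - ns - ne))
  }, sel, eli))
  tr <- make_traj(snaps, presentations = pres)
  st <- stage_statistics(tr, boundary = 200)
  sel <- st[st$group == "selected", ]
  expect_gt(sel$cohens_d, 5)
  expect_lt(sel$p_value, 1e-6)
  expect_equal(sel$n_before + sel$n_after, length(pres) - 1)

  # hand-computed 4+4 example against the direct formulas
  before <- c(0.9, 1.1, 1.0, 1.2); after <- c(0.1, 0.2, 0.15, 0.05)
  # build fraction steps realizing exactly these rates; the eliminated
  # fraction gets distinct rates so its statistics are non-degenerate
  fr <- cumsum(c(0, before, after)) / 100
  fe <- cumsum(c(0, rev(before), rev(after))) / 100
  snaps2 <- t(mapply(function(f, g) {
    ns <- round(f * 1e4); ne <- round(g * 1e4)
    c(rep(0.9, ns), rep(0.1, ne), rep(0.5, 1e4 - ns - ne))
  }, fr, fe))
  tr2 <- make_traj(snaps2, presentations = seq(0, 80, by = 10))
  st2 <- stage_statistics(tr2, boundary = 40)
  sel2 <- st2[st2$group == "selected", ]
  rates_b <- before / 100; rates_a <- after / 100
  sp <- sqrt((3 * var(rates_b) + 3 * var(rates_a)) / 6)
  d_direct <- abs(mean(rates_b) - mean(rates_a)) / sp
  tt_direct <- t.test(rates_b, rates_a)
  expect_equal(sel2$cohens_d, d_direct, tolerance = 1e-6)
  expect_equal(sel2$p_value, tt_direct$p.value, tolerance = 1e-6)
  expect_equal(sel2$t, unname(tt_direct$statistic), tolerance = 1e-6)
})

test_that("degenerate stage statistics are rejected", {
  # identical rates on both sides with zero variance: zero pooled SD
  snaps <- matrix(rep(seq(0.3, 0.42, by = 0.02), each = 10), ncol = 10,
                  byrow = TRUE)
  tr <- make_traj(snaps, presentations = seq(0, 60, by = 10))
  expect_error(stage_statistics(tr, boundary = 30),
               class = "gnwsim_degenerate_statistics")
  expect_error(stage_statistics(tr, boundary = 1000),
               class = "gnwsim_evaluation_error")
  # too few intervals on one side
  expect_error(stage_statistics(tr, boundary = 15),
               class = "gnwsim_evaluation_error")
})

test_that("identical rate distributions give a null effect size", {
  # same rates both sides but with variance: d = 0, no error
  fr <- cumsum(c(0, rep(c(0.01, 0.02, 0.03), 4)))
  fe <- cumsum(c(0, rep(c(0.03, 0.01, 0.02), 4)))
  snaps <- t(mapply(function(f, g) {
    ns <- round(f * 1e3); ne <- round(g * 1e3)
    c(rep(0.9, ns), rep(0.1, ne), rep(0.5, 1e3 - ns - ne))
  }, fr, fe))
  tr <- make_traj(snaps, presentations = seq(0, 120, by = 10))
  st <- stage_statistics(tr, boundary = 60)
  expect_equal(st$cohens_d[st$group == "selected"], 0, tolerance = 1e-9)
})

test_that("epigenesis tables are written as tidy CSV", {
  net <- fixture_local$net
  dir <- tempfile("tables")
  files <- write_epigenesis_tables(net, dir)
  expect_true(file.exists(files[["percentiles"]]))
  expect_true(file.exists(files[["states"]]))
  sf <- utils::read.csv(files[["states"]])
  expect_equal(names(sf),
               c("presentations", "eliminated", "undetermined", "selected"))
})
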