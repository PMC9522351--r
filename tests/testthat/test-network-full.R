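test_that("full-network assembly enforces the architecture", {
  net <- assemble_full_network(fixture_local$net, TRUE, 0.8, seed = 1)
  expect_equal(net$n_exc, 80)
  expect_equal(net$n_inh, 20)
  expect_equal(table(net$group)[["0"]], 40)
  expect_equal(table(net$group)[["1"]], 40)
  cfg <- net$config
  # internal excitatory weights start at 1% of their bound
  ee <- net$W[1:80, 1:80]
  expect_equal(unique(ee[ee > 0]), 0.01 * cfg$w_max_ee)
  # long-range motor weights start at 50%
  expect_equal(unique(net$w_mc), 0.5 * cfg$w_mc_max)
  expect_equal(diag(net$W), rep(0, 100))

  # no interneurons: no inhibitory synapse anywhere
  net0 <- assemble_full_network(fixture_local$net, FALSE, 0.8, seed = 1)
  expect_equal(net0$n_inh, 0)
  expect_equal(dim(net0$W), c(80, 80))

  expect_error(assemble_full_network(fixture_local$net,
                                     excitatory_fraction = 1.2),
               class = "gnwsim_config_error")
  unlabelled <- fixture_local$net
  unlabelled$label_assignment <- NULL
  expect_error(assemble_full_network(unlabelled),
               class = "gnwsim_config_error")
  unfrozen <- fixture_local$net
  unfrozen$frozen <- FALSE
  expect_error(assemble_full_network(unfrozen),
               class = "gnwsim_config_error")
})

test_that("toy network wiring overrides are applied verbatim", {
  toy <- make_toy_gnw(4, 2, groups = c(0L, 0L, 1L, 1L), w_ee = 0.1,
                      overrides = list(list(from = 1, to = 3, w = 0.42)))
  expect_equal(toy$W[1, 3], 0.42)
  expect_equal(toy$W[1, 2], 0.1)
  expect_equal(diag(toy$W), rep(0, 6))
})

test_that("strong recurrence self-sustains and inhibition terminates it", {
  spec <- trial_spec("trace")
  pulse <- list(seq(5, 100, by = 10))  # input volleys to group 0
  # purely excitatory pair with strong mutual weights: a pulse ignites
  # sustained firing that outlives the stimulus
  toy_exc <- make_toy_gnw(2, 0, groups = c(0L, 0L), w_ee = 1.2,
                          config = full_config(n_gnw = 2, rate_hz = 0))
  res <- withr::with_seed(1, gnwsim:::gnw_simulate(
    toy_exc, 1, 0, pulse, spec, rate_hz = 0, plastic = FALSE,
    plastic_internal = FALSE, record_raster = TRUE))
  late <- sum(res$raster_t > 300 & res$raster_neuron < 2)
  expect_gt(late, 10)

  # add a strongly wired interneuron: activity terminates after the input
  toy_inh <- make_toy_gnw(2, 1, groups = c(0L, 0L), w_ee = 1.2,
                          w_ei = 1.5, w_ie = 3,
                          config = full_config(n_gnw = 3, rate_hz = 0))
  res2 <- withr::with_seed(1, gnwsim:::gnw_simulate(
    toy_inh, 1, 0, pulse, spec, rate_hz = 0, plastic = FALSE,
    plastic_internal = FALSE, record_raster = TRUE))
  late2 <- sum(res2$raster_t > 300 & res2$raster_neuron < 2)
  expect_lt(late2, late / 2)
})

test_that("a held representation is erased by the next stimulus", {
  # hand-matured balanced network at its operating point, no plasticity:
  # group 1 is stimulated and held, then group 0's stimulus must shut it off
  cfg <- full_config()
  net <- assemble_full_network(fixture_local$net, TRUE, 0.8, config = cfg,
                               seed = 11)
  g <- net$group
  ne <- net$n_exc
  N <- ne + net$n_inh
  W <- matrix(0, N, N)
  for (a in 0:1) W[g == a, g == a] <- 0.02
  W[(ne + 1):N, 1:ne] <- 0.2
  W[1:ne, (ne + 1):N] <- 0.01
  diag(W) <- 0
  net$W <- W
  spec <- trial_spec("trace")
  spikes <- list(seq(5, 145, by = 30), seq(5, 145, by = 30))
  res <- withr::with_seed(5, gnwsim:::gnw_simulate(
    net, c(1, 0), c(1L, 0L), spikes, spec, plastic = FALSE,
    plastic_internal = FALSE, record_raster = TRUE))
  r1 <- res$raster_t[res$raster_neuron < ne & g[res$raster_neuron + 1] == 1]
  # held rate of group 1 late in trial 1 (during its gap/trigger)
  held <- sum(r1 > 400 & r1 <= 700) / 0.3
  skip_if(held < 100, "group 1 did not enter a held state under this seed")
  # within 100 ms of stimulus B onset the old representation collapses
  after <- sum(r1 > 730 & r1 <= 800) / 0.07
  expect_lt(after, 0.2 * held)
})
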