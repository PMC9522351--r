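test_that("trial timing follows the task definitions", {
  d <- trial_spec("delay")
  expect_equal(d$stimulus_ms, 150)
  expect_equal(d$trigger_ms, 50)
  # the trigger coincides with the last 50 ms of the stimulus
  expect_equal(d$trigger_onset_ms, 100)
  expect_equal(d$trigger_onset_ms + d$trigger_ms, d$stimulus_ms)
  tr <- trial_spec("trace")
  expect_equal(tr$trace_gap_ms, 200)
  expect_equal(tr$trigger_onset_ms, 350)  # 150 + 200
  r <- trial_spec("recognition")
  expect_equal(r$stimulus_ms, 250)
  expect_equal(r$trial_ms, 500)
})

test_that("trials_to_learn implements the sliding-window criterion", {
  expect_equal(trials_to_learn(rep(TRUE, 30), window = 20), 0)
  expect_equal(trials_to_learn(rep(FALSE, 30), window = 20), Inf)
  x <- c(rep(FALSE, 10), rep(TRUE, 20))
  expect_equal(trials_to_learn(x, window = 5, criterion = 1), 10)
  expect_error(trials_to_learn(logical(0)),
               class = "gnwsim_evaluation_error")
  expect_error(trials_to_learn(rep(TRUE, 5), window = 10),
               class = "gnwsim_evaluation_error")
})

test_that("recognition evaluation needs labelled cells", {
  net <- fixture_local$net
  net$label_assignment <- rep(NA_integer_, ncol(net$w))
  expect_error(run_recognition_eval(net, fixture_local$test,
                                    frontend = fixture_frontend),
               class = "gnwsim_evaluation_error")
})

test_that("conditioning runs are reproducible and rewards track decisions", {
  full <- assemble_full_network(fixture_local$net, FALSE, 0.8, seed = 2)
  r1 <- run_conditioning(full, "delay", fixture_local$train, n_trials = 25,
                         frontend = fixture_frontend150, seed = 6)
  r2 <- run_conditioning(full, "delay", fixture_local$train, n_trials = 25,
                         frontend = fixture_frontend150, seed = 6)
  expect_identical(r1$trials, r2$trials)
  tr <- r1$trials
  # reward only with motor output; sign follows the comparison with x = 0
  expect_true(all(tr$reward_sign[!tr$pressed] == 0))
  expect_true(all(tr$reward_sign[tr$pressed & tr$label == 1] == 1))
  expect_true(all(tr$reward_sign[tr$pressed & tr$label == 0] == -1))
  expect_true(all(tr$correct == (tr$pressed == (tr$label > 0))))
})

test_that("the striatum fires once per image within its jitter window", {
  full <- assemble_full_network(fixture_local$net, FALSE, 0.8, seed = 2)
  run <- run_conditioning(full, "delay", fixture_local$train, n_trials = 10,
                          frontend = fixture_frontend150,
                          record_raster = TRUE, seed = 8)
  r <- run$raster
  n_gnw <- full$n_exc + full$n_inh
  stri <- r$t_ms[r$neuron == n_gnw + 2]  # striatal neuron id
  expect_length(stri, 10)
  rel <- stri %% trial_spec("delay")$trial_ms
  expect_true(all(rel >= 0 & rel <= 1000 / 32 + 0.2))
  # one striatal spike per trial
  expect_equal(sort(unique(stri %/% 500)), 0:9)
})

test_that("frozen evaluation leaves the reward pathway untouched", {
  full <- assemble_full_network(fixture_local$net, FALSE, 0.8, seed = 3)
  trained <- run_conditioning(full, "delay", fixture_local$train,
                              n_trials = 30, frontend = fixture_frontend150,
                              seed = 6)
  w_mc <- trained$net$w_mc
  ev <- evaluate_conditioning(trained$net, "delay", fixture_local$test,
                              n_trials = 20, frontend = fixture_frontend150,
                              seed = 7)
  expect_identical(ev$net$w_mc, w_mc)
  expect_false(ev$plastic)
  expect_true(all(ev$trials$reward_sign[!ev$trials$pressed] == 0))
})

test_that("a single-cell sweep equals a direct conditioning run", {
  sw <- run_sweep(fixture_local$net, fixture_local$train, task = "delay",
                  rates = 4, fractions = 0.8, n_seeds = 1,
                  n_train = 25, n_eval = 15, seed = 2)
  expect_equal(nrow(sw$grid), 1)
  expect_equal(nrow(sw$summary), 1)
  expect_true(sw$grid$accuracy >= 0 && sw$grid$accuracy <= 1)
  # reproducible per (cell, seed)
  sw2 <- run_sweep(fixture_local$net, fixture_local$train, task = "delay",
                   rates = 4, fractions = 0.8, n_seeds = 1,
                   n_train = 25, n_eval = 15, seed = 2)
  expect_identical(sw$grid, sw2$grid)
})

test_that("broom-style accessors expose run summaries", {
  full <- assemble_full_network(fixture_local$net, FALSE, 0.8, seed = 2)
  run <- run_conditioning(full, "delay", fixture_local$train, n_trials = 25,
                          frontend = fixture_frontend150, seed = 6)
  td <- tidy(run)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("trial", "pressed", "correct", "mc_spikes") %in%
                    names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_trials, 25)
  gn <- glance(fixture_local$net)
  expect_equal(gn$n_s2, 20)
})
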