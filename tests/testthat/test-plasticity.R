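# The pair-protocol oracles (closed form for the classical rule, dense
# fine-step integration for the symmetric rule) are the reference every
# event-driven implementation is held against.

test_that("classical pair protocol matches the closed form exactly", {
  p <- classical_stdp_params()
  dts <- c(-50, -20, -10, -5, 5, 10, 20, 50)
  measured <- stdp_pair_measure("classical", p, dts)
  predicted <- stdp_pair_oracle("classical", p, dts)
  expect_equal(measured, predicted, tolerance = 1e-12)
  expect_true(all(measured[dts > 0] > 0))
  expect_true(all(measured[dts < 0] < 0))
  # closed-form endpoints
  expect_equal(stdp_pair_oracle("classical", p, p$tau_pre),
               p$dA_pre / exp(1))
  expect_equal(stdp_pair_measure("classical", p, 1e5), 0, tolerance = 1e-12)
  # tie rule: pre processed first, so the post event collects dA_pre
  expect_equal(stdp_pair_measure("classical", p, 0), p$dA_pre)
})

test_that("symmetric pair protocol matches dense integration", {
  p <- symmetric_stdp_params()
  dts <- c(-80, -40, -10, -2, 2, 10, 40, 80)
  measured <- stdp_pair_measure("symmetric", p, dts)
  predicted <- stdp_pair_oracle("symmetric", p, dts, dt_fine = 0.002)
  expect_lt(max(abs(measured - predicted)), 1e-3 * p$dA_pre * 15)
  # near-coincident pairing potentiates by roughly +dA
  expect_gt(stdp_pair_measure("symmetric", p, 0.5), 0.8 * p$dA_pre)
  # distant pairing picks up the negative resting trace
  expect_lt(stdp_pair_measure("symmetric", p, 200), 0)
  # both events pick up their partner's resting trace -dA/divisor
  expect_equal(stdp_pair_measure("symmetric", p, 200),
               -(p$dA_pre + p$dA_post) / p$divisor, tolerance = 1e-3)
  # with equal increments and taus the rule is symmetric in delta-t
  expect_equal(stdp_pair_measure("symmetric", p, dts),
               stdp_pair_measure("symmetric", p, -dts), tolerance = 1e-9)
})

test_that("oracle and implementation agree over random pairs and parameters", {
  withr::with_seed(42, {
    for (rep in 1:3) {
      pc <- classical_stdp_params(
        dA_pre = runif(1, 0.005, 0.05), dA_post = -runif(1, 0.005, 0.05),
        tau_pre = runif(1, 10, 40), tau_post = runif(1, 10, 40))
      dts <- runif(17, -100, 100)
      expect_equal(stdp_pair_measure("classical", pc, dts),
                   stdp_pair_oracle("classical", pc, dts),
                   tolerance = 1e-9)
      ps <- symmetric_stdp_params(
        dA_pre = runif(1, 0.005, 0.05), dA_post = runif(1, 0.005, 0.05),
        tau_pre = runif(1, 10, 40), tau_post = runif(1, 10, 40))
      expect_lt(max(abs(stdp_pair_measure("symmetric", ps, dts) -
                          stdp_pair_oracle("symmetric", ps, dts,
                                           dt_fine = 0.005))),
                1e-3 * max(ps$dA_pre, ps$dA_post) * 15)
    }
  })
})

test_that("the empirical STDP kernel recovers the trace time constants", {
  p <- classical_stdp_params(tau_pre = 20, tau_post = 20)
  dts <- seq(2, 100, by = 2)
  dw <- stdp_pair_measure("classical", p, dts)
  fit <- stats::lm(log(dw) ~ dts)
  tau_hat <- -1 / stats::coef(fit)[2]
  expect_lt(abs(tau_hat - p$tau_pre) / p$tau_pre, 0.05)
  dwn <- stdp_pair_measure("classical", p, -dts)
  fit2 <- stats::lm(log(-dwn) ~ dts)
  expect_lt(abs(-1 / stats::coef(fit2)[2] - p$tau_post) / p$tau_post, 0.05)
})

test_that("event-driven updates equal dense clock stepping", {
  # the module's core oracle: analytic decay applied only at events must
  # match stepping the trace ODEs every dt with exact decay factors
  withr::with_seed(7, {
    p <- classical_stdp_params()
    n_pre <- 3; n_post <- 2
    events <- tibble::tibble(
      t = sort(runif(60, 0, 500)),
      side = sample(c("pre", "post"), 60, replace = TRUE),
      id = NA_integer_
    )
    events$id <- ifelse(events$side == "pre",
                        sample(n_pre, 60, replace = TRUE),
                        sample(n_post, 60, replace = TRUE))
    w0 <- matrix(0.5, n_pre, n_post)

    run_event <- function() {
      syn <- synapse_population(w0, w_max = 1)
      st <- plasticity_state(n_pre, n_post, p)
      for (k in seq_len(nrow(events))) {
        up <- if (events$side[k] == "pre") {
          classical_on_pre(syn, st, events$t[k], events$id[k])
        } else {
          classical_on_post(syn, st, events$t[k], events$id[k])
        }
        syn <- up$syn; st <- up$state
      }
      syn$w
    }

    run_dense <- function(dt = 0.1) {
      w <- w0
      A_pre <- numeric(n_pre); A_post <- numeric(n_post)
      dec_pre <- exp(-dt / p$tau_pre); dec_post <- exp(-dt / p$tau_post)
      ev <- 1
      for (t in seq(dt, 520, by = dt)) {
        A_pre <- A_pre * dec_pre
        A_post <- A_post * dec_post
        while (ev <= nrow(events) && events$t[ev] <= t) {
          # decay the remaining fraction of the step up to the event time
          back <- t - events$t[ev]
          if (events$side[ev] == "pre") {
            i <- events$id[ev]
            w[i, ] <- pmin(pmax(w[i, ] + A_post * exp(back / p$tau_post), 0), 1)
            A_pre[i] <- A_pre[i] + p$dA_pre * exp(-back / p$tau_pre)
          } else {
            i <- events$id[ev]
            w[, i] <- pmin(pmax(w[, i] + A_pre * exp(back / p$tau_pre), 0), 1)
            A_post[i] <- A_post[i] + p$dA_post * exp(-back / p$tau_post)
          }
          ev <- ev + 1
        }
      }
      w
    }
    expect_equal(run_event(), run_dense(), tolerance = 1e-9)
  })
})

test_that("weight bounds are never violated under random event storms", {
  withr::with_seed(3, {
    p <- classical_stdp_params(dA_pre = 0.3, dA_post = -0.35)
    syn <- synapse_population(matrix(runif(6), 3, 2), w_max = 1)
    st <- plasticity_state(3, 2, p)
    t <- 0
    for (k in 1:2000) {
      t <- t + rexp(1, 1 / 5)
      if (runif(1) < 0.5) {
        up <- classical_on_pre(syn, st, t, sample(3, 1))
      } else {
        up <- classical_on_post(syn, st, t, sample(2, 1))
      }
      syn <- up$syn; st <- up$state
    }
    expect_true(all(syn$w >= 0 & syn$w <= syn$w_max))
  })
})

test_that("frozen synapse populations never change", {
  p <- classical_stdp_params()
  syn <- synapse_population(matrix(0.5, 2, 2), plastic = FALSE)
  st <- plasticity_state(2, 2, p)
  up <- classical_on_pre(syn, st, 1, 1)
  up <- classical_on_post(up$syn, up$state, 2, 1)
  expect_equal(up$syn$w, matrix(0.5, 2, 2))
})

test_that("dopamine-modulated STDP is gated by the dopamine deviation", {
  p <- dopamine_stdp_params()
  syn <- synapse_population(matrix(0.5, 2, 1), w_max = 1)
  st <- plasticity_state(2, 1, p)
  # spikes but d = 0 throughout: weights never change
  withr::with_seed(9, {
    t <- 0
    for (k in 1:200) {
      t <- t + rexp(1, 1 / 10)
      up <- if (runif(1) < 0.6) {
        dopamine_on_pre(syn, st, t, sample(2, 1))
      } else {
        dopamine_on_post(syn, st, t, 1)
      }
      syn <- up$syn; st <- up$state
      up <- dopamine_update(syn, st, 1)
      syn <- up$syn; st <- up$state
    }
  })
  expect_equal(syn$w, matrix(0.5, 2, 1))
  expect_gt(max(abs(st$c)), 0)  # eligibility accumulated nonetheless

  # no spikes ever: c stays 0 and w is unchanged regardless of d
  syn2 <- synapse_population(matrix(0.5, 2, 1), w_max = 1)
  st2 <- plasticity_state(2, 1, p)
  st2 <- apply_reward(st2, +1, 5)
  for (k in 1:100) {
    up <- dopamine_update(syn2, st2, 1)
    syn2 <- up$syn; st2 <- up$state
  }
  expect_equal(syn2$w, matrix(0.5, 2, 1))
})

test_that("pairing followed by a signed dopamine pulse moves the weight accordingly", {
  oracle_run <- function(sign, dt = 0.01) {
    # dense integration at a 10x finer step than the module default
    p <- dopamine_stdp_params()
    syn <- synapse_population(matrix(0.5, 1, 1), w_max = 1)
    st <- plasticity_state(1, 1, p)
    t <- 0
    up <- dopamine_on_pre(syn, st, 10, 1)
    up <- dopamine_on_post(up$syn, up$state, 15, 1)  # pre -> post: c > 0
    syn <- up$syn; st <- up$state
    st <- apply_reward(st, sign, 1)
    for (k in seq_len(round(400 / dt))) {
      up <- dopamine_update(syn, st, dt)
      syn <- up$syn; st <- up$state
    }
    syn$w[1, 1] - 0.5
  }
  expect_gt(oracle_run(+1), 0)
  expect_lt(oracle_run(-1), 0)
  expect_equal(oracle_run(+1), -oracle_run(-1), tolerance = 1e-9)
})

test_that("dopamine relaxes exponentially back to baseline", {
  p <- dopamine_stdp_params(tau_d = 200)
  syn <- synapse_population(matrix(0.5, 1, 1))
  st <- plasticity_state(1, 1, p)
  st <- apply_reward(st, +1, 2)
  expect_equal(st$d, 2)
  for (k in seq_len(1000)) {  # 5 tau_d at dt = 1
    up <- dopamine_update(syn, st, 1)
    st <- up$state; syn <- up$syn
  }
  expect_lt(abs(st$d), 0.01 * 2)
  # equal and opposite rewards cancel; zero magnitude is a no-op
  st2 <- plasticity_state(1, 1, p)
  st2 <- apply_reward(st2, +1, 3)
  st2 <- apply_reward(st2, -1, 3)
  expect_equal(st2$d, 0)
  st3 <- apply_reward(plasticity_state(1, 1, p), -1, 0)
  expect_equal(st3$d, 0)
})
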