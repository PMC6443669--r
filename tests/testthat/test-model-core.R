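# Circuit model: inputs, decision rule, plasticity updates, simulation.

test_that("make_inputs builds the published input patterns for both assignments", {
  sp_larger <- make_inputs(recruitment_scenario(1, 1, 2, larger = "S_PLUS"))
  expect_equal(unname(as.numeric(sp_larger$x_plus)), c(1, 0, 2))
  expect_equal(unname(as.numeric(sp_larger$x_minus)), c(1, 1, 0))

  sm_larger <- make_inputs(recruitment_scenario(1, 1, 2, larger = "S_MINUS"))
  expect_equal(unname(as.numeric(sm_larger$x_plus)), c(1, 0, 1))
  expect_equal(unname(as.numeric(sm_larger$x_minus)), c(1, 2, 0))
})

test_that("scenario and input validation enforce the model's invariants", {
  expect_error(recruitment_scenario(1, weak = 2, strong = 1),
               "strong_level")
  # equality is the symmetric control, not an error
  expect_s3_class(recruitment_scenario(1, 1, 1), "recruitment_scenario")
  expect_error(recruitment_scenario(0, 1, 2))
  expect_error(sensory_input(c(1, 1, 0), "S_PLUS"), "silent")
  expect_error(sensory_input(c(1, 0, 1), "S_MINUS"), "silent")
  expect_silent(sensory_input(c(1, 0, 2), "S_PLUS"))
})

test_that("decide thresholds the drive strictly against the noise draw", {
  w <- rw_weights(w_Ce = 1, w_Ci = 1, w_S = 0.5)  # zero net drive
  x <- sensory_input(c(1, 0, 0), "PROBE")
  expect_identical(decide(w, x, 0), 0L)       # theta(0) = 0, strict
  expect_identical(decide(w, x, -0.1), 1L)
  w2 <- rw_weights(w_Ce = 5, w_Ci = 1, w_S = 0.01)
  expect_identical(decide(w2, x, 1), 1L)      # drive 4 > noise 1
  expect_identical(decide(w2, x, 10), 0L)
})

test_that("decide agrees with lick_probability under standard-normal noise", {
  # drive of exactly 1: P(lick) should be pnorm(1)
  w <- rw_weights(w_Ce = 2, w_Ci = 1, w_S = 0.01)
  x <- sensory_input(c(1, 0, 0), "PROBE")
  expect_equal(lick_probability(w, x), pnorm(1))
  set.seed(99)
  n <- 1e6
  xi <- rnorm(n)
  frac <- mean(vapply(seq_len(n), function(i) decide(w, x, xi[i]),
                      integer(1)) == 1L)
  se <- sqrt(pnorm(1) * (1 - pnorm(1)) / n)
  expect_lt(abs(frac - pnorm(1)), 4 * se)
})

test_that("asymmetric_gain weights positive surprises v-fold", {
  expect_equal(asymmetric_gain(-0.5, 6), -0.5)
  expect_equal(asymmetric_gain(0.5, 6), 3)
  expect_equal(asymmetric_gain(0, 6), 0)
  expect_equal(asymmetric_gain(c(-1, 0, 2), 3), c(-1, 0, 6))
  expect_error(asymmetric_gain(1, 0.5))
})

test_that("one stochastic update matches the hand-computed oracle", {
  # start at the published configuration, rewarded lick on an S+ trial
  w <- rw_weights(w_Ce = 2, w_Ci = 1, w_S = 0.01)
  p <- rw_params(alpha = 0.01, sigma = 0.6195, v = 6)
  x <- sensory_input(c(1, 0, 2), "S_PLUS")
  # drive = (2-1)*1 + 0*2 = 1; prediction error 1 - 0.6195 = 0.3805 > 0,
  # gain = 6 * 0.3805 = 2.283
  gain <- 6 * (1 - 0.6195)
  out <- update_weights_stochastic(w, x, response = 1, reward = 1, p)
  expect_equal(unname(out$E),
               c(2 + 0.01 * 2 * gain * 1,
                 0.01,
                 0.01 + 0.01 * 0.01 * gain * 2),
               tolerance = 1e-12)
  expect_equal(unname(out$I),
               c(1 - 0.01 * 1 * gain * 1,
                 0.01,
                 0.01 - 0.01 * 0.01 * gain * 2),
               tolerance = 1e-12)
})

test_that("weights only change on licked trials", {
  w <- rw_weights(w_Ce = 2, w_Ci = 1, w_S = 0.01)
  p <- rw_params()
  x <- sensory_input(c(1, 1, 0), "S_MINUS")
  out <- update_weights_stochastic(w, x, response = 0, reward = -1, p)
  expect_identical(out$E, w$E)
  expect_identical(out$I, w$I)
})

test_that("the multiplicative rule keeps a zero weight at zero when unclamped", {
  w <- rw_weights(w_Ce = 2, w_Ci = 1, excitatory = c(2, 0, 0),
                  inhibitory = c(1, 0, 0))
  p <- rw_params(floor = 0)
  x <- sensory_input(c(1, 0, 2), "S_PLUS")
  out <- update_weights_stochastic(w, x, response = 1, reward = 1, p)
  expect_identical(unname(out$E[2:3]), c(0, 0))
  expect_identical(unname(out$I[2:3]), c(0, 0))
})

test_that("lick_probability is the normal upper tail of the drive", {
  w0 <- rw_weights(w_Ce = 1, w_Ci = 1, w_S = 0.3)
  blank <- sensory_input(c(0, 0, 0), "PROBE")
  expect_equal(lick_probability(w0, blank), 0.5)
  # drive at the learned fixed point 1/sigma gives the model's asymptotic
  # hit rate
  sigma <- 0.6195
  w <- rw_weights(excitatory = c(1 / sigma, 0, 0), inhibitory = c(0, 0, 0))
  x <- sensory_input(c(1, 0, 0), "PROBE")
  expect_equal(lick_probability(w, x), pnorm(1 / sigma))
  expect_equal(round(100 * pnorm(1 / sigma), 1), 94.7)
})

test_that("the ergodic update is stationary exactly at the fixed point", {
  # construct weights whose drives are +1/sigma on S+ and -1/sigma on S-
  sigma <- 0.6195
  p <- rw_params(sigma = sigma)
  scen <- recruitment_scenario(1, 1, 2, "S_PLUS")
  xs <- make_inputs(scen)
  w <- rw_weights(excitatory = c(1, 0.01, 0.01 + 1 / (2 * sigma)),
                  inhibitory = c(1, 0.01 + 1 / sigma, 0.01))
  expect_equal(sum(delta_w(w) * xs$x_plus), 1 / sigma)
  expect_equal(sum(delta_w(w) * xs$x_minus), -1 / sigma)
  out <- update_weights_ergodic(w, xs$x_plus, xs$x_minus, p)
  expect_equal(out$E, w$E, tolerance = 1e-14)
  expect_equal(out$I, w$I, tolerance = 1e-14)
})

test_that("the ergodic step equals the expected stochastic step", {
  # Monte-Carlo expectation of one stochastic update over stimulus and noise
  w <- rw_weights(w_Ce = 1.2, w_Ci = 0.8, w_S = 0.05)
  p <- rw_params(alpha = 0.01, sigma = 0.6195, v = 6, floor = 0)
  scen <- recruitment_scenario(1, 1, 2, "S_PLUS")
  xs <- make_inputs(scen)
  erg <- update_weights_ergodic(w, xs$x_plus, xs$x_minus, p)
  set.seed(7)
  n <- 2e4
  dE <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    is_plus <- i %% 2L == 1L  # balanced stimulus presentation
    x <- if (is_plus) xs$x_plus else xs$x_minus
    y <- decide(w, x, rnorm(1))
    out <- update_weights_stochastic(w, x, y, if (is_plus) 1 else -1, p)
    dE[i, ] <- out$E - w$E
  }
  mc <- colMeans(dE)
  se <- apply(dE, 2, sd) / sqrt(n)
  expect_true(all(abs(mc - (erg$E - w$E)) <= 3 * se + 1e-12))
})

test_that("the symmetric control is identical under both assignments", {
  init <- rw_weights(2, 1, 0.01)
  p <- rw_params()
  a <- simulate_learning(recruitment_scenario(1, 1, 1, "S_PLUS"), init, p,
                         n_trials = 300, mode = "ergodic")
  b <- simulate_learning(recruitment_scenario(1, 1, 1, "S_MINUS"), init, p,
                         n_trials = 300, mode = "ergodic")
  expect_identical(a$performance, b$performance)
  expect_identical(a$W_E, b$W_E)
})

test_that("probe utilities build component vectors and a blank probe is 0.5", {
  scen <- recruitment_scenario(1, 1, 2, "S_PLUS")
  pv <- probe_vectors(scen)
  expect_equal(unname(as.numeric(pv$C)), c(1, 0, 0))
  expect_equal(unname(as.numeric(pv$S_PLUS)), c(0, 0, 2))
  expect_equal(unname(as.numeric(pv$S_MINUS)), c(0, 1, 0))
  w <- rw_weights(1.7, 0.3, 0.2)
  expect_equal(probe_stimulus(w, "blank", scen), 0.5)
  expect_equal(probe_stimulus(w, "C", scen),
               lick_probability(w, pv$C))
  expect_error(probe_stimulus(w, "C"), "scenario")
})

test_that("simulate_learning is reproducible and validates its arguments", {
  scen <- recruitment_scenario(1, 1, 2, "S_PLUS")
  init <- rw_weights(2, 1, 0.01)
  a <- simulate_learning(scen, init, rw_params(seed = 5), n_trials = 200,
                         mode = "stochastic")
  b <- simulate_learning(scen, init, rw_params(seed = 5), n_trials = 200,
                         mode = "stochastic")
  expect_identical(a$response, b$response)
  expect_identical(a$W_E, b$W_E)
  expect_error(simulate_learning(scen, init, rw_params(), n_trials = NULL,
                                 mode = "stochastic"), "n_trials")
  expect_warning(simulate_learning(scen, init, rw_params(), n_trials = NULL,
                                   mode = "ergodic", max_steps = 10L),
                 "step cap")
})

test_that("trajectory accessors expose consistent per-step state", {
  scen <- recruitment_scenario(1, 1, 2, "S_PLUS")
  traj <- simulate_learning(scen, rw_weights(2, 1, 0.01),
                            rw_params(seed = 11), n_trials = 160,
                            mode = "stochastic")
  df <- as.data.frame(traj)
  expect_equal(nrow(df), 160)
  expect_equal(df$performance, (df$p_splus + 1 - df$p_sminus) / 2)
  s <- summary(traj)
  xs <- make_inputs(scen)
  dw <- delta_w(traj$final_weights)
  expect_equal(s$dwx_plus, sum(dw * xs$x_plus))
  expect_equal(s$dwx_minus, sum(dw * xs$x_minus))
})
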