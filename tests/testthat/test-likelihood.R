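test_that("the uniform policy has the closed-form log-likelihood", {
  sch <- builtin_schedule("session_out")
  ses <- simulate_agent(model_spec("bayes", "SMEP"),
                        model_params(beta = 0.2, phi = 1, rho = 2),
                        sch, seed = 1, missed_rate = 0)
  ll <- session_log_likelihood(model_spec("bayes", "SMEP"),
                               model_params(beta = 0, phi = 0, rho = 0),
                               ses)
  expect_equal(ll, 300 * log(0.25), tolerance = 1e-12)
})

test_that("an all-missed session contributes zero log-likelihood", {
  ses <- make_session(rep(NA, 10), rep(NA, 10))
  ll <- session_log_likelihood(model_spec("bayes", "SMEP"),
                               model_params(beta = 0.1, phi = 1, rho = 2),
                               ses)
  expect_identical(ll, 0)
})

test_that("log-likelihood is never positive and counts valid trials", {
  sch <- builtin_schedule("session_out")
  for (spec in all_model_specs()) {
    p <- default_generating_params(spec)
    ses <- simulate_agent(spec, p, sch, seed = 6, missed_rate = 0.03)
    ll <- session_log_likelihood(spec, p, ses)
    expect_lte(ll, 0)
  }
})

test_that("hand-written six-trial session matches the brute-force trace", {
  choice <- c(1, 3, 3, NA, 2, 4)
  outcome <- c(62, 41, 55, NA, 70, 30)
  ses <- make_session(choice, outcome)
  for (lr in c("delta", "bayes")) {
    for (cr in c("SM", "SME", "SMP", "SMEP")) {
      spec <- model_spec(lr, cr)
      params <- model_params(beta = 0.12, alpha = 0.4, phi = 0.6, rho = 1.5)
      ll <- session_log_likelihood(spec, params, ses)
      orc <- oracle_trace(choice, outcome, lr, cr, alpha = 0.4,
                          beta = 0.12, phi = 0.6, rho = 1.5)
      expect_equal(ll, orc$log_lik, tolerance = 1e-10)
    }
  }
})

test_that("per-trial probabilities normalize and match the R primitives", {
  # the compiled kernel against an independent walk through the exported
  # belief-update primitives
  choice <- c(2, 2, 1, NA, 4, 3, 1, 1)
  outcome <- c(55, 61, 40, NA, 35, 52, 47, 58)
  ses <- make_session(choice, outcome)
  spec <- model_spec("bayes", "SMEP")
  params <- model_params(beta = 0.1, phi = 0.8, rho = 3)
  wp <- walk_params()
  tr <- session_belief_trace(spec, params, ses, wp)
  expect_equal(rowSums(tr$probs), rep(1, 8), tolerance = 1e-12)

  b <- init_beliefs(spec, walk = wp)
  for (t in seq_along(choice)) {
    expect_equal(as.vector(tr$values[t, ]), b$values, tolerance = 1e-12)
    expect_equal(as.vector(tr$variances[t, ]), b$variances,
                 tolerance = 1e-12)
    expect_equal(as.vector(tr$probs[t, ]),
                 choice_probabilities(b, params, spec), tolerance = 1e-12)
    if (!is.na(choice[t])) {
      b <- kalman_update(b, choice[t], outcome[t], wp)
    } else {
      b <- restlessbandit:::advance_recency(b, NA_integer_)
    }
    b <- diffuse_beliefs(b, wp)
  }
})

test_that("variance observation step strictly shrinks the chosen bandit", {
  ses <- make_session(c(1, 1, 1), c(60, 55, 58))
  tr <- session_belief_trace(model_spec("bayes", "SM"),
                             model_params(beta = 0.1), ses)
  # before each successive trial the chosen bandit's variance decreases
  expect_lt(tr$variances[2, 1], tr$variances[1, 1])
  expect_lt(tr$variances[3, 1], tr$variances[2, 1])
  # unchosen bandits drift toward the diffusion fixed point instead
  expect_equal(tr$variances[1, 2], stationary_variance(walk_params()))
})

test_that("a missed trial triggers no observation update but still diffuses", {
  wp <- walk_params()
  ses <- make_session(c(2, NA, 2), c(90, NA, 88))
  tr <- session_belief_trace(model_spec("bayes", "SM"),
                             model_params(beta = 0.05), ses, wp)
  # across the missed trial the value only decays toward the centre
  q_before <- tr$values[2, 2]
  expect_equal(tr$values[3, 2],
               wp$decay * q_before + (1 - wp$decay) * wp$decay_center,
               tolerance = 1e-12)
  expect_equal(tr$variances[3, 2],
               wp$decay^2 * tr$variances[2, 2] + wp$diffusion_sd^2,
               tolerance = 1e-12)
})
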