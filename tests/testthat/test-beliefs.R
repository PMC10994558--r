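test_that("belief initialization is symmetric at the prior", {
  b <- init_beliefs(model_spec("bayes", "SMEP"))
  expect_equal(b$values, rep(50, 4))
  expect_equal(b$variances, rep(stationary_variance(walk_params()), 4))
  expect_true(is.na(b$last_choice))
  expect_equal(b$trials_since, rep(0L, 4))
  d <- init_beliefs(model_spec("delta", "SM"))
  expect_null(d$variances)
  expect_error(init_beliefs(model_spec("bayes", "SM"), prior_var = -1),
               "prior_var")
})

test_that("delta rule moves the chosen value by alpha times the error", {
  b <- init_beliefs(model_spec("delta", "SM"))
  b2 <- delta_update(b, 2, 70, alpha = 0.5)
  expect_equal(b2$values, c(50, 60, 50, 50))
  expect_equal(b2$last_choice, 2L)
  expect_equal(b2$trials_since, c(1L, 0L, 1L, 1L))
  # zero prediction error: unchanged for any alpha
  for (a in c(0.1, 0.5, 0.9)) {
    expect_equal(delta_update(b, 1, 50, a)$values, rep(50, 4))
  }
  # alpha -> 0 limit
  expect_equal(delta_update(b, 1, 99, 1e-12)$values[1], 50,
               tolerance = 1e-9)
  expect_error(delta_update(b, 1, 70, alpha = 1.2), "alpha")
})

test_that("Kalman update matches the hand-evaluated gain formulas", {
  wp <- walk_params()  # sigma_o = 4
  b <- init_beliefs(model_spec("bayes", "SM"), walk = wp)
  # gain is exactly 1/2 when the prior variance equals sigma_o^2
  b$variances <- rep(16, 4)
  b2 <- kalman_update(b, 1, 70, wp)
  expect_equal(b2$values[1], 60)           # halfway to the outcome
  expect_equal(b2$variances[1], 8)         # (1 - 1/2) * 16
  # hand-evaluated case: s^2 = 36, sigma_o^2 = 16, outcome 76
  b$variances <- rep(36, 4)
  b3 <- kalman_update(b, 3, 76, wp)
  expect_equal(b3$values[3], 50 + (36 / 52) * 26, tolerance = 1e-12)
  expect_equal(b3$values[3], 68, tolerance = 1e-12)
  expect_equal(b3$variances[3], 16 * 36 / 52, tolerance = 1e-12)
  # unchosen bandits untouched by the observation step
  expect_equal(b3$values[-3], rep(50, 3))
  expect_equal(b3$variances[-3], rep(36, 3))
  # uninformative-prior limit: value -> outcome
  b$variances <- rep(1e12, 4)
  expect_equal(kalman_update(b, 2, 83, wp)$values[2], 83, tolerance = 1e-6)
  expect_error(kalman_update(init_beliefs(model_spec("delta", "SM")),
                             1, 50, wp), "Bayesian")
})

test_that("diffusion contracts values to the centre and variances to the fixed point", {
  wp <- walk_params()
  b <- init_beliefs(model_spec("bayes", "SM"), walk = wp)
  # values at the centre are a fixed point
  expect_equal(diffuse_beliefs(b, wp)$values, rep(50, 4))
  # repeated diffusion converges to sigma_d^2 / (1 - lambda^2)
  b$variances <- rep(1, 4)
  for (i in 1:500) b <- diffuse_beliefs(b, wp)
  expect_equal(b$variances, rep(stationary_variance(wp), 4),
               tolerance = 1e-6)
  # approach is monotone from below
  b2 <- init_beliefs(model_spec("bayes", "SM"), walk = wp)
  b2$variances <- rep(1, 4)
  prev <- b2$variances[1]
  for (i in 1:50) {
    b2 <- diffuse_beliefs(b2, wp)
    expect_gt(b2$variances[1], prev)
    prev <- b2$variances[1]
  }
})

test_that("delta update equals the Kalman mean update when the gain is pinned", {
  # choosing s^2 so that kappa = s^2/(s^2 + sigma_o^2) = alpha makes the
  # two mean updates structurally identical
  wp <- walk_params()
  alpha <- 0.35
  s2 <- alpha * wp$observation_sd^2 / (1 - alpha)
  bk <- init_beliefs(model_spec("bayes", "SM"), walk = wp)
  bk$variances <- rep(s2, 4)
  bd <- init_beliefs(model_spec("delta", "SM"))
  out <- 72.5
  expect_equal(kalman_update(bk, 2, out, wp)$values,
               delta_update(bd, 2, out, alpha)$values, tolerance = 1e-12)
})

test_that("softmax probabilities match direct evaluation and stay normalized", {
  spec <- model_spec("bayes", "SM")
  b <- init_beliefs(spec)
  b$values <- c(60, 50, 40, 30)
  # uniform limit at beta = 0
  expect_equal(choice_probabilities(b, model_params(beta = 0)),
               rep(0.25, 4))
  # direct evaluation of softmax(6, 5, 4, 3)
  p <- choice_probabilities(b, model_params(beta = 0.1))
  expect_equal(p, exp(c(6, 5, 4, 3)) / sum(exp(c(6, 5, 4, 3))),
               tolerance = 1e-12)
  expect_equal(round(p, 4), c(0.6439, 0.2369, 0.0871, 0.0321))
  # greedy limit: overflow-safe at huge beta
  pg <- choice_probabilities(b, model_params(beta = 1e6))
  expect_equal(pg, c(1, 0, 0, 0))
  # probability conservation over random belief states
  set.seed(42)
  specs <- all_model_specs()
  for (i in 1:50) {
    sp <- specs[[sample(8, 1)]]
    bb <- init_beliefs(sp, walk = walk_params())
    bb$values <- rnorm(4, 50, 20)
    if (!is.null(bb$variances)) bb$variances <- runif(4, 1, 300)
    bb$trials_since <- sample(0:20, 4, replace = TRUE)
    bb$last_choice <- sample(c(NA, 1:4), 1)
    pp <- choice_probabilities(
      bb, model_params(beta = runif(1, 0, 0.3), alpha = 0.5,
                       phi = runif(1, 0, 2), rho = runif(1, -2, 5)), sp)
    expect_equal(sum(pp), 1, tolerance = 1e-12)
    expect_true(all(pp >= 0))
  }
})

test_that("perseveration and exploration bonuses enter the logit additively", {
  spec <- model_spec("bayes", "SMEP")
  b <- init_beliefs(spec)
  b$values <- c(50, 50, 50, 50)
  b$variances <- c(4, 4, 4, 4)
  b$last_choice <- 2L
  p <- choice_probabilities(b, model_params(beta = 0.1, phi = 0.5, rho = 1))
  # equal values and uncertainties: only the perseveration bonus differs
  expect_equal(p[2], exp(1) / (exp(1) + 3), tolerance = 1e-12)
  # variance scale option changes the bonus term
  b$variances <- c(100, 4, 4, 4)
  p_sd <- choice_probabilities(b, model_params(beta = 0, phi = 0.1, rho = 0))
  p_var <- choice_probabilities(b, model_params(beta = 0, phi = 0.1, rho = 0),
                                bonus_on = "variance")
  expect_gt(p_var[1], p_sd[1])
})

test_that("the bandit unchosen longest carries the largest variance", {
  wp <- walk_params()
  set.seed(7)
  for (rep in 1:20) {
    b <- init_beliefs(model_spec("bayes", "SM"), walk = wp)
    history <- sample(1:4, 30, replace = TRUE)
    for (c_t in history) {
      b <- kalman_update(b, c_t, rnorm(1, 50, 10), wp)
      b <- diffuse_beliefs(b, wp)
    }
    if (length(unique(history)) == 4) {
      longest <- which.max(b$trials_since)
      expect_equal(which.max(b$variances), longest)
    }
  }
})
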