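test_that("single-trial classification matches the definitions", {
  spec <- model_spec("bayes", "SMEP")
  b <- init_beliefs(spec)
  b$values <- c(60, 50, 40, 30)
  expect_equal(classify_trial(b, 1), "exploit")
  # bandit 4 unchosen longest has accumulated the largest variance
  b$variances <- c(10, 12, 14, 100)
  b$trials_since <- c(1L, 2L, 3L, 9L)
  expect_equal(classify_trial(b, 4), "directed")
  expect_equal(classify_trial(b, 2), "random")
  expect_equal(classify_trial(b, NA), "missed")
})

test_that("labels agree with the straight-line oracle over all orderings", {
  spec_b <- model_spec("bayes", "SMEP")
  spec_d <- model_spec("delta", "SMP")
  q_vals <- c(60, 50, 40, 30)
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ,
                 drop = FALSE]
  expect_equal(nrow(perms), 24)
  vars <- c(20, 35, 50, 65)
  tsc <- c(3L, 1L, 7L, 2L)
  for (j in seq_len(nrow(perms))) {
    q <- q_vals[perms[j, ]]
    bb <- init_beliefs(spec_b)
    bb$values <- q
    bb$variances <- vars
    bb$trials_since <- tsc
    bd <- init_beliefs(spec_d)
    bd$values <- q
    bd$trials_since <- tsc
    for (choice in 1:4) {
      expect_equal(classify_trial(bb, choice),
                   oracle_classify(q, choice, "bayes", variances = vars))
      expect_equal(classify_trial(bd, choice),
                   oracle_classify(q, choice, "delta", trials_since = tsc))
    }
  }
})

test_that("session labelling is deterministic and aligned", {
  sch <- builtin_schedule("session_out")
  spec <- model_spec("bayes", "SMEP")
  p <- model_params(beta = 0.1, phi = 0.8, rho = 4, spec = spec)
  ses <- simulate_agent(spec, p, sch, seed = 31, missed_rate = 0.05)
  l1 <- classify_session(ses, spec, p)
  l2 <- classify_session(ses, spec, p)
  expect_identical(l1, l2)
  expect_length(l1, nrow(ses))
  expect_identical(l1 == "missed", ses$missed == 1)
  # all-missed session
  mses <- make_session(rep(NA, 6), rep(NA, 6))
  expect_equal(classify_session(mses, spec, p), rep("missed", 6))
})

test_that("a greedy agent is labelled mostly exploitative", {
  sch <- builtin_schedule("session_out")
  spec <- model_spec("bayes", "SM")
  p <- model_params(beta = 2)
  ses <- simulate_agent(spec, p, sch, seed = 32)
  labs <- classify_session(ses, spec, p)
  expect_gt(mean(labs == "exploit"), 0.6)
})

test_that("label partition covers exactly the valid trials", {
  sch <- builtin_schedule("session_out")
  spec <- model_spec("delta", "SMEP")
  p <- model_params(beta = 0.1, alpha = 0.4, phi = 0.2, rho = 2, spec = spec)
  ses <- simulate_agent(spec, p, sch, seed = 33, missed_rate = 0.04)
  labs <- classify_session(ses, spec, p)
  n_valid <- sum(ses$missed == 0)
  expect_equal(sum(labs %in% c("exploit", "directed", "random")), n_valid)
  bs <- behavioural_summary(ses, labs, sch)
  expect_equal(bs$overall$p_exploit + bs$overall$p_directed +
                 bs$overall$p_random, 1, tolerance = 1e-12)
})

test_that("behavioural metrics match a hand-counted six-trial session", {
  # hand-built 2-bandit-style schedule on four bandits: bandit 1 is best
  # on trials 1-3, bandit 2 on trials 4-6
  wp <- walk_params()
  sch <- generate_schedule(wp, n_trials = 6, seed = 1)
  sch$means <- rbind(c(70, 70, 70, 10, 10, 10),
                     c(10, 10, 10, 70, 70, 70),
                     matrix(20, 2, 6))
  choice <- c(1, 1, 2, NA, 2, 1)  # best hits: t1, t2, t5 -> 3 of 5 valid
  outcome <- c(70, 68, 12, NA, 71, 9)
  ses <- make_session(choice, outcome)
  labs <- c("exploit", "exploit", "random", "missed", "exploit", "random")
  bs <- behavioural_summary(ses, labs, sch)
  expect_equal(bs$overall$p_best, 3 / 5)
  expect_equal(bs$overall$p_missed, 1 / 6)
  # stays: t2 (1 after 1); t5 compares to t3's choice (2): stay;
  # t6 (1 after 2): switch -> 2 stays of 4 comparable valid trials
  expect_equal(bs$overall$p_stay, 2 / 4)
  expect_equal(bs$overall$points_mean, mean(c(70, 68, 12, 71, 9)))
})

test_that("a constant chooser has p_stay 1 and chance-level checks hold", {
  sch <- builtin_schedule("session_out")
  ses <- make_session(rep(1, 300), rep(50, 300))
  labs <- rep("exploit", 300)
  bs <- behavioural_summary(ses, labs, sch)
  expect_equal(bs$overall$p_stay, 1)
  # uniform agent sits at chance for p_best and label base rates
  spec <- model_spec("bayes", "SM")
  u <- simulate_agent(spec, model_params(beta = 0), sch, seed = 34)
  labs_u <- classify_session(u, spec, model_params(beta = 0))
  bs_u <- behavioural_summary(u, labs_u, sch)
  se3 <- 3 * sqrt(0.25 * 0.75 / 300)
  expect_lt(abs(bs_u$overall$p_best - 0.25), se3)
  expect_lt(abs(bs_u$overall$p_exploit - 0.25), se3 + 0.05)
})

test_that("block summaries partition the session into 50-trial blocks", {
  sch <- builtin_schedule("session_out")
  spec <- model_spec("bayes", "SMEP")
  p <- model_params(beta = 0.1, phi = 0.8, rho = 4, spec = spec)
  ses <- simulate_agent(spec, p, sch, seed = 35, missed_rate = 0.03)
  labs <- classify_session(ses, spec, p)
  bs <- behavioural_summary(ses, labs, sch)
  expect_equal(nrow(bs$per_block), 6)
  expect_equal(bs$per_block$n_trials, rep(50, 6))
  expect_equal(sum(bs$per_block$n_valid), sum(ses$missed == 0))
})

test_that("Spearman correlation matches direct rank arithmetic", {
  expect_equal(correlate_with_score(1:6, c(2, 4, 5, 7, 8, 11))$rho, 1)
  expect_equal(correlate_with_score(1:6, -(1:6))$rho, -1)
  x <- c(3.2, 1.5, 4.8, 4.8, 2.2)
  y <- c(10, 14, 7, 9, 12)
  ct <- correlate_with_score(x, y)
  expect_equal(ct$rho, oracle_spearman(x, y), tolerance = 1e-12)
  expect_equal(ct$n, 5)
  expect_warning(out <- correlate_with_score(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$rho))
  expect_error(correlate_with_score(1:2, 1:2), ">= 3")
})
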