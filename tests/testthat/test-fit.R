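sch_fit <- builtin_schedule("session_out")

test_that("MLE dominates the generating parameters and finds beta near 0", {
  # data from the uniform (beta = 0) policy
  spec <- model_spec("bayes", "SM")
  ses <- simulate_agent(spec, model_params(beta = 0), sch_fit, seed = 21)
  fit <- fit_map(spec, ses, config = fit_config(prior = "flat",
                                                n_starts = 6), seed = 1)
  expect_lt(fit$estimates$beta, 0.01)
  ll_gen <- session_log_likelihood(spec, model_params(beta = 0), ses)
  expect_gte(fit$log_lik, ll_gen - 1e-6)

  # and on structured data from a known generator
  spec2 <- model_spec("bayes", "SMEP")
  p2 <- model_params(beta = 0.12, phi = 0.8, rho = 3, spec = spec2)
  ses2 <- simulate_agent(spec2, p2, sch_fit, seed = 22)
  fit2 <- fit_map(spec2, ses2, config = fit_config(prior = "flat",
                                                   n_starts = 8), seed = 2)
  expect_gte(fit2$log_lik, session_log_likelihood(spec2, p2, ses2) - 1e-6)
})

test_that("nesting never decreases the maximized log-likelihood", {
  spec <- model_spec("bayes", "SMP")
  ses <- simulate_agent(spec, model_params(beta = 0.12, rho = 3, spec = spec),
                        sch_fit, seed = 23)
  cfg <- fit_config(prior = "flat", n_starts = 8)
  ll <- vapply(c("SM", "SME", "SMP", "SMEP"), function(cr) {
    fit_map(model_spec("bayes", cr), ses, config = cfg, seed = 3)$log_lik
  }, numeric(1))
  expect_gte(ll[["SME"]], ll[["SM"]] - 1e-6)
  expect_gte(ll[["SMP"]], ll[["SM"]] - 1e-6)
  expect_gte(ll[["SMEP"]], ll[["SME"]] - 1e-6)
  expect_gte(ll[["SMEP"]], ll[["SMP"]] - 1e-6)
})

test_that("fits are deterministic under a fixed seed and report sane summaries", {
  spec <- model_spec("delta", "SMP")
  p <- model_params(beta = 0.15, alpha = 0.5, rho = 2, spec = spec)
  ses <- simulate_agent(spec, p, sch_fit, seed = 24, missed_rate = 0.03)
  a <- fit_map(spec, ses, config = fit_config(n_starts = 5), seed = 7)
  b <- fit_map(spec, ses, config = fit_config(n_starts = 5), seed = 7)
  expect_identical(a$estimates, b$estimates)
  expect_identical(a$summaries, b$summaries)
  expect_equal(a$n_valid_trials, sum(ses$missed == 0))
  expect_true(all(a$summaries$lower <= a$summaries$upper))
  expect_lte(a$log_lik, 0)
  # information criteria consistent with the reported likelihood
  expect_equal(a$aic, 2 * 3 - 2 * a$log_lik)
  expect_equal(a$bic, 3 * log(a$n_valid_trials) - 2 * a$log_lik)
})

test_that("a single-trial session fits without crashing and is uncertain", {
  ses <- make_session(2, 63)
  fit <- fit_map(model_spec("bayes", "SM"), ses,
                 config = fit_config(n_starts = 4), seed = 5)
  expect_s3_class(fit, "bandit_fit")
  expect_equal(fit$n_valid_trials, 1)
  bsum <- fit$summaries[fit$summaries$parameter == "beta", ]
  expect_gt(bsum$upper / max(bsum$lower, 1e-12), 2)  # wide interval
})

test_that("fitting requires at least one valid trial", {
  ses <- make_session(rep(NA, 5), rep(NA, 5))
  expect_error(fit_map(model_spec("bayes", "SM"), ses), "valid")
})

test_that("posterior sampling is reproducible and agrees with the MAP", {
  spec <- model_spec("bayes", "SMP")
  p <- model_params(beta = 0.12, rho = 3, spec = spec)
  ses <- simulate_agent(spec, p, sch_fit, seed = 25)
  cfg <- fit_config(n_starts = 5)
  sc <- sampler_config(n_chains = 2, n_warmup = 400, n_draws = 600)
  post <- suppressWarnings(
    fit_posterior(spec, ses, config = cfg, sampler = sc, seed = 11))
  map <- fit_map(spec, ses, config = cfg, seed = 11)
  for (nm in c("beta", "rho")) {
    ps <- post$summaries[post$summaries$parameter == nm, ]
    mp <- map$estimates[[nm]]
    expect_lt(abs(ps$mean - mp), 3 * ps$sd)
  }
  expect_true(all(is.finite(post$diagnostics$rhat)))
  expect_true(is.finite(post$waic))
  post2 <- suppressWarnings(
    fit_posterior(spec, ses, config = cfg, sampler = sc, seed = 11))
  expect_identical(post$summaries, post2$summaries)
  expect_error(sampler_config(n_draws = 0), "n_draws")
})

test_that("model comparison ranks, records failures, and demands >= 2 specs", {
  spec <- model_spec("bayes", "SMP")
  ses <- simulate_agent(spec, model_params(beta = 0.15, rho = 3, spec = spec),
                        sch_fit, seed = 26)
  tab <- compare_models(ses, list(model_spec("bayes", "SM"),
                                  model_spec("bayes", "SMP"),
                                  model_spec("bayes", "SMEP")),
                        config = fit_config(prior = "flat", n_starts = 5),
                        seed = 4)
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$model[1], "bayes+SMP")
  # nested SMEP cannot have a lower maximized likelihood than SMP
  expect_gte(tab$log_lik[tab$model == "bayes+SMEP"],
             tab$log_lik[tab$model == "bayes+SMP"] - 1e-4)
  expect_error(compare_models(ses, list(model_spec("bayes", "SM"))),
               "at least 2")
})

test_that("group contrasts recover a known shift with a covering interval", {
  spec <- model_spec("bayes", "SM")
  cfg <- fit_config(n_starts = 5)
  fit_group <- function(betas, seed0) {
    lapply(seq_along(betas), function(i) {
      ses <- simulate_agent(spec, model_params(beta = betas[i]), sch_fit,
                            seed = seed0 + i)
      fit_map(spec, ses, config = cfg, seed = seed0 + i)
    })
  }
  set.seed(31)
  betas_a <- pmax(rnorm(12, 0.08, 0.015), 0.01)
  betas_b <- pmax(rnorm(12, 0.10, 0.015), 0.01)
  fits_a <- fit_group(betas_a, 300)
  fits_b <- fit_group(betas_b, 600)
  gc <- group_contrast(fits_a, fits_b, "beta", seed = 1)
  expect_lt(gc$m_diff, 0)
  expect_true(gc$lower <= gc$m_diff && gc$m_diff <= gc$upper)
  # identical groups: contrast is exactly zero
  gc0 <- group_contrast(fits_a, fits_a, "beta", seed = 1)
  expect_equal(gc0$m_diff, 0)
  expect_true(gc0$lower <= 0 && gc0$upper >= 0)
  # degenerate single-subject groups warn
  expect_warning(group_contrast(fits_a[1], fits_b[1], "beta"), "degenerate")
  # inactive parameter is an error
  expect_error(group_contrast(fits_a, fits_b, "rho"), "not active")
})
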