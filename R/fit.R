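#' Fitting configuration
#'
#' @param prior `"weak"` uses weakly-informative priors (\eqn{\alpha}
#'   flat on (0, 1); \eqn{\beta}, \eqn{\phi} half-normal with scales
#'   `prior_scale_beta` / `prior_scale_phi`; \eqn{\rho} normal with sd
#'   `prior_scale_rho`); `"flat"` maximizes the likelihood alone (MLE).
#' @param n_starts Number of optimisation starts; the first is a fixed
#'   central start, the rest a Latin-hypercube over the transformed
#'   parameter box.
#' @param prior_scale_beta,prior_scale_phi,prior_scale_rho Prior scales
#'   on the natural parameter scale.
#' @param allow_negative_phi Fit \eqn{\phi} unconstrained (identity
#'   transform) instead of log-transformed and non-negative.
#' @param bonus_on Exploration-bonus scale, see [choice_probabilities()].
#' @param laplace_draws Multivariate-normal draws used to summarize the
#'   Laplace approximation on the natural scale.
#' @param criterion Model-comparison sort key: `"bic"`, `"aic"` or
#'   `"log_lik"`.
#' @param maxit Iteration cap per optimisation start.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(prior = c("weak", "flat"), n_starts = 10L,
                       prior_scale_beta = 1, prior_scale_phi = 5,
                       prior_scale_rho = 5, allow_negative_phi = FALSE,
                       bonus_on = c("sd", "variance"),
                       laplace_draws = 2000L,
                       criterion = c("bic", "aic", "log_lik"),
                       maxit = 500L) {
  structure(
    list(prior = match.arg(prior), n_starts = as.integer(n_starts),
         prior_scale_beta = prior_scale_beta,
         prior_scale_phi = prior_scale_phi,
         prior_scale_rho = prior_scale_rho,
         allow_negative_phi = isTRUE(allow_negative_phi),
         bonus_on = match.arg(bonus_on),
         laplace_draws = as.integer(laplace_draws),
         criterion = match.arg(criterion), maxit = as.integer(maxit)),
    class = "fit_config"
  )
}

# Transformed (unconstrained) parameterisation:
#   alpha = plogis(a), beta = exp(b), phi = exp(f) (or identity when
#   negative phi is allowed), rho = r.
transform_bounds <- function(spec, config) {
  act <- active_params(spec)
  lower <- c(alpha = -2.5, beta = log(1e-3),
             phi = if (config$allow_negative_phi) -5 else log(0.02),
             rho = -8)
  upper <- c(alpha = 2.5, beta = log(0.5),
             phi = if (config$allow_negative_phi) 5 else log(5),
             rho = 8)
  list(names = act, lower = lower[act], upper = upper[act])
}

theta_to_params <- function(theta, spec, config) {
  act <- active_params(spec)
  names(theta) <- act
  p <- list(alpha = NA_real_, beta = NA_real_, phi = NA_real_, rho = NA_real_)
  if ("alpha" %in% act) p$alpha <- stats::plogis(theta[["alpha"]])
  p$beta <- exp(theta[["beta"]])
  if ("phi" %in% act) {
    p$phi <- if (config$allow_negative_phi) theta[["phi"]]
             else exp(theta[["phi"]])
  }
  if ("rho" %in% act) p$rho <- theta[["rho"]]
  structure(p, class = "model_params")
}

# log prior density on the natural scale + log Jacobian of the
# transform, so the objective is the posterior density in the
# unconstrained space.
log_prior <- function(theta, params, spec, config) {
  if (config$prior == "flat") return(0)
  act <- active_params(spec)
  names(theta) <- act
  lp <- 0
  if ("alpha" %in% act) {
    a <- params$alpha
    lp <- lp + log(a * (1 - a))            # flat prior, logit Jacobian
  }
  lp <- lp - params$beta^2 / (2 * config$prior_scale_beta^2) +
    theta[["beta"]]                         # half-normal + log Jacobian
  if ("phi" %in% act) {
    lp <- lp - params$phi^2 / (2 * config$prior_scale_phi^2)
    if (!config$allow_negative_phi) lp <- lp + theta[["phi"]]
  }
  if ("rho" %in% act) {
    lp <- lp - params$rho^2 / (2 * config$prior_scale_rho^2)
  }
  lp
}

make_objective <- function(spec, session, walk, config, prior_mean,
                           prior_var) {
  session <- validate_session(session)
  # pre-extract the kernel arguments once; the optimizer calls the
  # objective thousands of times
  choice <- as.integer(session$choice)
  outcome <- as.numeric(session$outcome)
  missed <- as.integer(session$missed == 1)
  learning <- if (spec$learning_rule == "bayes") 1L else 0L
  bonus_type <- if (config$bonus_on == "sd") 0L else 1L
  function(theta) {
    params <- theta_to_params(theta, spec, config)
    p <- lapply(params, function(v) if (is.na(v)) 0 else v)
    ll <- tryCatch(
      session_trace_cpp(choice, outcome, missed, 4L, learning,
                        spec$uses_explore, spec$uses_persev, bonus_type,
                        p$alpha, p$beta, p$phi, p$rho,
                        walk$decay, walk$decay_center, walk$diffusion_sd,
                        walk$observation_sd, prior_mean, prior_var,
                        FALSE)$log_lik,
      error = function(e) -Inf
    )
    val <- ll + log_prior(theta, params, spec, config)
    if (!is.finite(val)) return(1e10)
    -val
  }
}

optim_one_start <- function(start, objective, config) {
  res <- tryCatch(
    stats::optim(start, objective, method = "BFGS",
                 control = list(maxit = config$maxit)),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$value)) {
    res <- tryCatch(
      stats::optim(start, objective, method = "Nelder-Mead",
                   control = list(maxit = 2L * config$maxit)),
      error = function(e) NULL
    )
  }
  res
}

#' Fit a model variant to one session by MAP (or MLE)
#'
#' Maximizes the log-likelihood plus log-prior over transformed
#' parameters (\eqn{\alpha} logit-transformed; \eqn{\beta}, \eqn{\phi}
#' log-transformed unless negative \eqn{\phi} is allowed; \eqn{\rho}
#' unconstrained), multi-starting from dispersed Latin-hypercube points
#' and keeping the best optimum (ties broken by lowest start index).
#' Posterior summaries come from a Laplace approximation at the optimum.
#' With `prior = "flat"` the result is the maximum-likelihood estimate.
#'
#' @param spec A [model_spec()].
#' @param session Session data frame with at least one valid trial.
#' @param config A [fit_config()].
#' @param walk Walk parameters assumed by the learner.
#' @param seed Seed for the start dispersion and Laplace draws.
#' @param prior_mean,prior_var Initial beliefs, see [init_beliefs()].
#' @return An object of class `bandit_fit` with point estimates,
#'   per-parameter posterior summaries (mean, sd, central 95% interval),
#'   the log-likelihood at the estimate, `n_valid_trials`, AIC, BIC and
#'   convergence diagnostics.
#' @examples
#' sch <- builtin_schedule("session_out")
#' ses <- simulate_agent(model_spec("bayes", "SM"),
#'                       model_params(beta = 0.12), sch, seed = 7)
#' fit <- fit_map(model_spec("bayes", "SM"), ses,
#'                config = fit_config(n_starts = 4))
#' fit$estimates$beta
#' @export
fit_map <- function(spec, session, config = fit_config(),
                    walk = walk_params(), seed = 1L,
                    prior_mean = walk$decay_center,
                    prior_var = stationary_variance(walk)) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "fit_config"))
  session <- validate_session(session)
  n_valid <- sum(session$missed == 0)
  if (n_valid < 1) {
    stop("fit requires at least one valid (non-missed) trial", call. = FALSE)
  }
  objective <- make_objective(spec, session, walk, config, prior_mean,
                              prior_var)
  tb <- transform_bounds(spec, config)
  d <- length(tb$names)

  central <- c(alpha = 0, beta = log(0.05), phi = log(0.5), rho = 0)
  if (config$allow_negative_phi) central[["phi"]] <- 0.5
  starts <- matrix(central[tb$names], nrow = 1,
                   dimnames = list(NULL, tb$names))
  if (config$n_starts > 1) {
    u <- with_seed(seed, lhs::randomLHS(config$n_starts - 1L, d))
    extra <- sweep(u, 2, tb$upper - tb$lower, "*")
    extra <- sweep(extra, 2, tb$lower, "+")
    colnames(extra) <- tb$names
    starts <- rbind(starts, extra)
  }

  best <- NULL
  best_start <- NA_integer_
  n_ok <- 0L
  for (s in seq_len(nrow(starts))) {
    res <- optim_one_start(starts[s, ], objective, config)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value - 1e-12) {
      best <- res
      best_start <- s
    }
  }
  if (is.null(best)) {
    stop(sprintf("fit of %s failed to converge from any of %d starts",
                 spec_label(spec), nrow(starts)), call. = FALSE)
  }

  theta_hat <- best$par
  params_hat <- theta_to_params(theta_hat, spec, config)
  ll_hat <- session_log_likelihood(spec, params_hat, session, walk,
                                   bonus_on = config$bonus_on,
                                   prior_mean = prior_mean,
                                   prior_var = prior_var)

  # Laplace approximation on the transformed scale, summarized on the
  # natural scale via MVN draws.
  hess <- tryCatch(stats::optimHess(theta_hat, objective),
                   error = function(e) NULL)
  sigma <- NULL
  if (!is.null(hess)) {
    hess <- (hess + t(hess)) / 2
    sigma <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(sigma) && any(!is.finite(sigma) | diag(sigma) <= 0)) {
      sigma <- NULL
    }
  }
  if (is.null(sigma)) {
    dh <- if (!is.null(hess)) pmax(diag(hess), 1e-4) else rep(1e-4, d)
    sigma <- diag(1 / dh, d)
  }
  sigma <- (sigma + t(sigma)) / 2
  draws <- with_seed(seed + 1L, tryCatch(
    MASS::mvrnorm(config$laplace_draws, mu = theta_hat, Sigma = sigma),
    error = function(e) {
      MASS::mvrnorm(config$laplace_draws, mu = theta_hat,
                    Sigma = diag(pmax(diag(sigma), 1e-6), d))
    }
  ))
  draws <- matrix(draws, ncol = d)
  natural <- t(apply(draws, 1, function(th) {
    unlist(theta_to_params(th, spec, config)[tb$names])
  }))
  natural <- matrix(natural, ncol = d, dimnames = list(NULL, tb$names))
  summaries <- data.frame(
    parameter = tb$names,
    mean = colMeans(natural),
    sd = apply(natural, 2, stats::sd),
    lower = apply(natural, 2, stats::quantile, probs = 0.025),
    upper = apply(natural, 2, stats::quantile, probs = 0.975),
    row.names = NULL
  )

  k <- d
  structure(
    list(spec = spec, method = "map",
         estimates = params_hat,
         theta = theta_hat,
         summaries = summaries,
         log_lik = ll_hat,
         log_post = -best$value,
         n_valid_trials = n_valid,
         aic = 2 * k - 2 * ll_hat,
         bic = k * log(n_valid) - 2 * ll_hat,
         convergence = list(code = best$convergence,
                            n_starts = nrow(starts),
                            n_converged = n_ok,
                            best_start = best_start),
         config = config, walk = walk, seed = as.integer(seed)),
    class = "bandit_fit"
  )
}

#' @export
print.bandit_fit <- function(x, ...) {
  cat(sprintf("<bandit_fit %s (%s): logLik %.2f on %d valid trials>\n",
              spec_label(x$spec), x$method, x$log_lik, x$n_valid_trials))
  est <- x$summaries
  est$estimate <- unlist(x$estimates[est$parameter])
  print(est[, c("parameter", "estimate", "mean", "sd", "lower", "upper")],
        digits = 4, row.names = FALSE)
  cat(sprintf("  AIC %.1f  BIC %.1f\n", x$aic, x$bic))
  invisible(x)
}
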