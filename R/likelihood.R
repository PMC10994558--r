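# Shared bridge from R arguments to the compiled session kernel.
call_session_kernel <- function(spec, params, session, walk, bonus_on,
                                prior_mean, prior_var, trace) {
  session <- validate_session(session)
  p <- params_for_kernel(params, spec)
  session_trace_cpp(
    choice = as.integer(session$choice),
    outcome = as.numeric(session$outcome),
    missed = as.integer(session$missed == 1),
    n_bandits = attr(session, "n_bandits") %||% 4L,
    learning = if (spec$learning_rule == "bayes") 1L else 0L,
    use_explore = spec$uses_explore,
    use_persev = spec$uses_persev,
    bonus_type = if (bonus_on == "sd") 0L else 1L,
    alpha = p$alpha, beta = p$beta, phi = p$phi, rho = p$rho,
    decay = walk$decay, center = walk$decay_center,
    diffusion_sd = walk$diffusion_sd, observation_sd = walk$observation_sd,
    prior_mean = prior_mean, prior_var = prior_var,
    trace = trace
  )
}

#' Log-likelihood of a session under a model variant
#'
#' Evolves the learner's beliefs along the recorded history (observed
#' choices and outcomes, never re-simulated ones) and sums the log
#' choice probability over non-missed trials. Missed trials contribute
#' zero and trigger no observation update; the Bayesian diffusion step
#' still runs between trials.
#'
#' @param spec A [model_spec()].
#' @param params A [model_params()] set for `spec`.
#' @param session Session data frame (see [simulate_agent()]); rows are
#'   re-ordered by `trial` if needed. A non-missed trial without an
#'   outcome, or a missed trial with one, is a data-integrity error.
#' @param walk Walk parameters assumed by the Bayesian learner.
#' @param bonus_on Exploration-bonus scale, see [choice_probabilities()].
#' @param prior_mean,prior_var Initial beliefs, see [init_beliefs()].
#' @return Total log-likelihood in nats (<= 0).
#' @examples
#' sch <- builtin_schedule("session_out")
#' ses <- simulate_agent(model_spec("bayes", "SM"),
#'                       model_params(beta = 0.1), sch, seed = 1)
#' session_log_likelihood(model_spec("bayes", "SM"),
#'                        model_params(beta = 0.1), ses)
#' @export
session_log_likelihood <- function(spec, params, session,
                                   walk = walk_params(),
                                   bonus_on = c("sd", "variance"),
                                   prior_mean = walk$decay_center,
                                   prior_var = stationary_variance(walk)) {
  stopifnot(inherits(spec, "model_spec"))
  bonus_on <- match.arg(bonus_on)
  res <- call_session_kernel(spec, params, session, walk, bonus_on,
                             prior_mean, prior_var, trace = FALSE)
  res$log_lik
}

#' Per-trial belief and probability trace for a session
#'
#' The pre-trial belief state (values, variances, recency counters,
#' last choice), the four choice probabilities, and the per-trial log
#' choice probability, for every trial of the recorded session.
#'
#' @inheritParams session_log_likelihood
#' @return A list with `log_lik`, matrices `values`, `variances`,
#'   `probs`, `trials_since` (trials x bandits, state *before* each
#'   trial), vector `last_choice` and `trial_log_lik`.
#' @export
session_belief_trace <- function(spec, params, session,
                                 walk = walk_params(),
                                 bonus_on = c("sd", "variance"),
                                 prior_mean = walk$decay_center,
                                 prior_var = stationary_variance(walk)) {
  stopifnot(inherits(spec, "model_spec"))
  bonus_on <- match.arg(bonus_on)
  call_session_kernel(spec, params, session, walk, bonus_on,
                      prior_mean, prior_var, trace = TRUE)
}
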