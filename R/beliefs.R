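#' Initialize a learner's belief state
#'
#' All bandit value estimates start at the prior mean (the walk's decay
#' centre by default) and, for the Bayesian learner, all posterior
#' variances at the prior variance (the walk's stationary variance by
#' default). Recency counters start at zero and no last choice is set.
#'
#' @param spec A [model_spec()].
#' @param n_bandits Number of bandits.
#' @param prior_mean Prior value estimate (points).
#' @param prior_var Prior variance (points^2); Bayesian learner only.
#'   Defaults to the stationary variance of `walk`.
#' @param walk Walk parameters used for the defaults.
#' @return An object of class `belief_state` with fields `values`,
#'   `variances` (`NULL` for delta-rule variants), `last_choice`
#'   (`NA` before any choice) and `trials_since` (per-bandit recency
#'   counters).
#' @examples
#' init_beliefs(model_spec("bayes", "SMEP"))
#' @export
init_beliefs <- function(spec, n_bandits = 4L,
                         prior_mean = walk$decay_center,
                         prior_var = stationary_variance(walk),
                         walk = walk_params()) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$learning_rule == "bayes") {
    if (!is.numeric(prior_var) || prior_var <= 0) {
      stop_config("beliefs.prior_var", "must be > 0 for the Bayesian learner")
    }
    variances <- rep(as.numeric(prior_var), n_bandits)
  } else {
    variances <- NULL
  }
  structure(
    list(values = rep(as.numeric(prior_mean), n_bandits),
         variances = variances,
         last_choice = NA_integer_,
         trials_since = rep(0L, n_bandits),
         spec = spec),
    class = "belief_state"
  )
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state %s: Q = (%s)", spec_label(x$spec),
              paste(sprintf("%.2f", x$values), collapse = ", ")))
  if (!is.null(x$variances)) {
    cat(sprintf("; s^2 = (%s)",
                paste(sprintf("%.2f", x$variances), collapse = ", ")))
  }
  cat(sprintf("; last = %s>\n", ifelse(is.na(x$last_choice), "none",
                                       x$last_choice)))
  invisible(x)
}

# Advance recency counters after a trial; choice = NA for a missed
# trial (counters still advance, last_choice is unchanged because no
# action was made).
advance_recency <- function(beliefs, choice = NA_integer_) {
  beliefs$trials_since <- beliefs$trials_since + 1L
  if (!is.na(choice)) {
    beliefs$trials_since[choice] <- 0L
    beliefs$last_choice <- as.integer(choice)
  }
  beliefs
}

check_choice <- function(beliefs, choice) {
  nb <- length(beliefs$values)
  if (!is_count(choice) || choice < 1 || choice > nb) {
    stop(sprintf("choice %s out of range [1, %d]", format(choice), nb),
         call. = FALSE)
  }
}

#' Delta-rule value update
#'
#' \eqn{Q_c \leftarrow Q_c + \alpha (r - Q_c)}; unchosen values are
#' unchanged. Recency counters and the last choice are advanced.
#'
#' @param beliefs A `belief_state`.
#' @param choice Chosen bandit (1-based).
#' @param outcome Observed payout (points).
#' @param alpha Learning rate in (0, 1).
#' @return Updated `belief_state`.
#' @export
delta_update <- function(beliefs, choice, outcome, alpha) {
  stopifnot(inherits(beliefs, "belief_state"))
  check_choice(beliefs, choice)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("params.alpha: must lie strictly in (0, 1)", call. = FALSE)
  }
  beliefs$values[choice] <- beliefs$values[choice] +
    alpha * (outcome - beliefs$values[choice])
  advance_recency(beliefs, choice)
}

#' Kalman-filter observation update
#'
#' Gain \eqn{\kappa = s_c^2 / (s_c^2 + \sigma_o^2)}; then
#' \eqn{Q_c \leftarrow Q_c + \kappa (r - Q_c)} and
#' \eqn{s_c^2 \leftarrow (1 - \kappa) s_c^2}. Unchosen bandits are
#' untouched by the observation step (they change only via
#' [diffuse_beliefs()]).
#'
#' @inheritParams delta_update
#' @param walk Walk parameters (supplies \eqn{\sigma_o}).
#' @return Updated `belief_state`.
#' @export
kalman_update <- function(beliefs, choice, outcome, walk = walk_params()) {
  stopifnot(inherits(beliefs, "belief_state"), inherits(walk, "walk_params"))
  if (is.null(beliefs$variances)) {
    stop(sprintf("kalman_update requires a Bayesian belief state, got %s",
                 spec_label(beliefs$spec)), call. = FALSE)
  }
  check_choice(beliefs, choice)
  s2 <- beliefs$variances[choice]
  gain <- s2 / (s2 + walk$observation_sd^2)
  beliefs$values[choice] <- beliefs$values[choice] +
    gain * (outcome - beliefs$values[choice])
  beliefs$variances[choice] <- (1 - gain) * s2
  advance_recency(beliefs, choice)
}

#' Between-trial diffusion (prediction) step of the Bayesian learner
#'
#' Tracks the decaying walk: for every bandit
#' \eqn{Q_i \leftarrow \lambda Q_i + (1 - \lambda)\theta} and
#' \eqn{s_i^2 \leftarrow \lambda^2 s_i^2 + \sigma_d^2}. Applied after
#' every trial, including missed trials.
#'
#' @param beliefs A Bayesian `belief_state`.
#' @param walk Walk parameters.
#' @return Updated `belief_state`.
#' @export
diffuse_beliefs <- function(beliefs, walk = walk_params()) {
  stopifnot(inherits(beliefs, "belief_state"), inherits(walk, "walk_params"))
  if (is.null(beliefs$variances)) {
    stop(sprintf("diffuse_beliefs requires a Bayesian belief state, got %s",
                 spec_label(beliefs$spec)), call. = FALSE)
  }
  beliefs$values <- walk$decay * beliefs$values +
    (1 - walk$decay) * walk$decay_center
  beliefs$variances <- walk$decay^2 * beliefs$variances + walk$diffusion_sd^2
  beliefs
}

# Per-bandit uncertainty term multiplied by phi in the softmax logit.
uncertainty_term <- function(beliefs, spec, bonus_on = c("sd", "variance")) {
  bonus_on <- match.arg(bonus_on)
  if (spec$learning_rule == "bayes") {
    if (bonus_on == "sd") sqrt(beliefs$variances) else beliefs$variances
  } else {
    as.numeric(beliefs$trials_since)
  }
}

#' Softmax choice probabilities with exploration and perseveration bonuses
#'
#' \deqn{P(c) \propto \exp(\beta Q_c + \phi u_c + \rho\,[c =
#'   \mathrm{last}])}
#' where the \eqn{\phi} term is present only for SME/SMEP (with
#' \eqn{u_c} the posterior SD or variance for the Bayesian learner, or
#' the recency count for the delta rule) and the \eqn{\rho} term only
#' for SMP/SMEP. Computed with the log-sum-exp trick, so large logits
#' do not overflow.
#'
#' @param beliefs A `belief_state`.
#' @param params A [model_params()] set (inactive parameters may be NA).
#' @param spec Model variant; defaults to the one carried by `beliefs`.
#' @param bonus_on For Bayesian learners, whether \eqn{\phi} multiplies
#'   the posterior `"sd"` (default) or `"variance"`.
#' @return Probability vector over bandits, summing to 1.
#' @examples
#' b <- init_beliefs(model_spec("bayes", "SM"))
#' b$values <- c(60, 50, 40, 30)
#' choice_probabilities(b, model_params(beta = 0.1))
#' @export
choice_probabilities <- function(beliefs, params, spec = beliefs$spec,
                                 bonus_on = c("sd", "variance")) {
  stopifnot(inherits(beliefs, "belief_state"))
  bonus_on <- match.arg(bonus_on)
  beta <- params$beta %||% 0
  phi <- params$phi %||% 0
  rho <- params$rho %||% 0
  if (is.na(beta)) beta <- 0
  logits <- beta * beliefs$values
  if (spec$uses_explore && !is.na(phi)) {
    logits <- logits + phi * uncertainty_term(beliefs, spec, bonus_on)
  }
  if (spec$uses_persev && !is.na(rho) && !is.na(beliefs$last_choice)) {
    logits[beliefs$last_choice] <- logits[beliefs$last_choice] + rho
  }
  if (any(!is.finite(logits))) {
    stop("non-finite softmax logits; check parameter and belief values",
         call. = FALSE)
  }
  w <- exp(logits - max(logits))
  w / sum(w)
}
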