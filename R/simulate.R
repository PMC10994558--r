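#' Simulate an agent playing a restless-bandit schedule
#'
#' Runs one session: on each trial the agent misses with probability
#' `missed_rate` (no choice, no outcome, no observation update — the
#' Bayesian prediction step still runs); otherwise it samples a choice
#' from [choice_probabilities()], reads the realized payout from the
#' schedule, applies the learning update and then (Bayesian learner)
#' the diffusion step. Deterministic under a fixed seed; the per-trial
#' draw order is: missed-trial uniform, choice sample, decision-time
#' draw.
#'
#' Decision times are pass-through metadata (log-normal draws truncated
#' to the 1.5-s response deadline), not a model of reaction times.
#'
#' @param spec A [model_spec()].
#' @param params A [model_params()] set valid for `spec`.
#' @param schedule A [generate_schedule()] / [builtin_schedule()] object.
#' @param seed Integer seed.
#' @param missed_rate Probability of a missed trial, in `[0, 1)`;
#'   `missed_rate = 1` is accepted for the degenerate all-missed case.
#' @param n_trials Number of trials to play (defaults to the full
#'   schedule; must not exceed it).
#' @param subject Subject label written into the output.
#' @param bonus_on Exploration-bonus scale, see [choice_probabilities()].
#' @param prior_mean,prior_var Initial beliefs, see [init_beliefs()].
#' @return A data frame with columns `subject`, `trial` (1-based),
#'   `block` (50-trial blocks), `choice` (1-based or NA), `outcome`
#'   (integer points or NA), `rt_s` (seconds or NA), `missed` (0/1) and
#'   `schedule_id`.
#' @examples
#' sch <- builtin_schedule("session_out")
#' ses <- simulate_agent(model_spec("bayes", "SMEP"),
#'                       model_params(beta = 0.1, phi = 0.8, rho = 4),
#'                       sch, seed = 1, missed_rate = 0.03)
#' head(ses)
#' @export
simulate_agent <- function(spec, params, schedule, seed = 1L,
                           missed_rate = 0,
                           n_trials = schedule$n_trials,
                           subject = "sim01",
                           bonus_on = c("sd", "variance"),
                           prior_mean = schedule$walk_params$decay_center,
                           prior_var = stationary_variance(schedule$walk_params)) {
  stopifnot(inherits(spec, "model_spec"), inherits(schedule, "bandit_schedule"))
  bonus_on <- match.arg(bonus_on)
  if (!is.numeric(missed_rate) || missed_rate < 0 || missed_rate > 1) {
    stop_config("simulate.missed_rate", "must lie in [0, 1]")
  }
  if (n_trials > schedule$n_trials) {
    stop(sprintf("requested %d trials but schedule has only %d",
                 n_trials, schedule$n_trials), call. = FALSE)
  }
  params_for_kernel(params, spec)  # validates active parameter ranges
  walk <- schedule$walk_params
  nb <- schedule$n_bandits

  with_seed(seed, {
    beliefs <- init_beliefs(spec, n_bandits = nb, prior_mean = prior_mean,
                            prior_var = if (spec$learning_rule == "bayes")
                              prior_var else NULL,
                            walk = walk)
    choice <- integer(n_trials)
    outcome <- numeric(n_trials)
    rt <- numeric(n_trials)
    missed <- logical(n_trials)
    for (t in seq_len(n_trials)) {
      missed[t] <- stats::runif(1) < missed_rate
      if (missed[t]) {
        choice[t] <- NA_integer_
        outcome[t] <- NA_real_
        rt[t] <- NA_real_
        beliefs <- advance_recency(beliefs, NA_integer_)
      } else {
        p <- choice_probabilities(beliefs, params, spec, bonus_on)
        c_t <- sample.int(nb, 1L, prob = p)
        choice[t] <- c_t
        outcome[t] <- schedule$payouts[c_t, t]
        rt[t] <- min(stats::rlnorm(1, meanlog = log(0.55), sdlog = 0.3), 1.49)
        if (spec$learning_rule == "delta") {
          beliefs <- delta_update(beliefs, c_t, outcome[t], params$alpha)
        } else {
          beliefs <- kalman_update(beliefs, c_t, outcome[t], walk)
        }
      }
      if (spec$learning_rule == "bayes") {
        beliefs <- diffuse_beliefs(beliefs, walk)
      }
    }
    data.frame(
      subject = subject,
      trial = seq_len(n_trials),
      block = ceiling(seq_len(n_trials) / 50),
      choice = choice,
      outcome = outcome,
      rt_s = round(rt, 3),
      missed = as.integer(missed),
      schedule_id = schedule$instantiation_id,
      stringsAsFactors = FALSE
    )
  })
}

# Validate a session data frame: ordered trials, missed trials carry no
# choice/outcome, valid trials carry both.
validate_session <- function(session) {
  need <- c("trial", "choice", "outcome", "missed")
  miss <- setdiff(need, names(session))
  if (length(miss)) {
    stop(sprintf("session is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  session <- session[order(session$trial), , drop = FALSE]
  mis <- session$missed == 1
  if (any(mis & (!is.na(session$choice) | !is.na(session$outcome)))) {
    stop("data integrity: missed trials must have empty choice and outcome",
         call. = FALSE)
  }
  if (any(!mis & (is.na(session$choice) | is.na(session$outcome)))) {
    stop("data integrity: non-missed trials must have both choice and outcome",
         call. = FALSE)
  }
  session
}
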