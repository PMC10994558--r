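choice_type_levels <- c("exploit", "directed", "random", "missed")

#' Classify one choice as exploit / directed / random exploration
#'
#' A choice is *exploit* when the chosen bandit's estimated value is
#' the (tie-broken: any argmax counts) maximum. Otherwise exactly one
#' non-best bandit is the *directed* target — the one with the largest
#' posterior variance for Bayesian learners, or the one unchosen
#' longest (largest recency count) for delta-rule learners, ties broken
#' toward the lowest bandit index — and choosing it is *directed*
#' exploration; choosing any other lower-valued bandit is *random*
#' exploration. A missed trial is labelled `missed` without inspecting
#' the beliefs.
#'
#' @param beliefs_before Belief state reflecting all information up to,
#'   but not including, this trial's outcome.
#' @param choice Chosen bandit (1-based), or `NA` for a missed trial.
#' @param spec Model variant; defaults to the one in `beliefs_before`.
#' @return One of `"exploit"`, `"directed"`, `"random"`, `"missed"`.
#' @examples
#' b <- init_beliefs(model_spec("bayes", "SMEP"))
#' b$values <- c(60, 50, 40, 30)
#' classify_trial(b, 1)  # exploit
#' @export
classify_trial <- function(beliefs_before, choice,
                           spec = beliefs_before$spec) {
  if (is.na(choice)) return("missed")
  check_choice(beliefs_before, choice)
  q <- beliefs_before$values
  tol <- 1e-9
  qmax <- max(q)
  if (q[choice] >= qmax - tol) return("exploit")
  non_best <- which(q < qmax - tol)
  crit <- if (spec$learning_rule == "bayes") {
    beliefs_before$variances[non_best]
  } else {
    as.numeric(beliefs_before$trials_since[non_best])
  }
  target <- non_best[which.max(crit)]  # which.max takes the lowest index tie
  if (choice == target) "directed" else "random"
}

#' Classify every trial of a session
#'
#' Evolves beliefs along the recorded history (observation update on
#' valid trials, recency advance on every trial, Bayesian diffusion
#' between trials) and labels each trial with [classify_trial()] using
#' the beliefs *before* that trial's outcome.
#'
#' @param session Session data frame.
#' @param spec Model variant supplying the learner.
#' @param params Fitted or supplied [model_params()] (only \eqn{\alpha}
#'   affects the labels, via the delta-rule value trace).
#' @param walk Walk parameters.
#' @param prior_mean,prior_var Initial beliefs.
#' @return Character vector of labels, one per trial, in
#'   `c("exploit", "directed", "random", "missed")`.
#' @export
classify_session <- function(session, spec, params, walk = walk_params(),
                             prior_mean = walk$decay_center,
                             prior_var = stationary_variance(walk)) {
  stopifnot(inherits(spec, "model_spec"))
  session <- validate_session(session)
  p <- params_for_kernel(params, spec)
  beliefs <- init_beliefs(spec, n_bandits = 4L, prior_mean = prior_mean,
                          prior_var = if (spec$learning_rule == "bayes")
                            prior_var else NULL,
                          walk = walk)
  labels <- character(nrow(session))
  for (t in seq_len(nrow(session))) {
    c_t <- session$choice[t]
    labels[t] <- classify_trial(beliefs, c_t, spec)
    if (is.na(c_t)) {
      beliefs <- advance_recency(beliefs, NA_integer_)
    } else if (spec$learning_rule == "delta") {
      beliefs <- delta_update(beliefs, c_t, session$outcome[t], p$alpha)
    } else {
      beliefs <- kalman_update(beliefs, c_t, session$outcome[t], walk)
    }
    if (spec$learning_rule == "bayes") {
      beliefs <- diffuse_beliefs(beliefs, walk)
    }
  }
  labels
}

#' Model-free behavioural summary of a session
#'
#' Computes the task's model-free metrics with valid (non-missed)
#' trials as the denominator: `p_best` (choosing the bandit with the
#' highest scheduled *latent mean* that trial, or the highest realized
#' payout when `best_by = "payout"`), mean points won, the three choice
#' -type proportions, `p_stay` (repeating the previous *valid* trial's
#' choice), `p_missed` (missed over all trials) and mean decision time.
#' Block metrics are computed over 50-trial blocks (trials 1-50,
#' 51-100, ...).
#'
#' @param session Session data frame.
#' @param labels Labels from [classify_session()], aligned to trials.
#' @param schedule The schedule the session was played on.
#' @param best_by `"mean"` (latent mean, default) or `"payout"`
#'   (realized payout) defines the best bandit per trial.
#' @return A list of class `behav_summary` with one-row data frame
#'   `overall` and per-block data frame `per_block`.
#' @export
behavioural_summary <- function(session, labels, schedule,
                                best_by = c("mean", "payout")) {
  stopifnot(inherits(schedule, "bandit_schedule"))
  best_by <- match.arg(best_by)
  session <- validate_session(session)
  if (length(labels) != nrow(session)) {
    stop("labels must align one-to-one with session trials", call. = FALSE)
  }
  if (max(session$trial) > schedule$n_trials) {
    stop("session has trials beyond the end of the schedule", call. = FALSE)
  }
  ref <- if (best_by == "mean") schedule$means else schedule$payouts
  best <- apply(ref, 2, which.max)[session$trial]
  valid <- session$missed == 0

  # previous valid choice for each trial (NA before the first valid one)
  prev_valid <- rep(NA_integer_, nrow(session))
  last <- NA_integer_
  for (t in seq_len(nrow(session))) {
    prev_valid[t] <- last
    if (valid[t]) last <- session$choice[t]
  }

  metrics <- function(idx) {
    v <- idx & valid
    nv <- sum(v)
    stay_ok <- v & !is.na(prev_valid)
    data.frame(
      n_trials = sum(idx),
      n_valid = nv,
      p_best = if (nv) mean(session$choice[v] == best[v]) else NA_real_,
      points_mean = if (nv) mean(session$outcome[v]) else NA_real_,
      p_exploit = if (nv) mean(labels[v] == "exploit") else NA_real_,
      p_directed = if (nv) mean(labels[v] == "directed") else NA_real_,
      p_random = if (nv) mean(labels[v] == "random") else NA_real_,
      p_stay = if (sum(stay_ok)) {
        mean(session$choice[stay_ok] == prev_valid[stay_ok])
      } else NA_real_,
      p_missed = mean(!valid[idx]),
      decision_time = if (nv && any(!is.na(session$rt_s[v]))) {
        mean(session$rt_s[v], na.rm = TRUE)
      } else NA_real_
    )
  }

  overall <- metrics(rep(TRUE, nrow(session)))
  blocks <- ceiling(session$trial / 50)
  per_block <- do.call(rbind, lapply(sort(unique(blocks)), function(b) {
    cbind(block = b, metrics(blocks == b))
  }))
  structure(list(overall = overall, per_block = per_block),
            class = "behav_summary")
}

#' @export
print.behav_summary <- function(x, ...) {
  cat("<behav_summary>\n")
  print(x$overall, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation of a behavioural metric with a score
#'
#' Tie-corrected Spearman correlation with a two-sided p-value, as used
#' for relating per-subject task metrics to apathy (LARS) scores.
#'
#' @param metric Numeric vector of per-subject metric values.
#' @param score Numeric vector of per-subject scores, same length.
#' @return A list with `rho`, `p`, `n` and a `note` flagging undefined
#'   correlations (constant input).
#' @examples
#' correlate_with_score(c(1, 2, 3, 4, 5), c(2, 4, 5, 7, 9))
#' @export
correlate_with_score <- function(metric, score) {
  ok <- stats::complete.cases(metric, score)
  metric <- metric[ok]
  score <- score[ok]
  n <- length(metric)
  if (n < 3L) {
    stop("correlate_with_score requires >= 3 paired observations",
         call. = FALSE)
  }
  if (stats::sd(metric) == 0 || stats::sd(score) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_, n = n, note = "constant input"))
  }
  ct <- suppressWarnings(
    stats::cor.test(metric, score, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, note = "ok")
}
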