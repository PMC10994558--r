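#' Configuration of a synthetic study cohort
#'
#' Three groups (healthy control, PD without apathy, PD with apathy)
#' with group-shifted decision parameters, group-level apathy (LARS)
#' scores linked to each subject's decision-parameter deficit, ~3%
#' missed trials, and one 300-trial session per subject on a built-in
#' schedule (optionally a second session on the other schedule).
#'
#' The default parameter *levels* anchor the PD-no-apathy group at
#' \eqn{\beta = 0.10}, \eqn{\phi = 0.8}, \eqn{\rho = 4.0},
#' \eqn{\alpha = 0.4} and shift the apathy group by the study's
#' reported group contrasts (\eqn{\beta} by \eqn{-0.02}, \eqn{\phi} by
#' \eqn{-0.40}, \eqn{\rho} by \eqn{-3.57}); healthy controls sit at the
#' no-apathy level. Group LARS centres/sds are \eqn{-28.1 \pm 3.6}
#' (HC), \eqn{-28.0 \pm 2.9} (PD no-apathy) and \eqn{-14.0 \pm 5.2}
#' (PD-apathy), truncated to \eqn{[-36, 36]}; scores above \eqn{-22}
#' are flagged apathetic.
#'
#' @param n_hc,n_pd_no_apathy,n_pd_apathy Group sizes (defaults 22, 28,
#'   25).
#' @param spec Generating model variant (Bayesian learner with both
#'   bonuses by default).
#' @param group_means Named list (`hc`, `pd_no_apathy`, `pd_apathy`) of
#'   lists with `alpha`, `beta`, `phi`, `rho` group means.
#' @param param_spread Named list of between-subject sds for the four
#'   parameters.
#' @param lars_centers,lars_sds Named numeric vectors of group LARS
#'   centres and sds.
#' @param lars_loading Loading (0-1) of the subject's standardized
#'   \eqn{\beta + \rho} deficit on their LARS score; 0.5 by default so
#'   behaviour-LARS correlations are non-trivial within groups.
#' @param missed_rate Missed-trial probability (all groups).
#' @param schedule `"session_out"` or `"session_in"`.
#' @param two_sessions Also simulate a second session on the other
#'   built-in schedule.
#' @param apathy_cutoff LARS threshold above which a subject is flagged
#'   apathetic.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_hc = 22L, n_pd_no_apathy = 28L,
                          n_pd_apathy = 25L,
                          spec = model_spec("bayes", "SMEP"),
                          group_means = NULL, param_spread = NULL,
                          lars_centers = c(hc = -28.1, pd_no_apathy = -28.0,
                                           pd_apathy = -14.0),
                          lars_sds = c(hc = 3.6, pd_no_apathy = 2.9,
                                       pd_apathy = 5.2),
                          lars_loading = 0.5, missed_rate = 0.03,
                          schedule = "session_out", two_sessions = FALSE,
                          apathy_cutoff = -22) {
  for (nm in c("n_hc", "n_pd_no_apathy", "n_pd_apathy")) {
    v <- get(nm)
    if (!is_count(v) || v < 0) {
      stop_config(paste0("cohort.", nm), "must be an integer >= 0")
    }
  }
  base <- list(alpha = 0.4, beta = 0.10, phi = 0.8, rho = 4.0)
  apath <- list(alpha = 0.4, beta = 0.10 - 0.02, phi = 0.8 - 0.40,
                rho = 4.0 - 3.57)
  group_means <- group_means %||%
    list(hc = base, pd_no_apathy = base, pd_apathy = apath)
  param_spread <- param_spread %||%
    list(alpha = 0.10, beta = 0.03, phi = 0.25, rho = 1.2)
  if (any(unlist(param_spread) < 0)) {
    stop_config("cohort.param_spread", "spreads must be >= 0")
  }
  if (lars_loading < 0 || lars_loading > 1) {
    stop_config("cohort.lars_loading", "must lie in [0, 1]")
  }
  if (missed_rate < 0 || missed_rate >= 1) {
    stop_config("cohort.missed_rate", "must lie in [0, 1)")
  }
  structure(
    list(n_hc = as.integer(n_hc),
         n_pd_no_apathy = as.integer(n_pd_no_apathy),
         n_pd_apathy = as.integer(n_pd_apathy),
         spec = spec, group_means = group_means,
         param_spread = param_spread,
         lars_centers = lars_centers, lars_sds = lars_sds,
         lars_loading = lars_loading, missed_rate = missed_rate,
         schedule = schedule, two_sessions = isTRUE(two_sessions),
         apathy_cutoff = apathy_cutoff),
    class = "cohort_config"
  )
}

#' Default cohort configuration
#'
#' [cohort_config()] with all defaults: group sizes 22/28/25, the
#' reported between-group parameter shifts, group LARS levels, and a 3%
#' missed-trial rate.
#'
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function() cohort_config()

truncate_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Sample a complete synthetic cohort
#'
#' Draws per-subject decision parameters and LARS scores from the
#' configured group distributions and simulates each subject's
#' session(s) with [simulate_agent()]. The ground-truth parameters are
#' stored alongside the data; regeneration from the same
#' `(config, seed)` is bit-exact.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; subject-level seeds derive from it.
#' @return A list of class `synthetic_cohort` with data frames
#'   `subjects` (group, LARS, apathy flag, true parameters) and
#'   `trials` (all sessions row-bound), plus `schedules`, `config` and
#'   `seed`.
#' @examples
#' \donttest{
#' coh <- sample_cohort(default_cohort_config(), seed = 1)
#' table(coh$subjects$group, coh$subjects$apathy_flag)
#' }
#' @export
sample_cohort <- function(config = default_cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- c(rep("hc", config$n_hc),
              rep("pd_no_apathy", config$n_pd_no_apathy),
              rep("pd_apathy", config$n_pd_apathy))
  n <- length(groups)
  schedules <- list(builtin_schedule(config$schedule))
  if (config$two_sessions) {
    other <- setdiff(c("session_out", "session_in"), config$schedule)
    schedules <- c(schedules, list(builtin_schedule(other)))
  }

  if (n == 0L) {
    subjects <- data.frame(subject = character(), group = character(),
                           lars = numeric(), apathy_flag = logical(),
                           alpha = numeric(), beta = numeric(),
                           phi = numeric(), rho = numeric(),
                           missed_rate = numeric(), seed = integer(),
                           stringsAsFactors = FALSE)
    trials <- simulate_agent(config$spec,
                             default_generating_params(config$spec),
                             schedules[[1]], seed = 1L)[0, ]
    return(structure(list(subjects = subjects, trials = trials,
                          schedules = schedules, config = config,
                          seed = as.integer(seed)),
                     class = "synthetic_cohort"))
  }

  sp <- config$param_spread
  subjects <- with_seed(seed, {
    alpha <- beta <- phi <- rho <- lars <- numeric(n)
    for (i in seq_len(n)) {
      gm <- config$group_means[[groups[i]]]
      alpha[i] <- truncate_range(stats::rnorm(1, gm$alpha, sp$alpha),
                                 0.02, 0.98)
      beta[i] <- max(stats::rnorm(1, gm$beta, sp$beta), 0.005)
      phi[i] <- max(stats::rnorm(1, gm$phi, sp$phi), 0)
      rho[i] <- stats::rnorm(1, gm$rho, sp$rho)
      # standardized beta+rho deficit drives the LARS score so that
      # lower reward sensitivity / perseveration means more apathy
      z <- ((beta[i] - gm$beta) / max(sp$beta, 1e-9) +
            (rho[i] - gm$rho) / max(sp$rho, 1e-9)) / sqrt(2)
      l <- config$lars_loading
      eps <- stats::rnorm(1)
      lars[i] <- config$lars_centers[[groups[i]]] +
        config$lars_sds[[groups[i]]] * (sqrt(1 - l^2) * eps - l * z)
    }
    lars <- truncate_range(lars, -36, 36)
    data.frame(
      subject = sprintf("S%03d", seq_len(n)),
      group = groups,
      lars = lars,
      apathy_flag = lars > config$apathy_cutoff,
      alpha = alpha, beta = beta, phi = phi, rho = rho,
      missed_rate = config$missed_rate,
      seed = vapply(seq_len(n), function(i) sub_seed(seed, i), integer(1)),
      stringsAsFactors = FALSE
    )
  })

  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(seq_along(schedules), function(s) {
      p <- model_params(beta = subjects$beta[i], alpha = subjects$alpha[i],
                        phi = subjects$phi[i], rho = subjects$rho[i])
      simulate_agent(config$spec, p, schedules[[s]],
                     seed = sub_seed(subjects$seed[i], s),
                     missed_rate = config$missed_rate,
                     subject = subjects$subject[i])
    }))
  }))
  rownames(trials) <- NULL

  structure(
    list(subjects = subjects, trials = trials, schedules = schedules,
         config = config, seed = as.integer(seed)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects (%s), %d trial rows, seed %d>\n",
              nrow(x$subjects),
              paste(sprintf("%s = %d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              nrow(x$trials), x$seed))
  invisible(x)
}

#' Write a cohort to delimited-text files
#'
#' Writes `trials.csv`, `subjects.csv` (group, LARS, true parameters),
#' `schedules.csv` (long format with a `schedule_id` column) and
#' `manifest.json` (config and seed). Byte-identical when regenerated
#' from the same cohort.
#'
#' @param cohort A [sample_cohort()] result.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of file paths (the manifest).
#' @export
cohort_to_files <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    trials = file.path(out_dir, "trials.csv"),
    subjects = file.path(out_dir, "subjects.csv"),
    schedules = file.path(out_dir, "schedules.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(cohort$trials, paths$trials, row.names = FALSE)
  utils::write.csv(cohort$subjects, paths$subjects, row.names = FALSE)
  sched_long <- do.call(rbind, lapply(cohort$schedules, function(s) {
    data.frame(
      schedule_id = s$instantiation_id,
      trial = rep(seq_len(s$n_trials), each = s$n_bandits),
      bandit = rep(seq_len(s$n_bandits), times = s$n_trials),
      mean = as.vector(s$means),
      payout = as.vector(s$payouts),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(sched_long, paths$schedules, row.names = FALSE)
  manifest <- list(
    seed = cohort$seed,
    n_subjects = nrow(cohort$subjects),
    files = lapply(paths[c("trials", "subjects", "schedules")], basename),
    config = serialize_cohort_config(cohort$config)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

serialize_cohort_config <- function(config) {
  out <- unclass(config)
  out$spec <- list(learning_rule = config$spec$learning_rule,
                   choice_rule = config$spec$choice_rule)
  out$lars_centers <- as.list(config$lars_centers)
  out$lars_sds <- as.list(config$lars_sds)
  out
}

#' Read a cohort back from [cohort_to_files()] output
#'
#' @param dir Directory containing `trials.csv`, `subjects.csv`,
#'   `schedules.csv` and `manifest.json`.
#' @return A list with `trials`, `subjects`, `schedules` (long data
#'   frame) and `manifest`.
#' @export
read_cohort_files <- function(dir) {
  list(
    trials = utils::read.csv(file.path(dir, "trials.csv")),
    subjects = utils::read.csv(file.path(dir, "subjects.csv")),
    schedules = utils::read.csv(file.path(dir, "schedules.csv")),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)
  )
}
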