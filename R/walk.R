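#' Parameters of the decaying Gaussian random-walk payout process
#'
#' The latent payout mean of each bandit follows a mean-reverting AR(1)
#' ("decaying Gaussian random walk"):
#' \deqn{\mu_{i,t+1} = \lambda \mu_{i,t} + (1 - \lambda)\theta + \nu_t,
#'   \quad \nu_t \sim N(0, \sigma_d^2)}
#' and the realized payout on each trial is
#' \eqn{\mathrm{round}(N(\mu_{i,t}, \sigma_o^2))}, clipped to
#' `[floor, ceiling]`. Defaults are the published Daw et al. (2006)
#' instantiation values on a 0-100 point scale.
#'
#' @param decay Decay \eqn{\lambda} of the walk, in (0, 1).
#' @param decay_center Decay centre \eqn{\theta} (points) the walk reverts to.
#' @param diffusion_sd Diffusion standard deviation \eqn{\sigma_d}
#'   (points), >= 0.
#' @param observation_sd Payout observation noise \eqn{\sigma_o}
#'   (points), >= 0.
#' @param floor,ceiling Clipping bounds for realized payouts (points).
#' @return An object of class `walk_params`.
#' @examples
#' wp <- walk_params()
#' stationary_variance(wp)
#' @export
walk_params <- function(decay = 0.9836, decay_center = 50,
                        diffusion_sd = 2.8, observation_sd = 4,
                        floor = 0, ceiling = 100) {
  if (!is.numeric(decay) || length(decay) != 1L || !is.finite(decay) ||
      decay <= 0 || decay >= 1) {
    stop_config("walk.decay", "must lie strictly in (0, 1)")
  }
  if (!is.numeric(decay_center) || length(decay_center) != 1L ||
      !is.finite(decay_center)) {
    stop_config("walk.decay_center", "must be a finite number")
  }
  if (!is.numeric(diffusion_sd) || length(diffusion_sd) != 1L ||
      !is.finite(diffusion_sd) || diffusion_sd < 0) {
    stop_config("walk.diffusion_sd", "must be >= 0")
  }
  if (!is.numeric(observation_sd) || length(observation_sd) != 1L ||
      !is.finite(observation_sd) || observation_sd < 0) {
    stop_config("walk.observation_sd", "must be >= 0")
  }
  if (!is.numeric(floor) || !is.numeric(ceiling) || floor >= ceiling) {
    stop_config("walk.floor", "floor must be strictly below ceiling")
  }
  structure(
    list(decay = decay, decay_center = decay_center,
         diffusion_sd = diffusion_sd, observation_sd = observation_sd,
         floor = floor, ceiling = ceiling),
    class = "walk_params"
  )
}

#' Stationary variance of the payout-mean walk
#'
#' The AR(1) walk has stationary distribution
#' \eqn{N(\theta, \sigma_d^2 / (1 - \lambda^2))}.
#'
#' @param walk A [walk_params()] object.
#' @return Stationary variance (points^2).
#' @export
stationary_variance <- function(walk) {
  stopifnot(inherits(walk, "walk_params"))
  walk$diffusion_sd^2 / (1 - walk$decay^2)
}

#' Generate a restless-bandit payout schedule
#'
#' Simulates the latent per-bandit payout means as independent decaying
#' Gaussian random walks and realizes integer payouts with observation
#' noise, clipped to the configured bounds. Regeneration with the same
#' `(walk, n_trials, n_bandits, seed, init)` is bit-exact.
#'
#' @param walk A [walk_params()] object.
#' @param n_trials Number of trials (>= 1); the task uses 300.
#' @param n_bandits Number of bandits (>= 2); the task uses 4.
#' @param seed Integer seed.
#' @param init `"stationary"` draws initial means from the walk's
#'   stationary distribution; `"fixed"` starts every mean at
#'   `decay_center`.
#' @param instantiation_id Optional label carried in the object and in
#'   exported files.
#' @return An object of class `bandit_schedule` with matrices `means`
#'   and `payouts` (`n_bandits` rows, `n_trials` columns; bandits are
#'   numbered 1-based everywhere).
#' @examples
#' sch <- generate_schedule(walk_params(), n_trials = 300, n_bandits = 4,
#'                          seed = 1)
#' range(sch$payouts)
#' @export
generate_schedule <- function(walk = walk_params(), n_trials = 300L,
                              n_bandits = 4L, seed = 1L,
                              init = c("stationary", "fixed"),
                              instantiation_id = NULL) {
  stopifnot(inherits(walk, "walk_params"))
  init <- match.arg(init)
  if (!is_count(n_trials) || n_trials < 1) {
    stop_config("schedule.n_trials", "must be an integer >= 1")
  }
  if (!is_count(n_bandits) || n_bandits < 2) {
    stop_config("schedule.n_bandits", "must be an integer >= 2")
  }
  n_trials <- as.integer(n_trials)
  n_bandits <- as.integer(n_bandits)

  out <- with_seed(seed, {
    means <- matrix(NA_real_, n_bandits, n_trials)
    mu <- if (init == "stationary") {
      stats::rnorm(n_bandits, walk$decay_center, sqrt(stationary_variance(walk)))
    } else {
      rep(walk$decay_center, n_bandits)
    }
    for (t in seq_len(n_trials)) {
      means[, t] <- mu
      mu <- walk$decay * mu + (1 - walk$decay) * walk$decay_center +
        stats::rnorm(n_bandits, 0, walk$diffusion_sd)
    }
    noise <- matrix(stats::rnorm(n_bandits * n_trials, 0, walk$observation_sd),
                    n_bandits, n_trials)
    payouts <- round(means + noise)
    payouts <- pmin(pmax(payouts, walk$floor), walk$ceiling)
    list(means = means, payouts = payouts)
  })

  structure(
    list(n_trials = n_trials, n_bandits = n_bandits,
         means = out$means, payouts = out$payouts,
         walk_params = walk, seed = as.integer(seed), init = init,
         instantiation_id = instantiation_id %||% sprintf("seed%d", seed)),
    class = "bandit_schedule"
  )
}

#' @export
print.bandit_schedule <- function(x, ...) {
  cat(sprintf("<bandit_schedule '%s': %d bandits x %d trials, seed %s>\n",
              x$instantiation_id, x$n_bandits, x$n_trials,
              ifelse(is.na(x$seed), "NA", x$seed)))
  cat(sprintf("  payouts in [%g, %g]; walk decay %.4f, centre %g\n",
              min(x$payouts), max(x$payouts),
              x$walk_params$decay, x$walk_params$decay_center))
  invisible(x)
}

#' Built-in canonical schedules
#'
#' Two fixed-seed schedule instantiations labelled `"session_out"` and
#' `"session_in"`, standing in for the two experimental-session payout
#' instantiations of the task (the originals are not published as
#' numbers, so these are synthetic canonical draws from the same walk).
#'
#' @param instantiation `"session_out"` or `"session_in"`.
#' @param walk Walk parameters.
#' @return A `bandit_schedule`.
#' @export
builtin_schedule <- function(instantiation = c("session_out", "session_in"),
                             walk = walk_params()) {
  instantiation <- match.arg(instantiation)
  seed <- c(session_out = 101L, session_in = 202L)[[instantiation]]
  generate_schedule(walk, n_trials = 300L, n_bandits = 4L, seed = seed,
                    instantiation_id = instantiation)
}

#' Look up a realized payout
#'
#' @param schedule A `bandit_schedule`.
#' @param bandit Bandit index (1-based).
#' @param trial Trial index (1-based).
#' @return The realized payout (points).
#' @export
payout_at <- function(schedule, bandit, trial) {
  stopifnot(inherits(schedule, "bandit_schedule"))
  if (!is_count(bandit) || bandit < 1 || bandit > schedule$n_bandits) {
    stop(sprintf("bandit index %s out of range [1, %d]",
                 format(bandit), schedule$n_bandits), call. = FALSE)
  }
  if (!is_count(trial) || trial < 1 || trial > schedule$n_trials) {
    stop(sprintf("trial index %s out of range [1, %d]",
                 format(trial), schedule$n_trials), call. = FALSE)
  }
  schedule$payouts[bandit, trial]
}

#' Validate a schedule and report violations
#'
#' Report-only: returns a data frame of violations (payouts out of
#' range, non-integer payouts, dimension mismatches) without raising.
#'
#' @param schedule A `bandit_schedule` (possibly hand-edited).
#' @return A data frame with columns `check` and `detail`; zero rows
#'   when the schedule is valid.
#' @export
validate_schedule <- function(schedule) {
  checks <- character()
  details <- character()
  add <- function(check, detail) {
    checks <<- c(checks, check)
    details <<- c(details, detail)
  }
  wp <- schedule$walk_params
  dims <- c(schedule$n_bandits, schedule$n_trials)
  if (!is.matrix(schedule$means) || !all(dim(schedule$means) == dims)) {
    add("dimension", sprintf("means is %s, expected %d x %d",
                             paste(dim(schedule$means), collapse = " x "),
                             dims[1], dims[2]))
  }
  if (!is.matrix(schedule$payouts) || !all(dim(schedule$payouts) == dims)) {
    add("dimension", sprintf("payouts is %s, expected %d x %d",
                             paste(dim(schedule$payouts), collapse = " x "),
                             dims[1], dims[2]))
  }
  if (is.matrix(schedule$payouts)) {
    bad <- which(schedule$payouts < wp$floor | schedule$payouts > wp$ceiling,
                 arr.ind = TRUE)
    if (nrow(bad)) {
      for (k in seq_len(nrow(bad))) {
        add("range", sprintf("payout %g at bandit %d, trial %d outside [%g, %g]",
                             schedule$payouts[bad[k, 1], bad[k, 2]],
                             bad[k, 1], bad[k, 2], wp$floor, wp$ceiling))
      }
    }
    nonint <- which(schedule$payouts != round(schedule$payouts), arr.ind = TRUE)
    if (nrow(nonint)) {
      for (k in seq_len(nrow(nonint))) {
        add("integer", sprintf("payout %g at bandit %d, trial %d is not an integer",
                               schedule$payouts[nonint[k, 1], nonint[k, 2]],
                               nonint[k, 1], nonint[k, 2]))
      }
    }
  }
  data.frame(check = checks, detail = details, stringsAsFactors = FALSE)
}

#' Write a schedule to a long-format CSV
#'
#' Columns `trial` (1-based), `bandit` (1-based), `mean`, `payout`,
#' with a mandatory header row.
#'
#' @param schedule A `bandit_schedule`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "bandit_schedule"))
  df <- data.frame(
    trial = rep(seq_len(schedule$n_trials), each = schedule$n_bandits),
    bandit = rep(seq_len(schedule$n_bandits), times = schedule$n_trials),
    mean = as.vector(schedule$means),
    payout = as.vector(schedule$payouts)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a schedule from a long-format CSV
#'
#' @param path CSV written by [write_schedule()].
#' @param walk Walk parameters to attach (the file does not carry them).
#' @param instantiation_id Label for the reconstructed schedule.
#' @return A `bandit_schedule` (with `seed = NA`: the generating seed is
#'   not stored in the file).
#' @export
read_schedule <- function(path, walk = walk_params(),
                          instantiation_id = basename(path)) {
  df <- utils::read.csv(path)
  need <- c("trial", "bandit", "mean", "payout")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("schedule file %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  n_trials <- max(df$trial)
  n_bandits <- max(df$bandit)
  means <- matrix(NA_real_, n_bandits, n_trials)
  payouts <- matrix(NA_real_, n_bandits, n_trials)
  means[cbind(df$bandit, df$trial)] <- df$mean
  payouts[cbind(df$bandit, df$trial)] <- df$payout
  structure(
    list(n_trials = as.integer(n_trials), n_bandits = as.integer(n_bandits),
         means = means, payouts = payouts, walk_params = walk,
         seed = NA_integer_, init = NA_character_,
         instantiation_id = instantiation_id),
    class = "bandit_schedule"
  )
}
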