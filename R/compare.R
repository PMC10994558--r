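#' Fit and rank several model variants on one session
#'
#' Fits each spec by [fit_map()] and tabulates log-likelihood,
#' parameter count, AIC and BIC, sorted by the configured criterion
#' (BIC by default). An individual fit failure is recorded in its row
#' (`status`), not fatal.
#'
#' @param session Session data frame.
#' @param specs List of at least two [model_spec()]s.
#' @param config A [fit_config()].
#' @param walk Walk parameters.
#' @param seed Seed passed to each fit.
#' @return A data frame (one row per spec, best first) with attribute
#'   `"fits"` holding the underlying `bandit_fit` objects.
#' @examples
#' sch <- builtin_schedule("session_out")
#' ses <- simulate_agent(model_spec("bayes", "SMP"),
#'                       model_params(beta = 0.12, rho = 3), sch, seed = 3)
#' compare_models(ses, list(model_spec("bayes", "SM"),
#'                          model_spec("bayes", "SMP")),
#'                config = fit_config(n_starts = 4))
#' @export
compare_models <- function(session, specs, config = fit_config(),
                           walk = walk_params(), seed = 1L) {
  if (!is.list(specs) || length(specs) < 2L) {
    stop("compare_models requires at least 2 model specs", call. = FALSE)
  }
  rows <- vector("list", length(specs))
  fits <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    fit <- tryCatch(
      fit_map(spec, session, config = config, walk = walk, seed = seed),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      rows[[i]] <- data.frame(
        model = spec_label(spec), learning_rule = spec$learning_rule,
        choice_rule = spec$choice_rule, k = length(active_params(spec)),
        log_lik = NA_real_, aic = NA_real_, bic = NA_real_,
        status = conditionMessage(fit), stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- fit
      rows[[i]] <- data.frame(
        model = spec_label(spec), learning_rule = spec$learning_rule,
        choice_rule = spec$choice_rule, k = length(active_params(spec)),
        log_lik = fit$log_lik, aic = fit$aic, bic = fit$bic,
        status = "ok", stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  names(fits) <- tab$model
  key <- switch(config$criterion,
                bic = tab$bic, aic = tab$aic, log_lik = -tab$log_lik)
  ord <- order(key, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "criterion") <- config$criterion
  tab
}

#' Posterior group contrast on one model parameter
#'
#' The contrast `M_diff` is the difference (group A minus group B) of
#' the group means of per-subject posterior-mean parameter estimates,
#' with a central 95% interval from a seeded bootstrap over subjects.
#'
#' @param fits_a,fits_b Lists of `bandit_fit` objects for the two
#'   groups.
#' @param parameter Parameter name, active in every fit.
#' @param seed Bootstrap seed.
#' @param n_boot Bootstrap resamples.
#' @return A list of class `group_contrast` with `m_diff`, `lower`,
#'   `upper`, group sizes and the per-subject values.
#' @export
group_contrast <- function(fits_a, fits_b, parameter, seed = 1L,
                           n_boot = 2000L) {
  extract <- function(fits) {
    vapply(fits, function(f) {
      if (!parameter %in% f$summaries$parameter) {
        stop(sprintf("parameter '%s' is not active in a %s fit", parameter,
                     spec_label(f$spec)), call. = FALSE)
      }
      f$summaries$mean[f$summaries$parameter == parameter]
    }, numeric(1))
  }
  va <- extract(fits_a)
  vb <- extract(fits_b)
  m_diff <- mean(va) - mean(vb)
  if (length(va) < 2L || length(vb) < 2L) {
    warning("group of size 1: degenerate bootstrap interval", call. = FALSE)
    lower <- upper <- m_diff
  } else {
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        mean(sample(va, replace = TRUE)) - mean(sample(vb, replace = TRUE))
      }, numeric(1))
    })
    lower <- stats::quantile(boots, 0.025, names = FALSE)
    upper <- stats::quantile(boots, 0.975, names = FALSE)
  }
  structure(
    list(parameter = parameter, m_diff = m_diff, lower = lower,
         upper = upper, n_a = length(va), n_b = length(vb),
         values_a = va, values_b = vb),
    class = "group_contrast"
  )
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast %s: M_diff = %.3f (%.3f, %.3f); n = %d vs %d>\n",
              x$parameter, x$m_diff, x$lower, x$upper, x$n_a, x$n_b))
  invisible(x)
}
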