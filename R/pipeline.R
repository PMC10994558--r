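# Known configuration schema: block -> allowed field names.
config_schema <- list(
  seed = NULL,
  walk = c("decay", "decay_center", "diffusion_sd", "observation_sd",
           "floor", "ceiling", "seed"),
  model = c("learning_rule", "choice_rule", "bonus_on"),
  params = c("alpha", "beta", "phi", "rho"),
  fitting = c("prior", "n_starts", "criterion", "maxit",
              "allow_negative_phi", "prior_scale_beta", "prior_scale_phi",
              "prior_scale_rho", "laplace_draws"),
  cohort = c("n_hc", "n_pd_no_apathy", "n_pd_apathy", "missed_rate",
             "lars_loading", "schedule", "two_sessions", "apathy_cutoff"),
  recovery = c("n_rows", "missed_rate")
)

#' Read and validate a pipeline configuration
#'
#' Accepts a JSON file path or an already-parsed nested list with
#' blocks `seed`, `walk`, `model`, `params`, `fitting`, `cohort` and
#' `recovery`. Unknown blocks or fields are rejected with the offending
#' field path; value validation happens in the constructors the blocks
#' feed ([walk_params()], [model_spec()], ...), whose errors carry the
#' same dotted field names.
#'
#' @param config Path to a JSON file, a list, or `NULL` (all defaults).
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(config = NULL) {
  if (is.null(config)) return(list())
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop("config must be a JSON file path or a nested list", call. = FALSE)
  }
  unknown_blocks <- setdiff(names(config), names(config_schema))
  if (length(unknown_blocks)) {
    stop(sprintf("unknown config field: %s", unknown_blocks[1]),
         call. = FALSE)
  }
  for (blk in names(config)) {
    allowed <- config_schema[[blk]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[blk]]), allowed)
    if (length(bad)) {
      stop(sprintf("unknown config field: %s.%s", blk, bad[1]),
           call. = FALSE)
    }
  }
  config
}

config_walk <- function(config) {
  w <- config$walk
  do.call(walk_params, w[setdiff(names(w), "seed")] %||% list())
}

config_model_spec <- function(config) {
  m <- config$model
  model_spec(m$learning_rule %||% "bayes", m$choice_rule %||% "SMEP")
}

config_fit <- function(config) {
  do.call(fit_config, c(config$fitting %||% list(),
                        list(bonus_on = config$model$bonus_on %||% "sd")))
}

write_resolved_config <- function(config, out_dir) {
  path <- file.path(out_dir, "resolved_config.json")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  path
}

#' Pipeline stage: simulate a synthetic cohort to files
#'
#' Builds a [cohort_config()] from the `cohort`/`walk`/`model` blocks,
#' samples the cohort and writes it with [cohort_to_files()], plus a
#' resolved-config copy next to the outputs. Deterministic under fixed
#' `(config, seed)`.
#'
#' @param config Configuration (path, list or `NULL`), see
#'   [read_pipeline_config()].
#' @param out_dir Output directory.
#' @param seed Seed; overrides `config$seed`.
#' @return Invisibly, the file manifest.
#' @export
run_simulate <- function(config = NULL, out_dir, seed = NULL) {
  config <- read_pipeline_config(config)
  config_walk(config)  # validates the walk block before any work
  seed <- seed %||% config$seed %||% 1L
  cc_args <- config$cohort %||% list()
  cc_args$spec <- config_model_spec(config)
  cc <- do.call(cohort_config, cc_args)
  cohort <- sample_cohort(cc, seed = seed)
  manifest <- cohort_to_files(cohort, out_dir)
  config$seed <- seed
  write_resolved_config(config, out_dir)
  invisible(manifest)
}

read_trials <- function(trials) {
  if (is.character(trials)) trials <- utils::read.csv(trials)
  need <- c("subject", "trial", "choice", "outcome", "missed")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop(sprintf("trials table is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  trials
}

#' Pipeline stage: fit model variant(s) per subject
#'
#' Fits the configured model variant to every subject in a trials
#' table by [fit_map()] and writes `fits.csv` (one row per subject) and
#' `fits.json` (full summaries). When `specs` lists more than one
#' variant, a per-subject model-comparison table (`comparison.csv`) is
#' written too and the configured variant's rows are reported.
#'
#' @param trials Trials CSV path or data frame (columns as written by
#'   [cohort_to_files()]).
#' @param config Configuration (path, list or `NULL`).
#' @param out_dir Optional output directory.
#' @param seed Seed.
#' @param specs Optional list of `model_spec`s to compare; default is
#'   the single configured variant.
#' @return A list with `fits` (data frame), `fit_objects`, and
#'   `comparison` (or `NULL`).
#' @export
run_fit <- function(trials, config = NULL, out_dir = NULL, seed = 1L,
                    specs = NULL) {
  config <- read_pipeline_config(config)
  trials <- read_trials(trials)
  walk <- config_walk(config)
  fc <- config_fit(config)
  spec <- config_model_spec(config)
  subjects <- unique(trials$subject)

  rows <- vector("list", length(subjects))
  objs <- vector("list", length(subjects))
  comparisons <- list()
  for (i in seq_along(subjects)) {
    ses <- trials[trials$subject == subjects[i], , drop = FALSE]
    if (!is.null(specs)) {
      tab <- compare_models(ses, specs, config = fc, walk = walk,
                            seed = sub_seed(seed, i))
      comparisons[[i]] <- cbind(subject = subjects[i], tab)
      fit <- attr(tab, "fits")[[spec_label(spec)]]
      if (is.null(fit)) {
        fit <- fit_map(spec, ses, config = fc, walk = walk,
                       seed = sub_seed(seed, i))
      }
    } else {
      fit <- fit_map(spec, ses, config = fc, walk = walk,
                     seed = sub_seed(seed, i))
    }
    objs[[i]] <- fit
    est <- fit$estimates
    rows[[i]] <- data.frame(
      subject = subjects[i], model = spec_label(spec),
      n_valid = fit$n_valid_trials,
      alpha = est$alpha, beta = est$beta, phi = est$phi, rho = est$rho,
      log_lik = fit$log_lik, aic = fit$aic, bic = fit$bic,
      stringsAsFactors = FALSE
    )
  }
  fits <- do.call(rbind, rows)
  names(objs) <- subjects
  comparison <- if (length(comparisons)) {
    do.call(rbind, comparisons)
  } else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(objs, function(f) list(
        spec = spec_label(f$spec), estimates = unclass(f$estimates),
        summaries = f$summaries, log_lik = f$log_lik,
        n_valid_trials = f$n_valid_trials, aic = f$aic, bic = f$bic)),
      file.path(out_dir, "fits.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    if (!is.null(comparison)) {
      utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                       row.names = FALSE)
    }
    write_resolved_config(config, out_dir)
  }
  list(fits = fits, fit_objects = objs, comparison = comparison)
}

#' Pipeline stage: classify choices and summarize behaviour
#'
#' Labels every trial of every subject (using that subject's fitted
#' parameters when a fits table is given, else the `params` block),
#' writes the labelled trials (`choice_type` column), per-subject and
#' per-block behavioural summaries, and — when a subjects table with a
#' `lars` column is supplied — Spearman correlations of the headline
#' metrics with the apathy score.
#'
#' @param trials Trials CSV path or data frame.
#' @param fits Optional fits CSV path or data frame from [run_fit()];
#'   must cover every subject in `trials`.
#' @param config Configuration (path, list or `NULL`).
#' @param out_dir Optional output directory.
#' @param subjects Optional subjects CSV path or data frame with
#'   `subject` and `lars` columns.
#' @param schedule Schedule the sessions were played on; defaults to
#'   the built-in schedule named by the config.
#' @return A list with `labelled` (trials + `choice_type`),
#'   `summaries` (per subject), `per_block`, and `correlations`
#'   (or `NULL`).
#' @export
run_classify <- function(trials, fits = NULL, config = NULL,
                         out_dir = NULL, subjects = NULL,
                         schedule = NULL) {
  config <- read_pipeline_config(config)
  trials <- read_trials(trials)
  walk <- config_walk(config)
  spec <- config_model_spec(config)
  schedule <- schedule %||%
    builtin_schedule(config$cohort$schedule %||% "session_out", walk)
  subj_ids <- unique(trials$subject)

  if (!is.null(fits)) {
    if (is.character(fits)) fits <- utils::read.csv(fits)
    orphans <- setdiff(subj_ids, fits$subject)
    if (length(orphans)) {
      stop(sprintf("fits do not cover subject(s): %s",
                   paste(orphans, collapse = ", ")), call. = FALSE)
    }
  }
  default_params <- config$params %||%
    list(alpha = 0.4, beta = 0.10, phi = 0.8, rho = 4.0)

  labelled <- list()
  summaries <- list()
  per_block <- list()
  for (i in seq_along(subj_ids)) {
    ses <- trials[trials$subject == subj_ids[i], , drop = FALSE]
    p <- if (!is.null(fits)) {
      row <- fits[fits$subject == subj_ids[i], , drop = FALSE][1, ]
      list(alpha = row$alpha, beta = row$beta, phi = row$phi, rho = row$rho)
    } else {
      default_params
    }
    labels <- classify_session(ses, spec, p, walk = walk)
    ses$choice_type <- labels
    labelled[[i]] <- ses
    bs <- behavioural_summary(ses, labels, schedule)
    summaries[[i]] <- cbind(subject = subj_ids[i], bs$overall)
    per_block[[i]] <- cbind(subject = subj_ids[i], bs$per_block)
  }
  labelled <- do.call(rbind, labelled)
  summaries <- do.call(rbind, summaries)
  per_block <- do.call(rbind, per_block)

  correlations <- NULL
  if (!is.null(subjects)) {
    if (is.character(subjects)) subjects <- utils::read.csv(subjects)
    if ("lars" %in% names(subjects) && nrow(summaries) >= 3) {
      m <- merge(summaries, subjects[, c("subject", "lars")], by = "subject")
      correlations <- do.call(rbind, lapply(
        c("p_best", "points_mean", "p_exploit", "p_random", "p_stay"),
        function(metric) {
          ct <- correlate_with_score(m[[metric]], m$lars)
          data.frame(metric = metric, rho = ct$rho, p = ct$p, n = ct$n,
                     stringsAsFactors = FALSE)
        }))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(labelled, file.path(out_dir, "trials_labelled.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(out_dir, "summary_subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(per_block, file.path(out_dir, "summary_blocks.csv"),
                     row.names = FALSE)
    if (!is.null(correlations)) {
      utils::write.csv(correlations,
                       file.path(out_dir, "score_correlations.csv"),
                       row.names = FALSE)
    }
    write_resolved_config(config, out_dir)
  }
  list(labelled = labelled, summaries = summaries, per_block = per_block,
       correlations = correlations)
}

#' Pipeline stage: parameter-recovery run
#'
#' Draws a dispersed true-parameter table for the configured variant,
#' runs [recover_parameters()] at the configured scale and writes the
#' report (`recovery_table.csv`, `recovery_metrics.csv`,
#' `recovery.json`).
#'
#' @param config Configuration (path, list or `NULL`); `recovery.n_rows`
#'   sets the number of synthetic agents (default 10).
#' @param out_dir Optional output directory.
#' @param seed Seed.
#' @return The `recovery_report`, invisibly.
#' @export
run_recover <- function(config = NULL, out_dir = NULL, seed = 1L) {
  config <- read_pipeline_config(config)
  walk <- config_walk(config)
  spec <- config_model_spec(config)
  fc <- config_fit(config)
  n_rows <- config$recovery$n_rows %||% 10L
  missed_rate <- config$recovery$missed_rate %||% 0
  schedule <- builtin_schedule(config$cohort$schedule %||% "session_out",
                               walk)
  tp <- draw_dispersed_params(spec, n_rows, seed = seed)
  rep <- recover_parameters(spec, tp, schedule, config = fc, seed = seed,
                            missed_rate = missed_rate)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rep$table, file.path(out_dir, "recovery_table.csv"),
                     row.names = FALSE)
    utils::write.csv(rep$metrics, file.path(out_dir, "recovery_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(spec = spec_label(spec), seed = seed, n_rows = n_rows,
           metrics = rep$metrics),
      file.path(out_dir, "recovery.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write_resolved_config(config, out_dir)
  }
  invisible(rep)
}
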