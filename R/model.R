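#' Specify a learning rule x choice rule model variant
#'
#' Eight model variants are formed by crossing two learning rules with
#' four softmax choice rules:
#' * learning: `"delta"` (constant learning rate \eqn{\alpha}) or
#'   `"bayes"` (Kalman-filter learner tracking a mean and variance per
#'   bandit);
#' * choice: `"SM"` (softmax), `"SME"` (+ exploration bonus
#'   \eqn{\phi}), `"SMP"` (+ perseveration bonus \eqn{\rho}), `"SMEP"`
#'   (both bonuses).
#'
#' For `bayes` variants the exploration bonus multiplies the learner's
#' posterior uncertainty (SD by default); for `delta` variants, which
#' track no variance, it multiplies the recency count (trials since the
#' bandit was last chosen).
#'
#' @param learning_rule `"delta"` or `"bayes"`.
#' @param choice_rule `"SM"`, `"SME"`, `"SMP"` or `"SMEP"`.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("bayes", "SMEP")
#' @export
model_spec <- function(learning_rule = c("bayes", "delta"),
                       choice_rule = c("SMEP", "SM", "SME", "SMP")) {
  learning_rule <- match.arg(learning_rule)
  choice_rule <- match.arg(choice_rule)
  structure(
    list(learning_rule = learning_rule, choice_rule = choice_rule,
         uses_explore = choice_rule %in% c("SME", "SMEP"),
         uses_persev = choice_rule %in% c("SMP", "SMEP")),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s>\n", spec_label(x)))
  invisible(x)
}

#' Label a model spec as e.g. "bayes+SMEP"
#' @param spec A `model_spec`.
#' @return Character label.
#' @export
spec_label <- function(spec) {
  paste0(spec$learning_rule, "+", spec$choice_rule)
}

#' All eight model variants
#' @return List of eight `model_spec` objects, delta rules first.
#' @export
all_model_specs <- function() {
  out <- list()
  for (lr in c("delta", "bayes")) {
    for (cr in c("SM", "SME", "SMP", "SMEP")) {
      out[[paste0(lr, "+", cr)]] <- model_spec(lr, cr)
    }
  }
  out
}

#' Names of the free parameters of a model variant
#'
#' \eqn{\alpha} (delta only), \eqn{\beta} (always), \eqn{\phi}
#' (SME/SMEP), \eqn{\rho} (SMP/SMEP).
#'
#' @param spec A `model_spec`.
#' @return Character vector of parameter names among
#'   `c("alpha", "beta", "phi", "rho")`.
#' @export
active_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  out <- character()
  if (spec$learning_rule == "delta") out <- c(out, "alpha")
  out <- c(out, "beta")
  if (spec$uses_explore) out <- c(out, "phi")
  if (spec$uses_persev) out <- c(out, "rho")
  out
}

#' Construct a validated parameter set for a model variant
#'
#' @param beta Inverse temperature / reward sensitivity (1/points), >= 0.
#' @param alpha Learning rate in (0, 1); delta-rule variants only.
#' @param phi Exploration bonus weight (points per uncertainty unit);
#'   SME/SMEP only. Negative values (uncertainty aversion) allowed when
#'   `allow_negative_phi`.
#' @param rho Perseveration bonus (softmax-logit units); SMP/SMEP only.
#' @param spec Optional `model_spec`; when supplied, parameters outside
#'   the variant's active set must be `NA` and active ones must be set.
#' @param allow_negative_phi Permit `phi < 0`.
#' @return A named list of class `model_params`.
#' @examples
#' model_params(beta = 0.1, phi = 0.8, rho = 4,
#'              spec = model_spec("bayes", "SMEP"))
#' @export
model_params <- function(beta, alpha = NA_real_, phi = NA_real_,
                         rho = NA_real_, spec = NULL,
                         allow_negative_phi = FALSE) {
  p <- list(alpha = as.numeric(alpha), beta = as.numeric(beta),
            phi = as.numeric(phi), rho = as.numeric(rho))
  if (!is.na(p$beta) && p$beta < 0) {
    stop("params.beta: must be >= 0", call. = FALSE)
  }
  if (!is.na(p$alpha) && (p$alpha <= 0 || p$alpha >= 1)) {
    stop("params.alpha: must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.na(p$phi) && !allow_negative_phi && p$phi < 0) {
    stop("params.phi: must be >= 0 (set allow_negative_phi to permit)",
         call. = FALSE)
  }
  if (!is.null(spec)) {
    act <- active_params(spec)
    for (nm in c("alpha", "beta", "phi", "rho")) {
      if (nm %in% act && is.na(p[[nm]])) {
        stop(sprintf("params.%s: required by %s but not set", nm,
                     spec_label(spec)), call. = FALSE)
      }
      if (!(nm %in% act) && !is.na(p[[nm]])) {
        stop(sprintf("params.%s: not a parameter of %s", nm,
                     spec_label(spec)), call. = FALSE)
      }
    }
  }
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  act <- !vapply(x, is.na, logical(1))
  cat("<model_params ",
      paste(sprintf("%s = %g", names(x)[act], unlist(x)[act]),
            collapse = ", "), ">\n", sep = "")
  invisible(x)
}

# Fill inactive parameters with the neutral value 0 for the numeric
# kernel (alpha unused by bayes, phi/rho absent from the logit).
params_for_kernel <- function(params, spec) {
  p <- lapply(params[c("alpha", "beta", "phi", "rho")], function(v) {
    if (is.null(v) || is.na(v)) 0 else v
  })
  if (spec$learning_rule == "delta" && (p$alpha <= 0 || p$alpha >= 1)) {
    stop("params.alpha: must lie strictly in (0, 1) for delta-rule variants",
         call. = FALSE)
  }
  p
}
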