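# Model inversion: maximize the log-joint (response log-likelihood summed
# over trials plus a Gaussian prior in transformed parameter space) with
# multi-restart CMA-ES, then Laplace-approximate the log model evidence from
# the numerically estimated Hessian at the mode.

#' Prior over transformed parameters
#'
#' An isotropic Gaussian `N(chi; eta0, s_o I)` in the unconstrained space.
#' The default zero mean corresponds on the native scale to `eps = 0.25`,
#' `tau = 0.75`, positive parameters at 1 and initial means at 0; `s_o = 2`
#' gives a moderately wide prior that keeps the Laplace approximation
#' well-behaved.
#'
#' @param model A [wcst_model()].
#' @param eta0 Prior mean (scalar recycled, or vector of the model's
#'   parameter dimension).
#' @param s_o Shared prior variance.
#' @return List of class `wcst_prior` with `eta0`, `s_o` and the parameter
#'   names.
#' @export
prior_spec <- function(model, eta0 = 0, s_o = 2) {
  info <- model_parameters(model)
  d <- nrow(info)
  eta0 <- rep_len(eta0, d)
  structure(list(eta0 = stats::setNames(eta0, info$name), s_o = s_o,
                 names = info$name),
            class = "wcst_prior")
}

#' Optimizer configuration for model fitting
#'
#' @param n_restarts Number of independent CMA-ES restarts per fit
#'   (study setting: 50; smaller values are used for desk-scale work).
#' @param sigma0 Initial step size in transformed space.
#' @param max_eval Evaluation budget of the global search phase per restart.
#' @param refine_eval Extra budget for a two-stage local CMA-ES refinement
#'   (step sizes `sigma0 / 5` then `sigma0 / 25`, half the budget each)
#'   started from each restart's best point; sharpens the mode for the
#'   Laplace step. Default `max_eval / 4`.
#' @param popsize Population size (default `4 + floor(3 log n)`).
#' @param hessian_r Richardson iterations for the per-restart Hessian
#'   (passed to \pkg{numDeriv}); the default 2 is accurate well beyond what
#'   the evidence term `log |2 pi S|` resolves, at half the cost of the
#'   package default 4.
#' @param seed Optional integer seed making the whole fit deterministic.
#' @return List of class `wcst_optim_config`.
#' @export
optimizer_config <- function(n_restarts = 50L, sigma0 = 0.5,
                             max_eval = 2e4, refine_eval = NULL,
                             popsize = NULL, hessian_r = 2L, seed = NULL) {
  stopifnot(n_restarts >= 1, hessian_r >= 1)
  if (is.null(refine_eval)) refine_eval <- ceiling(max_eval / 4)
  structure(list(n_restarts = as.integer(n_restarts), sigma0 = sigma0,
                 max_eval = max_eval, refine_eval = refine_eval,
                 popsize = popsize, hessian_r = as.integer(hessian_r),
                 seed = seed),
            class = "wcst_optim_config")
}

# slot of each named parameter in the positional C++ vector
#' @keywords internal
.param_slot <- c(
  eps = 1L, eps_nb = 2L, alpha = 3L, tau_e = 4L, tau_f = 5L, kappa_e = 6L,
  kappa_f = 7L, q_e = 8L, q_f = 9L, w_dist = 10L, mu_e0 = 11L, mu_f0 = 12L,
  sigma_e0 = 13L, sigma_f0 = 14L, theta1 = 15L, theta2 = 16L, theta3 = 17L,
  mu_f0_1 = 18L, mu_f0_2 = 19L, mu_f0_3 = 20L
)

# cached chi -> positional parameter vector mapping for one model; avoids
# rebuilding the parameter table on every objective evaluation
#' @keywords internal
.make_chi2par <- function(model) {
  info <- model_parameters(model)
  base <- .cpp_param_vector(complete_parameters(list(), model), model)
  slots <- .param_slot[info$name]
  i_log <- which(info$transform == "log")
  i_eps <- which(info$transform == "eps")
  i_tau <- which(info$transform == "tau")
  function(chi) {
    x <- chi
    x[i_log] <- exp(chi[i_log])
    x[i_eps] <- stats::plogis(chi[i_eps]) / 2
    e2 <- 2 * exp(chi[i_tau])
    x[i_tau] <- (e2 + 1) / (e2 + 2)
    v <- base
    v[slots] <- x
    v
  }
}

# positional parameter vector + flags consumed by block_loglik_cpp
#' @keywords internal
.cpp_param_vector <- function(p, model) {
  c(p$eps, p$eps_nb, p$alpha, p$tau_e, p$tau_f, p$kappa_e, p$kappa_f,
    p$q_e, p$q_f, p$w_dist, p$mu_e0, p$mu_f0, p$sigma_e0, p$sigma_f0,
    p$theta1, p$theta2, p$theta3, p$mu_f0_1, p$mu_f0_2, p$mu_f0_3)
}

#' @keywords internal
.cpp_flags <- function(model) {
  as.integer(c(model$bayesian, model$reduced,
               model$response == "full", model$baseline,
               model$d_topdown,
               identical(model$structure, "d")))
}

# split a trial tibble into per-block groups (filter state resets per block)
#' @keywords internal
.split_blocks <- function(trials) {
  key_cols <- intersect(c("subject", "condition", "block"), names(trials))
  if (length(key_cols) == 0) return(list(trials))
  split(trials, interaction(trials[key_cols], drop = TRUE, lex.order = TRUE))
}

#' Log-joint of parameters and responses
#'
#' `l(chi) = sum_k log p(r_k | b_k(chi)) + log N(chi; eta0, s_o I)`, the
#' quantity maximized during inversion. Responses are clamped to the simplex
#' interior before evaluation. If `trials` spans several blocks the belief
#' filter restarts at each block and the per-trial terms are summed across
#' blocks under the single shared prior.
#'
#' @param chi Transformed parameter vector (canonical order of
#'   [model_parameters()]).
#' @param trials Trial tibble with observation and response columns.
#' @param model A [wcst_model()].
#' @param prior A [prior_spec()].
#' @param engine `"cpp"` (default, fused filter + likelihood) or `"r"`
#'   (reference path composing [run_filter()] and [response_loglik()]).
#' @param floor_at Response clamp floor.
#' @return Scalar log-joint; `-Inf` when the likelihood is not finite.
#' @export
log_joint <- function(chi, trials, model, prior = prior_spec(model),
                      engine = c("cpp", "r"), floor_at = 1e-3) {
  engine <- match.arg(engine)
  if (engine == "r") {
    lp <- sum(stats::dnorm(chi, prior$eta0, sqrt(prior$s_o), log = TRUE))
    params <- from_unconstrained(chi, model)
    ll <- 0
    for (b in .split_blocks(trials)) {
      if (nrow(b) == 0) next
      ll <- ll + block_response_loglik_r(b, model, params, floor_at)
      if (!is.finite(ll)) return(-Inf)
    }
    return(ll + lp)
  }
  .log_joint_fast(chi, .block_data(trials, floor_at), model, prior)
}

# precompute per-block observation/response summaries reused across
# thousands of objective evaluations within one fit
#' @keywords internal
.block_data <- function(trials, floor_at = 1e-3) {
  lapply(.split_blocks(trials), function(b) {
    r_mat <- clamp_response(block_r_matrix(b), floor_at)
    lr <- log(r_mat)
    list(
      e = block_e_matrix(b),
      clr_r = lr - rowMeans(lr),
      const_term = -nrow(b) * log(3) - sum(lr)
    )
  })
}

#' @keywords internal
.log_joint_fast <- function(chi, block_data, model, prior,
                            chi2par = .make_chi2par(model),
                            flags = .cpp_flags(model)) {
  lp <- sum(stats::dnorm(chi, prior$eta0, sqrt(prior$s_o), log = TRUE))
  par_vec <- chi2par(chi)
  ll <- 0
  for (bd in block_data) {
    ll <- ll + block_loglik_cpp(bd$e, bd$clr_r, bd$const_term, par_vec, flags)
    if (!is.finite(ll)) return(-Inf)
  }
  ll + lp
}

#' Find the mode of an objective by multi-restart CMA-ES
#'
#' Runs [cma_es()] `n_restarts` times from starting points dispersed around
#' the prior mean (at half the prior scale; see Details in the package
#' vignette) and returns all restart solutions.
#'
#' @param objective Function of a real vector, to be maximized.
#' @param dimension Problem dimension.
#' @param config An [optimizer_config()].
#' @param prior Optional [prior_spec()] supplying start dispersion; defaults
#'   to standard normal starts.
#' @return List with `par` (best mode), `value` (objective at mode) and
#'   `restarts` (tibble of per-restart results).
#' @export
find_mode <- function(objective, dimension, config = optimizer_config(),
                      prior = NULL) {
  if (!is.null(config$seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed)
  }
  eta0 <- if (is.null(prior)) rep(0, dimension) else prior$eta0
  # restarts are dispersed at half the prior scale around the prior mean:
  # the CMA-ES initial step covers the remaining prior width, and starts in
  # the far prior tails routinely land outside the numerically stable
  # region of the belief filter
  s_sd <- if (is.null(prior)) 0.5 else sqrt(prior$s_o) / 2
  refine <- if (is.null(config$refine_eval)) 0 else config$refine_eval
  runs <- purrr::map(seq_len(config$n_restarts), function(i) {
    x0 <- stats::rnorm(dimension, eta0, s_sd)
    res <- cma_es(function(x) -objective(x), x0,
                  sigma0 = config$sigma0, max_eval = config$max_eval,
                  popsize = config$popsize)
    # two-stage local refinement sharpens the mode for the Laplace step
    for (shrink in c(5, 25)) {
      if (refine > 0 && all(is.finite(res$par))) {
        res2 <- cma_es(function(x) -objective(x), res$par,
                       sigma0 = config$sigma0 / shrink,
                       max_eval = ceiling(refine / 2))
        if (res2$value < res$value) {
          res$par <- res2$par
          res$value <- res2$value
        }
        res$counteval <- res$counteval + res2$counteval
      }
    }
    list(par = res$par, value = -res$value, counteval = res$counteval,
         convergence = res$convergence)
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- which.max(vals)
  list(
    par = runs[[best]]$par,
    value = vals[best],
    restarts = tibble::tibble(
      restart = seq_along(runs),
      value = vals,
      counteval = vapply(runs, `[[`, numeric(1), "counteval"),
      convergence = vapply(runs, `[[`, character(1), "convergence"),
      par = purrr::map(runs, "par")
    )
  )
}

#' Numerical Hessian
#'
#' Richardson-extrapolated central-difference Hessian (via
#' \pkg{numDeriv}); symmetrized.
#'
#' @param f Scalar function.
#' @param x Evaluation point.
#' @param r Number of Richardson iterations (default 4, the \pkg{numDeriv}
#'   default).
#' @return Symmetric matrix of second partial derivatives.
#' @export
numerical_hessian <- function(f, x, r = 4L) {
  H <- numDeriv::hessian(f, x, method.args = list(r = r))
  (H + t(H)) / 2
}

#' Laplace approximation to the log model evidence
#'
#' `log p(r | e) ~ l(beta) + 1/2 log |2 pi S|` with `S` the negative inverse
#' Hessian of the log-joint at its mode. Eigenvalues of `-H` below the
#' curvature floor are raised to it and the result is flagged.
#'
#' @param log_joint_at_mode Value `l(beta)` of the log-joint at the mode.
#' @param hessian Hessian matrix of the log-joint at the mode.
#' @param prior_var Optional prior variance `s_o`. When supplied, the
#'   eigenvalues of `-H` are floored at the prior precision `1 / s_o`: the
#'   log-joint contains the Gaussian prior, so its true curvature cannot be
#'   flatter than the prior's, and flatter numerical estimates (flat ridges,
#'   derivative noise on rough likelihood surfaces) would otherwise inflate
#'   the evidence by several nats per direction. Without it only positive
#'   definiteness is enforced (floor `1e-8`).
#' @return List with `log_evidence`, posterior covariance `S`, and
#'   `regularized` flag (`TRUE` when any eigenvalue was floored).
#' @export
laplace_log_evidence <- function(log_joint_at_mode, hessian,
                                 prior_var = NULL) {
  H <- (hessian + t(hessian)) / 2
  eig <- eigen(-H, symmetric = TRUE)
  floor_at <- if (is.null(prior_var)) 1e-8 else 1 / prior_var
  regularized <- min(eig$values) < floor_at
  lam <- pmax(eig$values, floor_at)
  S <- eig$vectors %*% ((1 / lam) * t(eig$vectors))
  S <- (S + t(S)) / 2
  d <- nrow(S)
  list(
    log_evidence = log_joint_at_mode +
      0.5 * (d * log(2 * pi) - sum(log(lam))),
    S = S,
    regularized = regularized
  )
}

#' Fit one model to behavioral data
#'
#' Maximizes the log-joint over transformed parameters with `n_restarts`
#' CMA-ES runs from prior-dispersed starts; for each restart solution the
#' Hessian is estimated numerically and the Laplace log-evidence computed,
#' and the solution with the largest evidence is kept.
#'
#' @param trials Trial tibble (one block, or several blocks fitted jointly
#'   with the filter restarting at block boundaries).
#' @param model A [wcst_model()].
#' @param prior A [prior_spec()].
#' @param config An [optimizer_config()].
#' @param floor_at Response clamp floor.
#' @return Object of class `wcst_fit`: `chi_mode`, `params` (native scale),
#'   `S`, `log_joint`, `log_evidence`, `regularized`, `restarts` tibble,
#'   `model`, `prior`, `config`, `n_trials`.
#' @export
fit_block <- function(trials, model, prior = prior_spec(model),
                      config = optimizer_config(), floor_at = 1e-3) {
  info <- model_parameters(model)
  d <- nrow(info)
  bd <- .block_data(trials, floor_at)
  chi2par <- .make_chi2par(model)
  flags <- .cpp_flags(model)
  obj <- function(chi) .log_joint_fast(chi, bd, model, prior, chi2par, flags)
  mode_res <- find_mode(obj, d, config, prior)
  hess_r <- if (is.null(config$hessian_r)) 2L else config$hessian_r
  per_restart <- purrr::map(mode_res$restarts$par, function(beta) {
    l_beta <- obj(beta)
    H <- numerical_hessian(obj, beta, r = hess_r)
    lap <- laplace_log_evidence(l_beta, H, prior_var = prior$s_o)
    list(log_joint = l_beta, log_evidence = lap$log_evidence,
         S = lap$S, regularized = lap$regularized)
  })
  lev <- vapply(per_restart, `[[`, numeric(1), "log_evidence")
  best <- which.max(lev)
  beta <- mode_res$restarts$par[[best]]
  names(beta) <- info$name
  structure(
    list(
      model = model,
      chi_mode = beta,
      params = from_unconstrained(beta, model),
      S = per_restart[[best]]$S,
      log_joint = per_restart[[best]]$log_joint,
      log_evidence = lev[best],
      regularized = per_restart[[best]]$regularized,
      restarts = dplyr::mutate(
        mode_res$restarts,
        log_evidence = lev,
        regularized = vapply(per_restart, `[[`, logical(1), "regularized")
      ),
      prior = prior, config = config, n_trials = nrow(trials)
    ),
    class = "wcst_fit"
  )
}

#' @export
print.wcst_fit <- function(x, ...) {
  cat("<wcst_fit>", x$model$id, "-", length(x$chi_mode), "parameters,",
      x$n_trials, "trials\n")
  cat("  log-evidence:", format(x$log_evidence, digits = 6),
      " log-joint:", format(x$log_joint, digits = 6), "\n")
  invisible(x)
}

#' Fit a set of models across subjects and blocks
#'
#' Convenience wrapper running [fit_block()] for every
#' (subject, condition, block) group and every model, returning a tidy
#' evidence table.
#'
#' @param data Trial tibble for one or more subjects.
#' @param models List of [wcst_model()] objects (default: full roster).
#' @param config An [optimizer_config()].
#' @param joint_blocks If `TRUE`, fit all of a subject's blocks within a
#'   condition jointly (single parameter vector); otherwise fit each block
#'   separately as in the study design.
#' @param floor_at Response clamp floor.
#' @return Tibble with `subject`, `condition`, `block` (absent if
#'   `joint_blocks`), `model`, `log_evidence`, `log_joint`, `regularized`
#'   and a `fit` list-column.
#' @export
fit_models <- function(data, models = wcst_models(),
                       config = optimizer_config(),
                       joint_blocks = FALSE, floor_at = 1e-3) {
  if (inherits(models, "wcst_model")) models <- list(models)
  keys <- if (joint_blocks) c("subject", "condition") else
    c("subject", "condition", "block")
  keys <- intersect(keys, names(data))
  groups <- dplyr::group_split(dplyr::group_by(data, !!!rlang::syms(keys)))
  purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(models, function(m) {
      cfg <- config
      if (!is.null(config$seed)) {
        # distinct but reproducible stream per group/model
        cfg$seed <- (config$seed +
                       sum(utf8ToInt(paste(g[[1]][1], g$condition[1],
                                           m$id, collapse = "")))) %% 2147483647L
      }
      fit <- fit_block(g, m, prior_spec(m), cfg, floor_at)
      out <- dplyr::distinct(g[keys])
      out$model <- m$id
      out$log_evidence <- fit$log_evidence
      out$log_joint <- fit$log_joint
      out$regularized <- fit$regularized
      out$fit <- list(fit)
      out
    })
  })
}

#' Per-condition summed log evidence
#'
#' Sums per-block log evidences over the blocks of each
#' (subject, condition, model) cell, the per-subject quantity entering
#' random-effects model selection.
#'
#' @param fits Evidence tibble from [fit_models()] (needs `subject`,
#'   `condition`, `model`, `log_evidence`).
#' @return Tibble with one row per subject x condition x model.
#' @export
condition_evidence <- function(fits) {
  dplyr::summarise(
    dplyr::group_by(fits, .data$subject, .data$condition, .data$model),
    n_blocks = dplyr::n(),
    log_evidence = sum(.data$log_evidence),
    .groups = "drop"
  )
}

#' Evidence matrix for one condition
#'
#' @param evidence Output of [condition_evidence()] (or a compatible tibble).
#' @param condition Condition label to select (default: use all rows).
#' @return Numeric subjects x models matrix of summed log evidences.
#' @export
evidence_matrix <- function(evidence, condition = NULL) {
  if (!is.null(condition)) {
    evidence <- dplyr::filter(evidence, .data$condition == !!condition)
  }
  wide <- tidyr::pivot_wider(
    evidence[c("subject", "model", "log_evidence")],
    names_from = "model", values_from = "log_evidence"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- as.character(wide$subject)
  if (anyNA(m)) stop("missing model evidences for some subjects")
  m
}
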