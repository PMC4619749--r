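# broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model fit
#'
#' One row per free parameter: posterior mode in the transformed space,
#' its Laplace standard error, and the mode mapped back to the native
#' scale.
#'
#' @param x A `wcst_fit` from [fit_block()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (transformed),
#'   `std.error` (transformed scale), `estimate_natural`.
#' @export
tidy.wcst_fit <- function(x, ...) {
  info <- model_parameters(x$model)
  nat <- x$params[info$name]
  tibble::tibble(
    term = info$name,
    estimate = as.numeric(x$chi_mode),
    std.error = sqrt(pmax(diag(x$S), 0)),
    estimate_natural = as.numeric(unlist(nat))
  )
}

#' Glance at a model fit
#'
#' @param x A `wcst_fit`.
#' @param ... Unused.
#' @return One-row tibble: `model`, `n_parameters`, `n_trials`,
#'   `log_joint`, `log_evidence`, `regularized`, `n_restarts`.
#' @export
glance.wcst_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$id,
    n_parameters = length(x$chi_mode),
    n_trials = x$n_trials,
    log_joint = x$log_joint,
    log_evidence = x$log_evidence,
    regularized = x$regularized,
    n_restarts = nrow(x$restarts)
  )
}

#' Tidy a model-selection result
#'
#' @param x A `wcst_bms` from [rfx_bms()] or [family_bms()].
#' @param ... Unused.
#' @return Tibble with one row per model (or family): `model`, `alpha`,
#'   `expected_prob`, `exceedance_prob`, `protected_xp`.
#' @export
tidy.wcst_bms <- function(x, ...) {
  tibble::tibble(
    model = if (is.null(x$models)) seq_along(x$alpha) else x$models,
    alpha = as.numeric(x$alpha),
    expected_prob = as.numeric(x$expected_prob),
    exceedance_prob = as.numeric(x$exceedance_prob),
    protected_xp = as.numeric(x$protected_xp)
  )
}

#' Glance at a model-selection result
#'
#' @param x A `wcst_bms`.
#' @param ... Unused.
#' @return One-row tibble: `n_subjects`, `n_models`, `bor`, `free_energy`,
#'   `free_energy_null`.
#' @export
glance.wcst_bms <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$subject_posteriors),
    n_models = length(x$alpha),
    bor = x$bor,
    free_energy = x$free_energy,
    free_energy_null = x$free_energy_null
  )
}

#' Tidy a belief trajectory
#'
#' @param x A `wcst_beliefs` from [run_filter()].
#' @param ... Unused.
#' @return Long tibble with `trial` (0 = initial state), `level`
#'   (`"exemplar"` or `"feature"`), `component` (exemplar/feature label),
#'   `mean` and `variance`.
#' @export
tidy.wcst_beliefs <- function(x, ...) {
  d <- ncol(x$mu)
  labels <- if (d == 9) c(.exemplars, .features) else .exemplars
  level <- if (d == 9) rep(c("exemplar", "feature"), c(6, 3)) else
    rep("exemplar", 6)
  vars <- t(vapply(x$Sigma, diag, numeric(d)))
  purrr::map_dfr(seq_len(nrow(x$mu)), function(i) {
    tibble::tibble(
      trial = i - 1L,
      level = level,
      component = labels,
      mean = x$mu[i, ],
      variance = vars[i, ]
    )
  })
}
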