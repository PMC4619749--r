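# Behavioral and model-based performance summaries. Performance is the
# money assigned to the truly relevant visual feature: the maximum of $20
# per trial is reached by betting everything on the relevant feature.

#' Subject performance per block
#'
#' Median and mean over trials of the money placed on the truly relevant
#' feature (20 times the response component of the relevant feature).
#'
#' @param data Trial tibble with responses and the hidden
#'   `relevant_feature` column.
#' @return Tibble with one row per subject x condition x block:
#'   `perf_median`, `perf_mean` (dollars in `[0, 20]`).
#' @export
subject_performance <- function(data) {
  r <- block_r_matrix(data)
  money <- 20 * r[cbind(seq_len(nrow(r)), data$relevant_feature)]
  data$money_relevant <- money
  keys <- intersect(c("subject", "condition", "block"), names(data))
  dplyr::summarise(
    dplyr::group_by(data, !!!rlang::syms(keys)),
    perf_median = stats::median(.data$money_relevant),
    perf_mean = mean(.data$money_relevant),
    .groups = "drop"
  )
}

#' Expected model performance per block
#'
#' Runs the belief filter at the posterior-mode parameters, takes the
#' noise-free risk-adjusted response each trial, and averages the money on
#' the truly relevant feature over the block.
#'
#' @param fit A [fit_block()] result.
#' @param trials The block's trial tibble (with hidden columns).
#' @return Mean model performance in dollars.
#' @export
model_expected_performance <- function(fit, trials) {
  r <- modal_responses(fit, trials)
  mean(20 * r[cbind(seq_len(nrow(r)), trials$relevant_feature)])
}

# noise-free per-trial modal responses of a fitted model
#' @keywords internal
modal_responses <- function(fit, trials) {
  model <- fit$model
  p <- fit$params
  n <- nrow(trials)
  r <- matrix(NA_real_, n, 3)
  if (model$baseline) {
    loc <- .softmax(c(p$mu_f0_1, p$mu_f0_2, p$mu_f0_3))
    for (t in seq_len(n)) r[t, ] <- loc
    return(r)
  }
  bel <- run_filter(trials, model, p)
  for (t in seq_len(n)) {
    probs <- feature_probs(bel$mu[t + 1L, ], model)
    r[t, ] <- optimal_response(probs, p$theta1)
  }
  r
}

#' Correlation between model and subject performance
#'
#' Pearson correlation between paired mean performances across blocks.
#'
#' @param subject_perf,model_perf Numeric vectors of paired per-block mean
#'   performances (at least 3 pairs).
#' @return Pearson correlation coefficient.
#' @export
performance_correlation <- function(subject_perf, model_perf) {
  stopifnot(length(subject_perf) == length(model_perf),
            length(subject_perf) >= 3)
  if (stats::sd(subject_perf) == 0 || stats::sd(model_perf) == 0) {
    stop("performance correlation undefined: zero variance")
  }
  stats::cor(subject_perf, model_perf)
}

#' Model-averaged expected responses
#'
#' Averages the noise-free modal responses of several fitted models,
#' weighted by the subject's posterior model probabilities from
#' random-effects model selection. Weights are renormalized over the models
#' supplied.
#'
#' @param fits List of [fit_block()] results for one subject (one per
#'   model).
#' @param trials The block's trial tibble.
#' @param weights Numeric vector of posterior model probabilities, same
#'   length and order as `fits` (e.g. a row of `subject_posteriors` from
#'   [rfx_bms()]).
#' @return Tibble with `trial`, `feature` and the weighted `response`.
#' @export
average_model_responses <- function(fits, trials, weights) {
  stopifnot(length(fits) == length(weights), all(weights >= 0),
            sum(weights) > 0)
  w <- weights / sum(weights)
  r <- Reduce(`+`, purrr::map2(fits, w, function(f, wi) {
    wi * modal_responses(f, trials)
  }))
  purrr::map_dfr(seq_len(nrow(r)), function(t) {
    tibble::tibble(trial = t, feature = .features, response = r[t, ])
  })
}

#' Expected response trajectory with probability intervals
#'
#' Per-trial noise-free modal response of a fitted model plus the central
#' 95% interval of each response component obtained by sampling from the
#' fitted response distribution.
#'
#' @param fit A [fit_block()] result.
#' @param trials The block's trial tibble.
#' @param n_samples Response draws per trial for the interval (default
#'   10000).
#' @param level Interval coverage (default 0.95).
#' @return Tibble with `trial`, `feature`, `response` (modal), `lower`,
#'   `upper`, and the observed response `observed` when present.
#' @export
expected_response_trajectory <- function(fit, trials, n_samples = 1e4,
                                         level = 0.95) {
  model <- fit$model
  p <- fit$params
  n <- nrow(trials)
  modal <- modal_responses(fit, trials)
  lo <- (1 - level) / 2
  bel <- if (model$baseline) NULL else run_filter(trials, model, p)
  bands <- purrr::map(seq_len(n), function(t) {
    dp <- if (model$baseline) {
      response_density_params(NULL, NULL, model, p)
    } else {
      response_density_params(bel$mu[t + 1L, ], bel$Sigma[[t + 1L]], model, p)
    }
    draws <- sample_response(dp$m, dp$P, n = n_samples)
    apply(draws, 2, stats::quantile, probs = c(lo, 1 - lo))
  })
  obs <- block_r_matrix(trials)
  purrr::map_dfr(seq_len(n), function(t) {
    tibble::tibble(
      trial = t,
      feature = .features,
      response = modal[t, ],
      lower = bands[[t]][1, ],
      upper = bands[[t]][2, ],
      observed = obs[t, ]
    )
  })
}
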