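# Forward simulation: couple the task generator with any behavioral model
# acting as a generative agent, and build whole synthetic cohorts with known
# ground-truth parameters for recovery studies.

#' Simulate an agent's responses on a block
#'
#' Runs the model's belief filter over the block's observation sequence and
#' samples one stochastic response per trial from the model's
#' logistic-normal response distribution (after the trial's observation).
#'
#' @param trials Trial tibble from [generate_block()].
#' @param model A [wcst_model()].
#' @param params Named list of native-scale parameters.
#' @return The trial tibble with `r_color`, `r_motion`, `r_shape` filled in.
#' @export
#' @examples
#' set.seed(7)
#' b <- generate_block(task_config("no-switch", n_trials = 5))
#' simulate_agent(b, wcst_model("rd"),
#'                list(eps = 0.2, tau_e = 0.8, q_e = 0.5, mu_e0 = 0,
#'                     sigma_e0 = 1, theta1 = 2, theta2 = 0.1))
simulate_agent <- function(trials, model, params) {
  p <- complete_parameters(params, model)
  n <- nrow(trials)
  r <- matrix(NA_real_, n, 3)
  if (model$baseline) {
    dp <- response_density_params(NULL, NULL, model, p)
    for (t in seq_len(n)) r[t, ] <- sample_response(dp$m, dp$P)
  } else {
    bel <- run_filter(trials, model, p)
    for (t in seq_len(n)) {
      dp <- response_density_params(bel$mu[t + 1L, ], bel$Sigma[[t + 1L]],
                                    model, p)
      r[t, ] <- sample_response(dp$m, dp$P)
    }
  }
  trials$r_color <- r[, 1]
  trials$r_motion <- r[, 2]
  trials$r_shape <- r[, 3]
  trials
}

#' Default ground-truth parameter sampler
#'
#' Uniform draws on native-scale ranges chosen to produce clearly
#' belief-driven behavior: a subjective error rate near the design values,
#' moderately persistent dynamics, risk factors around probability matching
#' and low response noise.
#'
#' @param model A [wcst_model()].
#' @return A function `(void) -> named list` drawing one parameter set.
#' @export
default_parameter_sampler <- function(model) {
  ranges <- list(
    eps = c(0.2, 0.3), eps_nb = c(0.2, 0.3), alpha = c(0.5, 1.5),
    tau_e = c(0.65, 0.8), tau_f = c(0.65, 0.8),
    kappa_e = c(0.3, 0.6), kappa_f = c(0.3, 0.6),
    q_e = c(0.05, 0.15), q_f = c(0.05, 0.15),
    w_dist = c(0.3, 0.6), mu_e0 = c(-0.2, 0.2), mu_f0 = c(-0.2, 0.2),
    sigma_e0 = c(0.5, 1.5), sigma_f0 = c(0.5, 1.5),
    theta1 = c(1.2, 2), theta2 = c(0.05, 0.15), theta3 = c(0.1, 0.5),
    mu_f0_1 = c(-1, 1), mu_f0_2 = c(-1, 1), mu_f0_3 = c(-1, 1)
  )
  nms <- model_parameters(model)$name
  function() {
    stats::setNames(lapply(nms, function(nm) {
      rg <- ranges[[nm]]
      stats::runif(1, rg[1], rg[2])
    }), nms)
  }
}

#' Generate a synthetic cohort
#'
#' Emulates the study design: each subject completes
#' `n_blocks_per_condition` switch and no-switch blocks of `n_trials`
#' trials under the design settings (switch probability 0.35 with an
#' 8-trial refractory period and error rate 0.3 in the switch condition;
#' constant rule and error rate 0.2 in the no-switch condition), with
#' responses generated by `generating_model` under per-subject parameters
#' drawn from `parameter_sampler`.
#'
#' @param n_subjects Number of subjects (study size: 22).
#' @param generating_model A [wcst_model()] acting as the generative agent.
#' @param parameter_sampler Function returning one named parameter list per
#'   call; default [default_parameter_sampler()].
#' @param n_blocks_per_condition Blocks per condition (default 3).
#' @param n_trials Trials per block (default 40).
#' @param seed Optional integer seed; identical seeds reproduce the cohort
#'   exactly.
#' @return List with `data` (trial tibble over all subjects) and `truth`
#'   (tibble subject x parameter of generating values, native scale, plus
#'   the generating model id).
#' @export
generate_cohort <- function(n_subjects = 22L,
                            generating_model = wcst_model("w1"),
                            parameter_sampler =
                              default_parameter_sampler(generating_model),
                            n_blocks_per_condition = 3L,
                            n_trials = 40L,
                            seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  configs <- list(
    task_config("switch", n_trials = n_trials),
    task_config("no-switch", n_trials = n_trials)
  )
  out <- purrr::map(seq_len(n_subjects), function(s) {
    params <- parameter_sampler()
    blocks <- purrr::map_dfr(configs, function(cfg) {
      purrr::map_dfr(seq_len(n_blocks_per_condition), function(b) {
        trials <- generate_block(cfg, block = b, subject = s)
        simulate_agent(trials, generating_model, params)
      })
    })
    truth <- tibble::as_tibble(params)
    truth$subject <- s
    truth$model <- generating_model$id
    list(data = blocks, truth = truth)
  })
  list(
    data = purrr::map_dfr(out, "data"),
    truth = dplyr::relocate(purrr::map_dfr(out, "truth"),
                            "subject", "model")
  )
}
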