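# Shared fixtures: canonical parameter sets in the moderate learning regime
# and small simulated blocks.

params_w1 <- function(response = "reduced") {
  p <- list(
    eps = 0.22, tau_e = 0.75, tau_f = 0.75, kappa_e = 0.5, kappa_f = 0.5,
    q_e = 0.1, q_f = 0.1, w_dist = 0.5, mu_e0 = 0, mu_f0 = 0,
    sigma_e0 = 1, sigma_f0 = 1, theta1 = 1.6, theta2 = 0.05
  )
  if (response == "full") p$theta3 <- 0.3
  p
}

params_rd <- function() {
  list(eps = 0.25, tau_e = 0.8, q_e = 0.3, mu_e0 = 0, sigma_e0 = 1,
       theta1 = 1.5, theta2 = 0.05)
}

params_nb_rw <- function() {
  list(eps_nb = 0.25, alpha = 1, tau_e = 0.75, kappa_e = 0.5, mu_e0 = 0,
       theta1 = 1.5, theta2 = 0.1)
}

# one simulated block with responses
sim_block <- function(model, params, condition = "switch", n_trials = 40,
                      seed = 1) {
  set.seed(seed)
  b <- generate_block(task_config(condition, n_trials = n_trials))
  simulate_agent(b, model, params)
}

# valid random parameter set for any model (moderate regime)
random_params <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  default_parameter_sampler(model)()
}

expect_simplex <- function(r, tol = 1e-10) {
  expect_true(all(r >= 0))
  expect_equal(sum(r), 1, tolerance = tol)
}
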