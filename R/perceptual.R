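# Hidden-state dynamics and belief updates. The hidden state h = (h_e, h_f)
# stacks six exemplar-relevance components and (for full-hierarchy variants)
# three feature-relevance components. Lateral inhibition of strength
# w_lat = 2 * kappa implements winner-take-all competition within a level;
# symmetric excitation w_dist couples each exemplar to its feature.

#' @keywords internal
.logistic <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
.softmax <- function(x) {
  y <- exp(x - max(x))
  y / sum(y)
}

#' Build the connectivity matrices of a perceptual variant
#'
#' Lateral matrices have zero diagonal and constant off-diagonal inhibition
#' `-2 * kappa`; the inter-level excitation matrix carries `w_dist` at
#' positions pairing exemplar i with its feature v(i). For the diffusive
#' variant `d` the feature-to-exemplar (top-down) excitation is absent by
#' default; set `d_topdown = TRUE` in [wcst_model()] to keep it.
#'
#' @param model A [wcst_model()].
#' @param params Named list with `kappa_e`, `kappa_f`, `w_dist` as required
#'   by the variant (missing entries are treated as the variant's fixed
#'   zeros via [complete_parameters()]).
#' @return List with `W_lat_e` (6 x 6), and for full-hierarchy variants
#'   `W_lat_f` (3 x 3), `W_dist_fe` (6 x 3, feature-to-exemplar input) and
#'   `W_dist_ef` (3 x 6, exemplar-to-feature input).
#' @export
build_connectivity <- function(model, params) {
  stopifnot(inherits(model, "wcst_model"), !model$baseline)
  p <- complete_parameters(params, model)
  if (p$kappa_e < 0 || p$kappa_f < 0 || p$w_dist < 0) {
    stop("kappa and w_dist must be nonnegative")
  }
  W_lat_e <- -2 * p$kappa_e * (matrix(1, 6, 6) - diag(6))
  if (model$reduced) {
    return(list(W_lat_e = W_lat_e))
  }
  W_lat_f <- -2 * p$kappa_f * (matrix(1, 3, 3) - diag(3))
  W_dist_fe <- matrix(0, 6, 3)
  W_dist_fe[cbind(1:6, .exemplar_feature)] <- p$w_dist
  W_dist_ef <- t(W_dist_fe)
  if (model$structure == "d" && !model$d_topdown) {
    W_dist_fe[] <- 0  # bottom-up excitation only
  }
  list(W_lat_e = W_lat_e, W_lat_f = W_lat_f,
       W_dist_fe = W_dist_fe, W_dist_ef = W_dist_ef)
}

#' Noise-free state propagation g(mu)
#'
#' One step of the deterministic part of the hidden-state dynamics:
#' `g_e = tau_e h_e + kappa_e + W_lat_e phi(h_e - kappa_e) +
#'  W_dist_fe phi(h_f - kappa_f)` and the analogous feature-level map, with
#' `phi` the elementwise logistic function. Process noise enters only
#' through the covariance prediction ([predict_belief()]).
#'
#' @param mu Belief mean: length 9 for full-hierarchy variants, 6 for
#'   reduced ones.
#' @param model A [wcst_model()].
#' @param params Named parameter list.
#' @return Predicted mean of the same length as `mu`.
#' @export
propagate_mean <- function(mu, model, params) {
  p <- complete_parameters(params, model)
  W <- build_connectivity(model, p)
  if (model$reduced) {
    stopifnot(length(mu) == 6)
    return(as.numeric(
      p$tau_e * mu + p$kappa_e + W$W_lat_e %*% .logistic(mu - p$kappa_e)
    ))
  }
  stopifnot(length(mu) == 9)
  h_e <- mu[1:6]; h_f <- mu[7:9]
  phi_e <- .logistic(h_e - p$kappa_e)
  phi_f <- .logistic(h_f - p$kappa_f)
  g_e <- p$tau_e * h_e + p$kappa_e + W$W_lat_e %*% phi_e + W$W_dist_fe %*% phi_f
  g_f <- p$tau_f * h_f + p$kappa_f + W$W_lat_f %*% phi_f + W$W_dist_ef %*% phi_e
  c(as.numeric(g_e), as.numeric(g_f))
}

#' Jacobian of the state propagation
#'
#' Closed-form block Jacobian of [propagate_mean()] at `mu`, using
#' `phi' = phi (1 - phi)`.
#'
#' @inheritParams propagate_mean
#' @return Square matrix matching the state dimension.
#' @export
jacobian_g <- function(mu, model, params) {
  p <- complete_parameters(params, model)
  W <- build_connectivity(model, p)
  dphi <- function(x) {
    s <- .logistic(x)
    s * (1 - s)
  }
  if (model$reduced) {
    stopifnot(length(mu) == 6)
    return(p$tau_e * diag(6) +
             W$W_lat_e %*% diag(dphi(mu - p$kappa_e), 6))
  }
  stopifnot(length(mu) == 9)
  d_e <- dphi(mu[1:6] - p$kappa_e)
  d_f <- dphi(mu[7:9] - p$kappa_f)
  J <- matrix(0, 9, 9)
  J[1:6, 1:6] <- p$tau_e * diag(6) + W$W_lat_e %*% diag(d_e, 6)
  J[1:6, 7:9] <- W$W_dist_fe %*% diag(d_f, 3)
  J[7:9, 1:6] <- W$W_dist_ef %*% diag(d_e, 6)
  J[7:9, 7:9] <- p$tau_f * diag(3) + W$W_lat_f %*% diag(d_f, 3)
  J
}

#' Predict the belief forward one trial
#'
#' Linearizes the dynamics around the current mean: predicted mean
#' `g(mu)`, predicted covariance `J Sigma J' + Q` with process-noise block
#' `Q = q_e I_6 (+) q_f I_3` (direct sum), symmetrized.
#'
#' @param belief List with components `mu` (mean) and `Sigma` (covariance).
#' @inheritParams propagate_mean
#' @return List with `mu` (predicted mean) and `Sigma` (predicted
#'   covariance).
#' @export
predict_belief <- function(belief, model, params) {
  p <- complete_parameters(params, model)
  J <- jacobian_g(belief$mu, model, p)
  d <- length(belief$mu)
  Q <- if (model$reduced) {
    diag(rep(p$q_e, 6))
  } else {
    diag(c(rep(p$q_e, 6), rep(p$q_f, 3)))
  }
  S <- J %*% belief$Sigma %*% t(J) + Q
  list(mu = propagate_mean(belief$mu, model, p), Sigma = (S + t(S)) / 2)
}

#' Posterior over the six rule hypotheses
#'
#' Combines the observation likelihood `p(e_k | eps) = (1 - eps)` if
#' exemplar k was on the chosen card and `eps` otherwise with the predicted
#' exemplar relevance: `rho_k` is proportional to
#' `p(e_k | eps) * exp(g_k)`, normalized over the six hypotheses. Also
#' returns the predicted hypothesis probabilities `pi_pred = softmax(g_e)`,
#' the prediction error `delta = (rho - pi_pred, 0_3)` and the precision
#' contribution `Y = (diag(pi) - pi pi') (+) 0` used by [bayes_update()].
#'
#' @param e Binary 6-vector with exactly three ones.
#' @param g_pred Predicted belief mean (length 9 or 6; only the exemplar
#'   part is used).
#' @param eps Subjective experimenter error rate in (0, 1/2).
#' @return List with `rho`, `pi_pred`, `delta`, `Y`.
#' @export
hypothesis_posterior <- function(e, g_pred, eps) {
  stopifnot(length(e) == 6, sum(e) == 3, all(e %in% c(0, 1)),
            eps > 0, eps < 0.5)
  d <- length(g_pred)
  g_e <- g_pred[1:6]
  log_lik <- ifelse(e == 1, log1p(-eps), log(eps))
  w <- log_lik + g_e
  rho <- .softmax(w)
  pi_pred <- .softmax(g_e)
  delta <- c(rho - pi_pred, rep(0, d - 6))
  Y <- matrix(0, d, d)
  Y[1:6, 1:6] <- diag(pi_pred) - tcrossprod(pi_pred)
  list(rho = rho, pi_pred = pi_pred, delta = delta, Y = Y)
}

#' Variational Bayesian belief update
#'
#' Posterior covariance `Sigma_t = (Sigma_hat^{-1} + Y)^{-1}` (the symmetric
#' form of the matrix-fraction update), symmetrized, with a small diagonal
#' jitter retry if the predicted covariance is numerically singular;
#' posterior mean `mu_t = g(mu_{t-1}) + Sigma_t delta`. This equals one
#' Newton step on the quadratic expansion of the variational energy around
#' the predicted mean.
#'
#' @param pred Predicted belief from [predict_belief()].
#' @param hyp Hypothesis posterior from [hypothesis_posterior()].
#' @return List with `mu` and `Sigma`.
#' @export
bayes_update <- function(pred, hyp) {
  Sig_hat <- pred$Sigma
  prec <- tryCatch(
    chol2inv(chol(Sig_hat)),
    error = function(err) {
      chol2inv(chol(Sig_hat + 1e-8 * diag(nrow(Sig_hat))))
    }
  )
  A <- prec + hyp$Y
  Sigma <- tryCatch(
    chol2inv(chol((A + t(A)) / 2)),
    error = function(err) {
      solve((A + t(A)) / 2 + 1e-8 * diag(nrow(A)))
    }
  )
  Sigma <- (Sigma + t(Sigma)) / 2
  list(mu = as.numeric(pred$mu + Sigma %*% hyp$delta), Sigma = Sigma)
}

#' Fixed-uncertainty (non-Bayesian) mean update
#'
#' With the posterior covariance pinned to `alpha * I`, the exemplar means
#' follow a Rescorla-Wagner-like rule
#' `mu_e <- g_e(mu) + alpha (rho - softmax(g_e(mu)))` where the evidence
#' vector is `rho_k = 1 - eps_nb` for selected exemplars and `eps_nb`
#' otherwise (unnormalized); feature means follow the deterministic
#' dynamics.
#'
#' @param mu Current belief mean.
#' @param e Binary 6-vector observation.
#' @inheritParams propagate_mean
#' @return Updated mean vector.
#' @export
nonbayes_update <- function(mu, e, model, params) {
  p <- complete_parameters(params, model)
  stopifnot(p$eps_nb > 0, p$eps_nb < 0.5)
  g <- propagate_mean(mu, model, p)
  rho <- ifelse(e == 1, 1 - p$eps_nb, p$eps_nb)
  g_e <- g[1:6]
  upd <- g_e + p$alpha * (rho - .softmax(g_e))
  if (model$reduced) upd else c(upd, g[7:9])
}

#' Run the belief filter over a block
#'
#' Initializes the belief at `mu_0 = (mu_e0 1_6, mu_f0 1_3)` with
#' `Sigma_0 = sigma_e0 I_6 (+) sigma_f0 I_3` (Bayesian variants) or the
#' fixed `alpha I` (non-Bayesian variants) and iterates
#' predict / hypothesis-posterior / update over the observation sequence.
#'
#' @param trials A trial tibble from [generate_block()] (or any data frame
#'   with the `e_*` columns), or a T x 6 binary matrix of observations.
#' @param model A [wcst_model()] (not the baseline model).
#' @param params Named list of native-scale parameters.
#' @return An object of class `wcst_beliefs`: list with `mu`
#'   ((T + 1) x d matrix of belief means, first row the initial state),
#'   `Sigma` (list of T + 1 covariance matrices), `rho` and `pi_pred`
#'   (T x 6 matrices), plus the model and parameters.
#' @export
run_filter <- function(trials, model, params) {
  stopifnot(inherits(model, "wcst_model"), !model$baseline)
  e_mat <- if (is.data.frame(trials)) block_e_matrix(trials) else as.matrix(trials)
  p <- complete_parameters(params, model)
  d <- if (model$reduced) 6L else 9L
  n <- nrow(e_mat)
  mu <- matrix(NA_real_, n + 1L, d)
  mu[1, ] <- if (model$reduced) rep(p$mu_e0, 6) else
    c(rep(p$mu_e0, 6), rep(p$mu_f0, 3))
  Sigma0 <- if (model$bayesian) {
    if (model$reduced) diag(rep(p$sigma_e0, 6)) else
      diag(c(rep(p$sigma_e0, 6), rep(p$sigma_f0, 3)))
  } else {
    p$alpha * diag(d)
  }
  Sigma <- vector("list", n + 1L)
  Sigma[[1]] <- Sigma0
  rho <- matrix(NA_real_, n, 6)
  pi_pred <- matrix(NA_real_, n, 6)
  state <- list(mu = mu[1, ], Sigma = Sigma0)
  for (t in seq_len(n)) {
    if (model$bayesian) {
      pred <- predict_belief(state, model, p)
      hyp <- hypothesis_posterior(e_mat[t, ], pred$mu, p$eps)
      state <- bayes_update(pred, hyp)
      rho[t, ] <- hyp$rho
      pi_pred[t, ] <- hyp$pi_pred
    } else {
      g <- propagate_mean(state$mu, model, p)
      pi_pred[t, ] <- .softmax(g[1:6])
      rho[t, ] <- ifelse(e_mat[t, ] == 1, 1 - p$eps_nb, p$eps_nb)
      state <- list(mu = nonbayes_update(state$mu, e_mat[t, ], model, p),
                    Sigma = Sigma0)
    }
    mu[t + 1L, ] <- state$mu
    Sigma[[t + 1L]] <- state$Sigma
  }
  structure(
    list(mu = mu, Sigma = Sigma, rho = rho, pi_pred = pi_pred,
         model = model, params = p),
    class = "wcst_beliefs"
  )
}

#' @export
print.wcst_beliefs <- function(x, ...) {
  cat("<wcst_beliefs>", x$model$id, "-", nrow(x$mu) - 1L, "trials,",
      ncol(x$mu), "state components\n")
  invisible(x)
}
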