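# Beliefs -> money-allocation responses. Responses live on the 2-simplex;
# the likelihood is a logistic-normal density on centered log-ratio
# coordinates, with a normalization constant accounting for the projection
# of the 3-dimensional Gaussian onto the zero-sum plane.

#' Posterior feature-relevance probabilities
#'
#' Full-hierarchy variants read the feature level directly:
#' `p = softmax(mu_f)`. Reduced variants integrate the exemplar level:
#' `p_i = (exp(mu_e[2i-1]) + exp(mu_e[2i])) / sum_j exp(mu_e[j])`.
#'
#' @param mu Belief mean (length 9 or 6).
#' @param model A [wcst_model()].
#' @return Probability 3-vector over (color, motion, shape).
#' @export
#' @examples
#' feature_probs(rep(0, 6), wcst_model("rd"))
feature_probs <- function(mu, model) {
  if (model$reduced) {
    stopifnot(length(mu) == 6)
    w <- exp(mu - max(mu))
    p <- as.numeric(tapply(w, .exemplar_feature, sum))
    return(p / sum(p))
  }
  stopifnot(length(mu) == 9)
  .softmax(mu[7:9])
}

#' Risk-adjusted optimal response
#'
#' The utility-maximizing money allocation under the derived response rule
#' raises the feature probabilities to the inverse risk factor and
#' renormalizes: `r = p^theta1 / sum(p^theta1)`. As `theta1 -> 0` the
#' response approaches the uniform allocation regardless of beliefs
#' (infinite risk aversion); `theta1 = 1` reproduces probability matching.
#'
#' @param p Probability 3-vector.
#' @param theta1 Positive inverse risk factor.
#' @return Simplex 3-vector.
#' @export
#' @examples
#' optimal_response(c(0.6, 0.3, 0.1), theta1 = 2)
optimal_response <- function(p, theta1) {
  stopifnot(theta1 > 0, all(p > 0))
  w <- exp(theta1 * (log(p) - max(log(p))))
  w / sum(w)
}

#' Centered log-ratio transform
#'
#' `clr(r) = log(r / gm(r))` with `gm` the geometric mean; maps the open
#' simplex onto the zero-sum plane.
#'
#' @param r Strictly positive simplex 3-vector.
#' @return Zero-sum 3-vector.
#' @export
#' @examples
#' clr(c(0.5, 0.25, 0.25))
clr <- function(r) {
  if (any(r <= 0)) stop("clr requires strictly positive components")
  lr <- log(r)
  as.numeric(lr - mean(lr))
}

#' Clamp a response away from the simplex boundary
#'
#' Observed allocations can touch the corners of the response triangle where
#' the clr transform is undefined; components are floored at `floor_at` and
#' the vector renormalized before likelihood evaluation.
#'
#' @param r Simplex 3-vector or n x 3 matrix.
#' @param floor_at Interior floor (default 1e-3).
#' @return Clamped simplex values of the same shape.
#' @export
clamp_response <- function(r, floor_at = 1e-3) {
  if (is.matrix(r)) {
    r <- pmax(r, floor_at)
    return(r / rowSums(r))
  }
  r <- pmax(r, floor_at)
  r / sum(r)
}

#' Response-noise covariance
#'
#' `P = theta2 I + theta3 Sigma_f`: a constant isotropic component plus a
#' component proportional to the posterior uncertainty about feature
#' relevance (the latter only for Bayesian full-hierarchy perceptual models
#' with the full response model).
#'
#' @param theta2 Baseline noise variance (positive).
#' @param theta3 Uncertainty-coupling weight (nonnegative; 0 in the reduced
#'   response model).
#' @param Sigma_f Optional 3 x 3 posterior feature covariance.
#' @return 3 x 3 covariance matrix.
#' @export
response_covariance <- function(theta2, theta3 = 0, Sigma_f = NULL) {
  P <- theta2 * diag(3)
  if (theta3 > 0) {
    if (is.null(Sigma_f)) stop("theta3 > 0 requires Sigma_f")
    P <- P + theta3 * Sigma_f
  }
  (P + t(P)) / 2
}

# Per-trial response-density parameters (location m, covariance P) for a
# model given the posterior belief after the trial's observation.
#' @keywords internal
response_density_params <- function(mu, Sigma, model, params) {
  p <- complete_parameters(params, model)
  if (model$baseline) {
    return(list(m = c(p$mu_f0_1, p$mu_f0_2, p$mu_f0_3),
                P = (1 + p$theta3) * diag(3)))
  }
  if (model$reduced) {
    m <- p$theta1 * clr(feature_probs(mu, model))
  } else {
    m <- p$theta1 * mu[7:9]
  }
  Sigma_f <- if (model$response == "full") Sigma[7:9, 7:9] else NULL
  list(m = m, P = response_covariance(p$theta2, p$theta3, Sigma_f))
}

#' Sample a stochastic response
#'
#' Draws a Gaussian perturbation `xi ~ N(0, P)` on log scale and returns the
#' softmax-renormalized response `r propto exp(m + xi)`; equivalent to
#' perturbing the risk-adjusted optimal response multiplicatively.
#'
#' @param m Location 3-vector on clr/log scale.
#' @param P 3 x 3 positive-definite covariance.
#' @param n Number of draws.
#' @return Simplex 3-vector (`n = 1`) or n x 3 matrix.
#' @export
sample_response <- function(m, P, n = 1L) {
  if (max(abs(P)) == 0) {
    r <- .softmax(m)
    return(if (n == 1L) r else matrix(r, n, 3L, byrow = TRUE))
  }
  L <- chol(P)
  xi <- matrix(stats::rnorm(3L * n), n, 3L) %*% L
  z <- sweep(xi, 2L, m, "+")
  z <- exp(z - apply(z, 1L, max))
  r <- z / rowSums(z)
  if (n == 1L) as.numeric(r) else r
}

#' Logistic-normal normalization constant
#'
#' Mass of the Gaussian `N(m, P)` on the zero-sum plane:
#' `Z = (2 pi a' P a)^{-1/2} exp(-(a' m)^2 / (2 a' P a))` with
#' `a = (1, 1, 1)'`. `Z` is invariant to adding any zero-sum vector to `m`.
#'
#' @inheritParams sample_response
#' @return Positive scalar.
#' @export
#' @examples
#' lognormal_constant(c(0, 0, 0), diag(3))  # (6 * pi)^(-1/2)
lognormal_constant <- function(m, P) {
  a_P_a <- sum(P)
  a_m <- sum(m)
  exp(-a_m^2 / (2 * a_P_a)) / sqrt(2 * pi * a_P_a)
}

#' Logistic-normal response log-likelihood
#'
#' Log of the simplex density
#' `p(r) = N(clr(r); m, P) / (3 r_1 r_2 r_3 Z(m, P))`, i.e.
#' `-log 3 - sum(log r) - log Z + log N(clr(r); m, P)`, where `N` is the
#' 3-dimensional Gaussian density and `Z` the plane-restriction constant of
#' [lognormal_constant()]. The density integrates to 1 over the simplex.
#'
#' @param r Simplex 3-vector (clamped to the interior first; see
#'   [clamp_response()]).
#' @param m Location 3-vector.
#' @param P 3 x 3 positive-definite covariance.
#' @param floor_at Interior clamp floor.
#' @return Log-density (scalar).
#' @export
response_loglik <- function(r, m, P, floor_at = 1e-3) {
  r <- clamp_response(r, floor_at)
  x <- clr(r)
  -log(3) - sum(log(r)) - log(lognormal_constant(m, P)) +
    mvtnorm::dmvnorm(x, mean = m, sigma = P, log = TRUE)
}

# Sum of response log-likelihoods over a block, given a fitted belief
# trajectory (R reference path; the C++ path fuses this with the filter).
#' @keywords internal
block_response_loglik_r <- function(trials, model, params, floor_at = 1e-3) {
  p <- complete_parameters(params, model)
  r_mat <- clamp_response(block_r_matrix(trials), floor_at)
  n <- nrow(r_mat)
  if (model$baseline) {
    dp <- response_density_params(NULL, NULL, model, p)
    return(sum(vapply(seq_len(n), function(t) {
      response_loglik(r_mat[t, ], dp$m, dp$P, floor_at)
    }, numeric(1))))
  }
  bel <- run_filter(trials, model, p)
  sum(vapply(seq_len(n), function(t) {
    dp <- response_density_params(bel$mu[t + 1L, ], bel$Sigma[[t + 1L]],
                                  model, p)
    response_loglik(r_mat[t, ], dp$m, dp$P, floor_at)
  }, numeric(1)))
}
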