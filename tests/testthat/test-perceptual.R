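test_that("connectivity matrices follow the variant constraints", {
  p <- params_w1()
  W <- build_connectivity(wcst_model("w1"), p)
  expect_equal(diag(W$W_lat_e), rep(0, 6))
  expect_equal(W$W_lat_e[1, 2], -2 * p$kappa_e)
  expect_equal(W$W_lat_e, t(W$W_lat_e))
  expect_equal(W$W_dist_ef, t(W$W_dist_fe))
  # excitation pairs exemplar i with feature v(i) only
  expect_equal(which(W$W_dist_fe != 0, arr.ind = TRUE)[, "col"],
               rep(1:3, each = 2), ignore_attr = TRUE)
  # w2 fixes kappa_e = 0, hence no exemplar-level inhibition
  W2 <- build_connectivity(wcst_model("w2"), list(kappa_f = 1, w_dist = 1))
  expect_equal(W2$W_lat_e, matrix(0, 6, 6))
  expect_equal(W2$W_lat_f[1, 2], -2)
  # kappa_e = 1 gives off-diagonal -2
  W1 <- build_connectivity(wcst_model("w1"),
                           list(kappa_e = 1, kappa_f = 1, w_dist = 1))
  expect_equal(W1$W_lat_e[2, 1], -2)
  # diffusive variant: lateral matrices zero, bottom-up excitation only
  Wd <- build_connectivity(wcst_model("d"), list(w_dist = 0.7))
  expect_equal(Wd$W_lat_e, matrix(0, 6, 6))
  expect_equal(Wd$W_lat_f, matrix(0, 3, 3))
  expect_equal(Wd$W_dist_fe, matrix(0, 6, 3))
  expect_equal(Wd$W_dist_ef[1, 1:2], c(0.7, 0.7))
  # Eq-literal toggle restores the top-down coupling
  Wd2 <- build_connectivity(wcst_model("d", d_topdown = TRUE),
                            list(w_dist = 0.7))
  expect_equal(Wd2$W_dist_fe[1, 1], 0.7)
  expect_error(build_connectivity(wcst_model("w1"),
                                  list(kappa_e = -1, kappa_f = 1,
                                       w_dist = 1)))
})

test_that("state propagation has the stated limits", {
  # rd: pure decay, origin is a fixed point
  expect_equal(propagate_mean(rep(0, 6), wcst_model("rd"), params_rd()),
               rep(0, 6))
  # identity limit tau = 1, kappa = 0, w_dist = 0
  m <- wcst_model("d")
  p <- list(tau_e = 1, tau_f = 1, w_dist = 0, eps = 0.25,
            q_e = 0, q_f = 0, mu_e0 = 0, mu_f0 = 0,
            sigma_e0 = 1, sigma_f0 = 1)
  mu <- c(rnorm(9))
  expect_equal(propagate_mean(mu, m, p), mu, tolerance = 1e-12)
})

test_that("WTA iteration preserves and amplifies a unique winner", {
  m <- wcst_model("w1")
  p <- params_w1()
  mu <- c(2, 0, 0, 0, 0, 0, 1, 0, 0)
  for (i in 1:200) mu <- propagate_mean(mu, m, p)
  expect_equal(which.max(mu[1:6]), 1L)
  expect_true(all(mu[1] > mu[2:6]))
  expect_true(all(is.finite(mu)))
  # rw variant likewise on the exemplar level alone
  mrw <- wcst_model("rw")
  prw <- list(eps = 0.25, tau_e = 0.8, kappa_e = 0.6, q_e = 0.1,
              mu_e0 = 0, sigma_e0 = 1)
  mu6 <- c(1.5, 0, 0, 0, 0, 0)
  for (i in 1:200) mu6 <- propagate_mean(mu6, mrw, prw)
  expect_equal(which.max(mu6), 1L)
})

test_that("rd dynamics decay geometrically at rate tau_e", {
  p <- params_rd()
  mu <- c(1, -0.5, 2, 0, 0.3, -1)
  expect_equal(propagate_mean(mu, wcst_model("rd"), p), p$tau_e * mu)
})

test_that("the closed-form Jacobian matches finite differences", {
  set.seed(5)
  for (spec in list(list(wcst_model("w1"), params_w1(), 9),
                    list(wcst_model("w2"), random_params(wcst_model("w2")), 9),
                    list(wcst_model("d"), random_params(wcst_model("d")), 9),
                    list(wcst_model("d", d_topdown = TRUE),
                         random_params(wcst_model("d")), 9),
                    list(wcst_model("rw"), random_params(wcst_model("rw")), 6),
                    list(wcst_model("rd"), params_rd(), 6))) {
    mu <- rnorm(spec[[3]])
    J <- jacobian_g(mu, spec[[1]], spec[[2]])
    J_fd <- pracma::jacobian(function(x) {
      propagate_mean(x, spec[[1]], spec[[2]])
    }, mu)
    expect_equal(J, J_fd, tolerance = 1e-6)
  }
  # rd: linear dynamics, J = tau_e I
  expect_equal(jacobian_g(rnorm(6), wcst_model("rd"), params_rd()),
               params_rd()$tau_e * diag(6))
  # decoupled levels when w_dist = 0
  p0 <- params_w1(); p0$w_dist <- 0
  J0 <- jacobian_g(rnorm(9), wcst_model("w1"), p0)
  expect_equal(J0[1:6, 7:9], matrix(0, 6, 3))
  expect_equal(J0[7:9, 1:6], matrix(0, 3, 6))
})

test_that("belief prediction propagates covariance correctly", {
  # rd with Sigma = s I: cov = tau^2 s I + q I exactly
  p <- params_rd()
  pred <- predict_belief(list(mu = rnorm(6), Sigma = 0.4 * diag(6)),
                         wcst_model("rd"), p)
  expect_equal(pred$Sigma, (p$tau_e^2 * 0.4 + p$q_e) * diag(6))
  # tiny input covariance: output ~ Q
  p2 <- params_w1()
  pred2 <- predict_belief(list(mu = rep(0, 9), Sigma = 1e-14 * diag(9)),
                          wcst_model("w1"), p2)
  expect_equal(pred2$Sigma, diag(c(rep(p2$q_e, 6), rep(p2$q_f, 3))),
               tolerance = 1e-10)
  # symmetric positive definite over random draws
  set.seed(8)
  m <- wcst_model("w1")
  for (i in 1:100) {
    A <- matrix(rnorm(81), 9, 9)
    S <- crossprod(A) / 9 + 0.1 * diag(9)
    pred <- predict_belief(list(mu = rnorm(9), Sigma = S), m, params_w1())
    expect_equal(pred$Sigma, t(pred$Sigma))
    expect_gt(min(eigen(pred$Sigma, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
  }
})

test_that("hypothesis posterior matches the direct normalization oracle", {
  set.seed(9)
  for (i in 1:50) {
    e <- encode_choice(sample(8, 1), sample(c("top", "bottom"), 1))
    g <- rnorm(9)
    eps <- runif(1, 0.05, 0.45)
    hp <- hypothesis_posterior(e, g, eps)
    expect_equal(hp$rho, brute_hypothesis_posterior(e, g[1:6], eps),
                 tolerance = 1e-12)
    expect_equal(sum(hp$rho), 1, tolerance = 1e-12)
    expect_equal(hp$delta[7:9], rep(0, 3))
    expect_equal(hp$Y[7:9, ], matrix(0, 3, 9))
  }
  # eps -> 1/2: evidence uninformative, rho = predicted probabilities
  g <- rnorm(9)
  hp <- hypothesis_posterior(encode_choice(3, "top"), g, 0.4999999)
  expect_equal(hp$rho, hp$pi_pred, tolerance = 1e-5)
  # uniform prediction: (1 - eps)/3 on selected, eps/3 on unselected
  hp2 <- hypothesis_posterior(c(1, 0, 1, 0, 1, 0), rep(0, 9), 0.2)
  expect_equal(hp2$rho, c(0.8, 0.2, 0.8, 0.2, 0.8, 0.2) / 3,
               tolerance = 1e-12)
})

test_that("the Bayesian update equals a Newton step on the variational energy", {
  set.seed(10)
  m <- wcst_model("w1")
  p <- params_w1()
  for (i in 1:5) {
    A <- matrix(rnorm(81), 9, 9)
    belief <- list(mu = rnorm(9, 0, 0.8), Sigma = crossprod(A) / 12 + 0.2 * diag(9))
    pred <- predict_belief(belief, m, p)
    e <- encode_choice(sample(8, 1), "top")
    hyp <- hypothesis_posterior(e, pred$mu, p$eps)
    upd <- bayes_update(pred, hyp)
    # oracle: numeric Newton step on I(h) = E_q(H)[ln p(e, H, h | past)]
    prec_hat <- solve(pred$Sigma)
    I_h <- function(h) {
      log_pi <- h[1:6] - log(sum(exp(h[1:6])))
      sum(hyp$rho * log_pi) -
        0.5 * as.numeric(t(h - pred$mu) %*% prec_hat %*% (h - pred$mu))
    }
    g0 <- richardson_grad(I_h, pred$mu, h = 1e-4)
    H0 <- richardson_hessian(I_h, pred$mu, h = 5e-3)
    newton <- pred$mu - solve(H0, g0)
    expect_equal(upd$mu, as.numeric(newton), tolerance = 1e-8)
  }
})

test_that("the two algebraic forms of the covariance update agree", {
  set.seed(11)
  for (i in 1:20) {
    A <- matrix(rnorm(81), 9, 9)
    Sig_hat <- crossprod(A) / 9 + 0.2 * diag(9)
    pi_pred <- as.numeric(wcstfocus:::.softmax(rnorm(6)))
    Y <- matrix(0, 9, 9)
    Y[1:6, 1:6] <- diag(pi_pred) - tcrossprod(pi_pred)
    form1 <- solve(solve(Sig_hat) + Y)
    form2 <- Sig_hat %*% solve(diag(9) + Y %*% Sig_hat)
    expect_equal(form1, form2, tolerance = 1e-10)
    # and the implementation matches
    upd <- bayes_update(list(mu = rep(0, 9), Sigma = Sig_hat),
                        list(rho = pi_pred, pi_pred = pi_pred,
                             delta = rep(0, 9), Y = Y))
    expect_equal(upd$Sigma, (form1 + t(form1)) / 2, tolerance = 1e-8)
  }
})

test_that("degenerate update inputs reduce to the prediction", {
  A <- matrix(rnorm(81), 9, 9)
  Sig_hat <- crossprod(A) / 9 + 0.3 * diag(9)
  mu_hat <- rnorm(9)
  # zero prediction error: mean unchanged
  pi_pred <- as.numeric(wcstfocus:::.softmax(rnorm(6)))
  Y <- matrix(0, 9, 9)
  Y[1:6, 1:6] <- diag(pi_pred) - tcrossprod(pi_pred)
  upd <- bayes_update(list(mu = mu_hat, Sigma = Sig_hat),
                      list(rho = pi_pred, pi_pred = pi_pred,
                           delta = rep(0, 9), Y = Y))
  expect_equal(upd$mu, mu_hat)
  # no information gain: covariance unchanged
  upd0 <- bayes_update(list(mu = mu_hat, Sigma = Sig_hat),
                       list(rho = pi_pred, pi_pred = pi_pred,
                            delta = rep(0, 9), Y = matrix(0, 9, 9)))
  expect_equal(upd0$Sigma, Sig_hat, tolerance = 1e-8)
})

test_that("the fixed-uncertainty update follows the prediction-error rule", {
  m <- wcst_model("rw", bayesian = FALSE)
  p <- params_nb_rw()
  # alpha = 0: no learning
  p0 <- p; p0$alpha <- 0
  mu <- rnorm(6)
  expect_equal(nonbayes_update(mu, c(1, 0, 1, 0, 1, 0), m, p0),
               propagate_mean(mu, m, p0))
  # from g = 0 with eps_nb = 0.2, alpha = 1: rho - 1/6 shift
  mrd <- wcst_model("rd", bayesian = FALSE)
  prd <- list(eps_nb = 0.2, alpha = 1, tau_e = 0.8, mu_e0 = 0)
  out <- nonbayes_update(rep(0, 6), c(1, 0, 1, 0, 1, 0), mrd, prd)
  expect_equal(out, c(0.8, 0.2, 0.8, 0.2, 0.8, 0.2) - 1 / 6,
               tolerance = 1e-12)
  # eps_nb -> 1/2: uniform shift alpha (1/2 - 1/6)
  p5 <- prd; p5$eps_nb <- 0.4999999; p5$alpha <- 2
  out5 <- nonbayes_update(rep(0, 6), c(0, 1, 1, 0, 0, 1), mrd, p5)
  expect_equal(out5, rep(2 * (0.5 - 1 / 6), 6), tolerance = 1e-5)
})

test_that("run_filter composes the updates and keeps its invariants", {
  m <- wcst_model("w1")
  p <- params_w1()
  b <- sim_block(m, p, seed = 21)
  traj <- run_filter(b, m, p)
  expect_equal(nrow(traj$mu), 41)
  expect_equal(traj$mu[1, ], c(rep(p$mu_e0, 6), rep(p$mu_f0, 3)))
  expect_equal(traj$Sigma[[1]], diag(c(rep(p$sigma_e0, 6), rep(p$sigma_f0, 3))))
  expect_true(all(abs(rowSums(traj$rho) - 1) < 1e-12))
  for (S in traj$Sigma) {
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # empty block: initial state only
  traj0 <- run_filter(b[0, ], m, p)
  expect_equal(nrow(traj0$mu), 1)
  # cards always containing exemplar 1 (red) with the other features mixed:
  # red becomes and stays the winner
  e_rep <- matrix(rep(c(1L, 0L, 1L, 0L, 1L, 0L,
                        1L, 0L, 0L, 1L, 0L, 1L), 20), 40, 6, byrow = TRUE)
  traj1 <- run_filter(e_rep, m, p)
  mu_end <- traj1$mu[41, 1:6]
  expect_equal(which.max(mu_end), 1L)
  expect_true(all(mu_end[1] > mu_end[-1]))
  # non-Bayesian filter keeps the fixed covariance throughout
  mnb <- wcst_model("rw", bayesian = FALSE)
  pnb <- params_nb_rw()
  trajnb <- run_filter(b, mnb, pnb)
  for (S in trajnb$Sigma) expect_equal(S, pnb$alpha * diag(6))
})

test_that("covariances stay symmetric PD over 40-trial runs across draws", {
  set.seed(33)
  m <- wcst_model("w1")
  for (i in 1:100) {
    p <- random_params(m)
    b <- generate_block(task_config(sample(c("switch", "no-switch"), 1)))
    traj <- run_filter(b, m, p)
    eigs <- vapply(traj$Sigma, function(S) {
      min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    }, numeric(1))
    expect_true(all(eigs > 0))
  }
})
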