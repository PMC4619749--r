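test_that("CMA-ES recovers a quadratic optimum and a multimodal global", {
  set.seed(1)
  A <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  a <- c(1.3, -0.7)
  res <- cma_es(function(x) as.numeric(t(x - a) %*% A %*% (x - a)),
                c(0, 0), sigma0 = 0.5, max_eval = 4000)
  expect_equal(res$par, a, tolerance = 1e-4)
  # tilted double well: global minimum on the positive branch
  f <- function(x) (x^2 - 1)^2 + 0.2 * (1 - x)
  grid <- seq(-3, 3, by = 1e-4)
  x_star <- grid[which.min(f(grid))]
  set.seed(2)
  best <- Inf; best_x <- NA
  for (i in 1:10) {
    r <- cma_es(function(x) f(x[1]), rnorm(1, 0, 2), sigma0 = 0.5,
                max_eval = 500)
    if (r$value < best) { best <- r$value; best_x <- r$par }
  }
  expect_equal(best_x, x_star, tolerance = 1e-3)
})

test_that("numerical Hessians are exact for quadratics and match an oracle", {
  A <- matrix(c(3, 1, 0.5, 1, 2, 0.2, 0.5, 0.2, 1.5), 3, 3)
  A <- (A + t(A)) / 2
  H <- numerical_hessian(function(x) -0.5 * sum(x * (A %*% x)), c(0.3, -1, 2))
  expect_equal(H, -A, tolerance = 1e-6)
  sigma <- 0.7
  H1 <- numerical_hessian(function(x) dnorm(x, 0, sigma, log = TRUE), 0.2)
  expect_equal(H1[1, 1], -1 / sigma^2, tolerance = 1e-6)
  f <- function(x) sin(x[1]) * exp(-x[2]^2) + 0.3 * x[1] * x[2]
  x0 <- c(0.4, -0.6)
  expect_equal(numerical_hessian(f, x0), richardson_hessian(f, x0),
               tolerance = 1e-4)
})

test_that("the Laplace evidence matches exact and quadrature references", {
  # 1-D standard normal log-kernel: evidence = log integral exp(-x^2/2)
  lap <- laplace_log_evidence(0, matrix(-1, 1, 1))
  expect_equal(lap$log_evidence, 0.5 * log(2 * pi), tolerance = 1e-12)
  expect_false(lap$regularized)
  # additive constants shift the evidence exactly
  lap_c <- laplace_log_evidence(3.7, matrix(-1, 1, 1))
  expect_equal(lap_c$log_evidence - lap$log_evidence, 3.7)
  # non-PD Hessian is repaired and flagged
  lap_bad <- laplace_log_evidence(0, matrix(c(-1, 0, 0, 0.5), 2, 2))
  expect_true(lap_bad$regularized)
  expect_true(is.finite(lap_bad$log_evidence))
})

test_that("Laplace evidence is within 0.1 nats of quadrature on a 2-parameter fixture", {
  # genuine 2-parameter fixture: a reduced-model log-joint profiled over
  # (eps, theta2) with the remaining parameters pinned
  m <- wcst_model("rd")
  p0 <- params_rd()
  b <- sim_block(m, p0, n_trials = 10, seed = 31)
  chi_full <- to_unconstrained(p0, m)
  idx <- match(c("eps", "theta2"), names(chi_full))
  pr <- prior_spec(m)
  l2 <- function(x) {
    chi <- chi_full
    chi[idx] <- x
    log_joint(chi, b, m, pr)
  }
  opt <- stats::optim(chi_full[idx], function(x) -l2(x), method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  beta <- opt$par
  H <- numerical_hessian(l2, beta)
  lap <- laplace_log_evidence(l2(beta), H)
  # midpoint quadrature over a wide grid around the mode
  sds <- sqrt(diag(lap$S))
  g1 <- seq(beta[1] - 7 * sds[1], beta[1] + 7 * sds[1], length.out = 121)
  g2 <- seq(beta[2] - 7 * sds[2], beta[2] + 7 * sds[2], length.out = 121)
  lvals <- outer(g1, g2, Vectorize(function(x, y) l2(c(x, y))))
  mx <- max(lvals)
  quad <- mx + log(sum(exp(lvals - mx)) * diff(g1)[1] * diff(g2)[1])
  expect_equal(lap$log_evidence, quad, tolerance = 0.1)
})

test_that("log_joint reduces to the prior on empty data and sums per trial", {
  m <- wcst_model("rd")
  p <- params_rd()
  pr <- prior_spec(m)
  chi <- to_unconstrained(p, m)
  b <- sim_block(m, p, n_trials = 3, seed = 41)
  expect_equal(log_joint(chi, b[0, ], m, pr),
               sum(dnorm(chi, 0, sqrt(2), log = TRUE)))
  # independently coded trial-by-trial sum on the 3-trial fixture
  bel <- run_filter(b, m, p)
  r_mat <- clamp_response(as.matrix(b[, c("r_color", "r_motion", "r_shape")]))
  ll <- 0
  for (t in 1:3) {
    pt <- feature_probs(bel$mu[t + 1, ], m)
    mt <- p$theta1 * clr(pt)
    ll <- ll + response_loglik(r_mat[t, ], mt, p$theta2 * diag(3))
  }
  expect_equal(log_joint(chi, b, m, pr),
               ll + sum(dnorm(chi, 0, sqrt(2), log = TRUE)),
               tolerance = 1e-8)
})

test_that("the fused C++ path equals the reference path for every model", {
  set.seed(51)
  for (model in wcst_models()) {
    p <- random_params(model)
    gen_model <- if (model$baseline) wcst_model("rd") else model
    gen_p <- if (model$baseline) params_rd() else p
    b <- sim_block(gen_model, gen_p, n_trials = 12,
                   seed = 60 + nchar(model$id))
    chi <- to_unconstrained(p, model)
    pr <- prior_spec(model)
    expect_equal(log_joint(chi, b, model, pr, engine = "cpp"),
                 log_joint(chi, b, model, pr, engine = "r"),
                 tolerance = 1e-8, label = model$id)
  }
})

test_that("multi-block log-joints restart the filter at block boundaries", {
  m <- wcst_model("rd")
  p <- params_rd()
  pr <- prior_spec(m)
  chi <- to_unconstrained(p, m)
  b1 <- sim_block(m, p, n_trials = 8, seed = 71)
  b2 <- sim_block(m, p, n_trials = 8, seed = 72)
  b2$block <- 2L
  joint <- log_joint(chi, dplyr::bind_rows(b1, b2), m, pr)
  lp <- sum(dnorm(chi, 0, sqrt(2), log = TRUE))
  expect_equal(joint,
               (log_joint(chi, b1, m, pr) - lp) +
                 (log_joint(chi, b2, m, pr) - lp) + lp,
               tolerance = 1e-10)
})

test_that("mode finding is deterministic given a seed", {
  m <- wcst_model("rd")
  p <- params_rd()
  b <- sim_block(m, p, n_trials = 15, seed = 81)
  cfg <- optimizer_config(n_restarts = 2, max_eval = 400, refine_eval = 100,
                          seed = 7)
  f1 <- fit_block(b, m, config = cfg)
  f2 <- fit_block(b, m, config = cfg)
  expect_identical(f1$chi_mode, f2$chi_mode)
  expect_identical(f1$log_evidence, f2$log_evidence)
})

test_that("fitting the generating reduced model recovers the error rate", {
  m <- wcst_model("rd")
  truth <- params_rd()
  set.seed(91)
  dat <- purrr::map_dfr(1:3, function(i) {
    b <- generate_block(task_config("no-switch"), block = i)
    simulate_agent(b, m, truth)
  })
  fit <- fit_block(dat, m,
                   config = optimizer_config(n_restarts = 3, max_eval = 2000,
                                             refine_eval = 1000, seed = 5))
  expect_lt(abs(fit$params$eps - truth$eps), 0.1)
  # the generating model beats the baseline on strong-signal data
  bm <- wcst_model(baseline = TRUE)
  fit_bm <- fit_block(dat, bm,
                      config = optimizer_config(n_restarts = 3,
                                                max_eval = 1500,
                                                refine_eval = 500, seed = 5))
  expect_gt(fit$log_evidence, fit_bm$log_evidence)
  # tidy/glance accessors
  td <- tidy(fit)
  expect_equal(td$term, model_parameters(m)$name)
  expect_true(all(is.finite(td$std.error)))
  expect_equal(glance(fit)$log_evidence, fit$log_evidence)
})

test_that("the baseline fit to unstructured responses is well-behaved", {
  set.seed(101)
  b <- generate_block(task_config("no-switch", n_trials = 20))
  r <- matrix(rexp(60), 20, 3)
  r <- r / rowSums(r)
  b$r_color <- r[, 1]; b$r_motion <- r[, 2]; b$r_shape <- r[, 3]
  bm <- wcst_model(baseline = TRUE)
  fit <- fit_block(b, bm,
                   config = optimizer_config(n_restarts = 2, max_eval = 1500,
                                             refine_eval = 500, seed = 3))
  expect_true(is.finite(fit$log_evidence))
  # location near the clr barycenter of unstructured responses
  expect_lt(max(abs(c(fit$params$mu_f0_1, fit$params$mu_f0_2,
                      fit$params$mu_f0_3))), 1)
})

test_that("duplicating data does not help a mismatched model per block", {
  m <- wcst_model("rd")
  truth <- params_rd()
  b <- sim_block(m, truth, n_trials = 25, seed = 121)
  dup <- dplyr::bind_rows(b, dplyr::mutate(b, block = 2L))
  cfg <- optimizer_config(n_restarts = 2, max_eval = 1000,
                          refine_eval = 600, seed = 8)
  bm <- wcst_model(baseline = TRUE)
  gap1 <- fit_block(b, bm, config = cfg)$log_evidence -
    fit_block(b, m, config = cfg)$log_evidence
  gap2 <- (fit_block(dup, bm, config = cfg)$log_evidence -
             fit_block(dup, m, config = cfg)$log_evidence) / 2
  # per-block evidence advantage of the mismatched baseline cannot grow
  expect_lte(gap2, gap1 + 1)
})

test_that("fit_models produces a tidy evidence table over blocks and models", {
  m <- wcst_model("rd")
  p <- params_rd()
  set.seed(111)
  dat <- purrr::map_dfr(1:2, function(b) {
    simulate_agent(generate_block(task_config("no-switch", n_trials = 12),
                                  block = b), m, p)
  })
  fits <- fit_models(dat, list(wcst_model(baseline = TRUE), m),
                     config = optimizer_config(n_restarts = 1,
                                               max_eval = 400,
                                               refine_eval = 200, seed = 2))
  expect_equal(nrow(fits), 4)
  expect_setequal(fits$model, c("BM", "B_rd_r"))
  expect_true(all(is.finite(fits$log_evidence)))
  ce <- condition_evidence(fits)
  expect_equal(nrow(ce), 2)
  em <- evidence_matrix(ce, "no-switch")
  expect_equal(dim(em), c(1, 2))
})

test_that("condition evidence sums per-block evidences", {
  fits <- tibble::tibble(
    subject = c(1, 1, 1, 2, 2, 2),
    condition = "switch",
    block = c(1, 2, 3, 1, 2, 3),
    model = "B_rd_r",
    log_evidence = c(-10, -12, -11, -20, -21, -19)
  )
  ce <- condition_evidence(fits)
  expect_equal(ce$log_evidence, c(-33, -60))
  expect_equal(ce$n_blocks, c(3L, 3L))
  # permutation invariance
  ce2 <- condition_evidence(fits[sample(6), ])
  expect_equal(dplyr::arrange(ce2, subject), dplyr::arrange(ce, subject))
  # evidence matrix layout
  ce$model <- "A"
  ce2 <- ce; ce2$model <- "B"; ce2$log_evidence <- ce2$log_evidence + 1
  em <- evidence_matrix(dplyr::bind_rows(ce, ce2), "switch")
  expect_equal(dim(em), c(2, 2))
  expect_equal(em[, "B"] - em[, "A"], c(1, 1), ignore_attr = TRUE)
})
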