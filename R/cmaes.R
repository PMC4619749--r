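# Covariance matrix adaptation evolution strategy (CMA-ES), the standard
# (mu/mu_w, lambda) formulation with cumulative step-size adaptation and
# rank-one plus rank-mu covariance updates. Used as the derivative-free mode
# finder for the log-joint, whose surface is multimodal and ill-conditioned
# in the transformed parameter space.

#' Minimize a function with CMA-ES
#'
#' @param fn Objective returning a scalar; non-finite values are treated as
#'   +Inf (rejected candidates).
#' @param x0 Numeric start vector.
#' @param sigma0 Initial global step size.
#' @param max_eval Budget of function evaluations.
#' @param popsize Population size lambda; default `4 + floor(3 log n)`.
#' @param tol_fun Stop when the best value has changed by less than this
#'   over the recent history.
#' @param tol_x Stop when the search distribution collapses below this
#'   scale.
#' @return List with `par`, `value`, `counteval`, `convergence`
#'   (`"tol_fun"`, `"tol_x"` or `"max_eval"`).
#' @export
cma_es <- function(fn, x0, sigma0 = 0.5, max_eval = 2e4, popsize = NULL,
                   tol_fun = 1e-9, tol_x = 1e-12) {
  n <- length(x0)
  lambda <- if (is.null(popsize)) 4L + floor(3 * log(n)) else as.integer(popsize)
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- as.numeric(x0)
  sigma <- sigma0
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n); C <- diag(n); invsqrtC <- diag(n)
  counteval <- 0L
  best_f <- Inf; best_x <- xmean
  hist_len <- 10L + ceiling(30 * n / lambda)
  f_hist <- rep(NA_real_, 0)
  convergence <- "max_eval"

  while (counteval < max_eval) {
    arz <- matrix(stats::rnorm(n * lambda), n, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    fit <- apply(arx, 2, function(x) {
      v <- fn(x)
      if (!is.finite(v)) Inf else v
    })
    counteval <- counteval + lambda
    ord <- order(fit)
    if (fit[ord[1]] < best_f) {
      best_f <- fit[ord[1]]
      best_x <- arx[, ord[1]]
    }
    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- as.numeric(arx[, sel, drop = FALSE] %*% w)
    y_w <- (xmean - xold) / sigma
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(invsqrtC %*% y_w)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * counteval / lambda)) / chiN < 1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * y_w
    artmp <- (arx[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (w * t(artmp))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-24))
    B <- eig$vectors
    invsqrtC <- B %*% ((1 / D) * t(B))

    f_hist <- c(f_hist, fit[ord[1]])
    if (length(f_hist) > hist_len) f_hist <- f_hist[-1]
    if (length(f_hist) == hist_len &&
        is.finite(max(f_hist)) &&
        max(f_hist) - min(f_hist) < tol_fun) {
      convergence <- "tol_fun"
      break
    }
    if (sigma * max(D) < tol_x) {
      convergence <- "tol_x"
      break
    }
  }
  list(par = best_x, value = best_f, counteval = counteval,
       convergence = convergence)
}
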