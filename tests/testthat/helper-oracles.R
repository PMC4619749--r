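# Independent numerical oracles used by the tests. These deliberately avoid
# the package's closed-form code paths.

# central-difference gradient with one Richardson refinement
richardson_grad <- function(f, x, h = 1e-3) {
  g1 <- vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h)
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
  g2 <- vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h / 2)
    (f(x + e) - f(x - e)) / h
  }, numeric(1))
  (4 * g2 - g1) / 3
}

# central-difference Hessian with one Richardson refinement
richardson_hessian <- function(f, x, h = 1e-2) {
  n <- length(x)
  hess_at <- function(hh) {
    H <- matrix(0, n, n)
    f0 <- f(x)
    for (i in seq_len(n)) {
      ei <- replace(numeric(n), i, hh)
      H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hh^2
      for (j in seq_len(n)) {
        if (j <= i) next
        ej <- replace(numeric(n), j, hh)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) +
             f(x - ei - ej)) / (4 * hh^2)
      }
    }
    H
  }
  (4 * hess_at(h / 2) - hess_at(h)) / 3
}

# midpoint-rule integral of a density over the open 2-simplex,
# parametrized by (r1, r2) with r3 = 1 - r1 - r2
simplex_integral <- function(density, n_grid = 400) {
  h <- 1 / n_grid
  u <- seq(h / 2, 1 - h / 2, by = h)
  total <- 0
  for (r1 in u) {
    r2 <- u[u < 1 - r1]
    if (length(r2) == 0) next
    r3 <- 1 - r1 - r2
    vals <- vapply(seq_along(r2), function(k) {
      density(c(r1, r2[k], r3[k]))
    }, numeric(1))
    total <- total + sum(vals) * h * h
  }
  total
}

# brute-force hypothesis posterior: normalize the six likelihood x prior
# products directly
brute_hypothesis_posterior <- function(e, g_e, eps) {
  lik <- ifelse(e == 1, 1 - eps, eps)
  w <- lik * exp(g_e)
  w / sum(w)
}
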