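# Random-effects Bayesian model selection over subjects: a variational
# Dirichlet posterior over model frequencies, exceedance probabilities by
# Monte-Carlo, and the null-protected variant based on the Bayes omnibus
# risk. The variational update and the free-energy bookkeeping are
# re-derived here from the published description of the hierarchical
# random-effects scheme and its 'protected' extension:
#   iterate  z_nk  propto exp(lev_nk + psi(alpha_k) - psi(sum alpha))
#            alpha = alpha0 + sum_n z_n.
# until the alpha update stabilizes; the free energy of the fitted
# alternative is compared with the null (all models equally frequent) to
# give BOR = 1 / (1 + exp(F1 - F0)) and pXP = (1 - BOR) XP + BOR / K.

#' Random-effects BMS over an evidence matrix
#'
#' @param evidence Subjects x models matrix of (per-condition summed) log
#'   model evidences, as from [evidence_matrix()].
#' @param alpha0 Dirichlet prior counts (scalar recycled or length-K
#'   vector; default 1 per model).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities.
#' @param tol Convergence tolerance on the alpha update.
#' @param seed Optional seed for the exceedance sampling.
#' @return Object of class `wcst_bms`: `alpha`, `expected_prob` (EP),
#'   `exceedance_prob` (XP), `protected_xp`, `bor`, `subject_posteriors`
#'   (subjects x models), `free_energy` (alternative) and
#'   `free_energy_null`.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, n_samples = 1e6, tol = 1e-6,
                    seed = NULL) {
  evidence <- as.matrix(evidence)
  stopifnot(ncol(evidence) >= 2, nrow(evidence) >= 1,
            all(is.finite(evidence)))
  n <- nrow(evidence); K <- ncol(evidence)
  alpha0 <- rep_len(alpha0, K)
  alpha <- alpha0 + n / K
  z <- matrix(1 / K, n, K)
  for (iter in seq_len(10000)) {
    w <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1, max)
    z <- exp(w) / rowSums(exp(w))
    alpha_new <- alpha0 + colSums(z)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  ep <- alpha / sum(alpha)
  xp <- exceedance_probability(alpha, n_samples = n_samples, seed = seed)
  f1 <- .bms_free_energy(evidence, alpha, alpha0, z)
  f0 <- sum(apply(evidence, 1, function(l) {
    m <- max(l)
    m + log(mean(exp(l - m)))
  }))
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * xp + bor / K
  structure(
    list(alpha = stats::setNames(alpha, colnames(evidence)),
         expected_prob = stats::setNames(ep, colnames(evidence)),
         exceedance_prob = stats::setNames(xp, colnames(evidence)),
         protected_xp = stats::setNames(pxp, colnames(evidence)),
         bor = bor,
         subject_posteriors = z,
         free_energy = f1, free_energy_null = f0,
         alpha0 = alpha0, models = colnames(evidence)),
    class = "wcst_bms"
  )
}

# variational free energy of the Dirichlet alternative at (alpha, z)
#' @keywords internal
.bms_free_energy <- function(evidence, alpha, alpha0, z) {
  dg <- digamma(alpha) - digamma(sum(alpha))
  e_log_joint <- sum(z * evidence) +
    sum((alpha0 - 1) * dg) + lgamma(sum(alpha0)) - sum(lgamma(alpha0)) +
    sum(colSums(z) * dg)
  entropy_r <- sum(lgamma(alpha)) - lgamma(sum(alpha)) -
    sum((alpha - 1) * dg)
  entropy_z <- -sum(z[z > 0] * log(z[z > 0]))
  e_log_joint + entropy_r + entropy_z
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Monte-Carlo frequency with which each component is the largest in draws
#' from `Dirichlet(alpha)`. For K = 2 the analytic value is the Beta tail
#' probability `P(r_1 > 1/2)`.
#'
#' @param alpha Positive Dirichlet parameter vector.
#' @param n_samples Number of draws.
#' @param seed Optional seed.
#' @return Probability vector summing to 1 (up to Monte-Carlo resolution).
#' @export
#' @examples
#' exceedance_probability(c(2, 1), n_samples = 1e5, seed = 1)  # ~0.75
exceedance_probability <- function(alpha, n_samples = 1e6, seed = NULL) {
  stopifnot(all(alpha > 0))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  K <- length(alpha)
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              n_samples, K)
  wins <- max.col(g, ties.method = "random")
  as.numeric(tabulate(wins, K)) / n_samples
}

#' The four family partitions of the model roster
#'
#' Named partitions used for family-wise comparisons: Bayesian vs
#' non-Bayesian (`bayesian`: BM / NB / B), reduced vs full perceptual
#' hierarchy (`hierarchy`: BM / RP / FP), structure-free vs structured
#' dynamics (`structure`: BM / SFM / SM), and reduced vs full response
#' model (`response`: RR / FR).
#'
#' @return Named list of partitions; each partition is a named list of
#'   character vectors of model ids covering all 17 models exactly once.
#' @export
model_families <- function() {
  ids <- names(wcst_models())
  b <- grep("^B_", ids, value = TRUE)
  nb <- grep("^NB_", ids, value = TRUE)
  reduced <- grep("_(rw|rd)_", ids, value = TRUE)
  structured <- grep("_(w1|w2|w3|rw)_", ids, value = TRUE)
  full_resp <- grep("_f$", ids, value = TRUE)
  list(
    bayesian = list(BM = "BM", NB = nb, B = b),
    hierarchy = list(BM = "BM", RP = reduced, FP = setdiff(c(b, nb), reduced)),
    structure = list(BM = "BM", SFM = setdiff(c(b, nb), structured),
                     SM = structured),
    response = list(RR = c("BM", setdiff(ids, c("BM", full_resp))),
                    FR = full_resp)
  )
}

#' Family-wise random-effects BMS
#'
#' Runs [rfx_bms()] with family-balanced prior counts (`alpha0_k =
#' 1 / |family(k)|`, equal prior mass per family) and aggregates the
#' Dirichlet mass within families: family EP sums member EPs and family
#' XP/pXP are the Monte-Carlo probabilities that a family's total frequency
#' is the largest.
#'
#' @param evidence Subjects x models matrix; column names must match model
#'   ids in the partition.
#' @param partition Named list of character vectors partitioning the
#'   columns (e.g. one element of [model_families()], restricted to the
#'   fitted models).
#' @inheritParams rfx_bms
#' @return Object of class `wcst_bms` at the family level, with an extra
#'   `model_level` entry containing the underlying model-level result.
#' @export
family_bms <- function(evidence, partition, n_samples = 1e6, seed = NULL) {
  evidence <- as.matrix(evidence)
  ids <- colnames(evidence)
  partition <- lapply(partition, intersect, ids)
  partition <- partition[lengths(partition) > 0]
  flat <- unlist(partition, use.names = FALSE)
  if (length(flat) != length(ids) || !setequal(flat, ids) ||
      anyDuplicated(flat)) {
    stop("partition must cover the evidence columns exactly once")
  }
  fam_of <- stats::setNames(
    rep(names(partition), lengths(partition)), flat
  )[ids]
  alpha0 <- 1 / lengths(partition)[fam_of]
  res <- rfx_bms(evidence, alpha0 = as.numeric(alpha0),
                 n_samples = n_samples, seed = seed)
  fam_names <- names(partition)
  agg <- function(v) {
    vapply(fam_names, function(f) sum(v[fam_of == f]), numeric(1))
  }
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed + 1L)
  }
  K <- length(ids)
  g <- matrix(stats::rgamma(n_samples * K,
                            shape = rep(res$alpha, each = n_samples)),
              n_samples, K)
  fam_sum <- vapply(fam_names, function(f) {
    rowSums(g[, fam_of == f, drop = FALSE])
  }, numeric(n_samples))
  wins <- max.col(fam_sum, ties.method = "random")
  fam_xp <- as.numeric(tabulate(wins, length(fam_names))) / n_samples
  fam_pxp <- (1 - res$bor) * fam_xp + res$bor / length(fam_names)
  structure(
    list(alpha = agg(res$alpha),
         expected_prob = agg(res$expected_prob),
         exceedance_prob = stats::setNames(fam_xp, fam_names),
         protected_xp = stats::setNames(fam_pxp, fam_names),
         bor = res$bor,
         subject_posteriors = vapply(fam_names, function(f) {
           rowSums(res$subject_posteriors[, fam_of == f, drop = FALSE])
         }, numeric(nrow(evidence))),
         free_energy = res$free_energy,
         free_energy_null = res$free_energy_null,
         alpha0 = agg(res$alpha0), models = fam_names,
         model_level = res),
    class = "wcst_bms"
  )
}

#' Protected exceedance probabilities
#'
#' Convenience accessor running [rfx_bms()] and returning the
#' null-protected exceedance probabilities together with the Bayes omnibus
#' risk.
#'
#' @inheritParams rfx_bms
#' @return List with `pxp` and `bor`.
#' @export
protected_xp <- function(evidence, alpha0 = 1, n_samples = 1e6,
                         seed = NULL) {
  res <- rfx_bms(evidence, alpha0 = alpha0, n_samples = n_samples,
                 seed = seed)
  list(pxp = res$protected_xp, bor = res$bor)
}

#' @export
print.wcst_bms <- function(x, ...) {
  cat("<wcst_bms>", length(x$alpha), "models/families,",
      nrow(x$subject_posteriors), "subjects; BOR =",
      format(x$bor, digits = 3), "\n")
  tab <- data.frame(ep = round(x$expected_prob, 3),
                    xp = round(x$exceedance_prob, 3),
                    pxp = round(x$protected_xp, 3))
  rownames(tab) <- x$models
  print(tab)
  invisible(x)
}
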