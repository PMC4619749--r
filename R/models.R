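# The 17 behavioral models: a perceptual variant (hidden-state structure x
# Bayesian/non-Bayesian update) paired with a response variant. The full
# response model (theta3 free, response noise coupled to posterior feature
# uncertainty) is only admissible for Bayesian full-hierarchy perceptual
# models, where that uncertainty is a dynamic quantity.

#' Construct a behavioral model specification
#'
#' @param structure Hidden-state structure: `"w1"` (lateral inhibition on
#'   both levels), `"w2"` (feature level only, kappa_e = 0), `"w3"` (exemplar
#'   level only, kappa_f = 0), `"d"` (diffusive, kappa_e = kappa_f = 0),
#'   `"rw"` (reduced, exemplar level only, with inhibition), `"rd"` (reduced
#'   diffusive). Ignored for the baseline model.
#' @param bayesian If `TRUE` beliefs carry a dynamic posterior covariance and
#'   are updated by the variational filter; if `FALSE` the covariance is
#'   fixed at `alpha * I` and the mean update is a Rescorla-Wagner-like
#'   prediction-error rule.
#' @param response `"full"` (theta3 free) or `"reduced"` (theta3 = 0).
#' @param baseline If `TRUE`, the static baseline model BM (constant beliefs;
#'   free parameters: location `mu_f0` as a 3-vector and `theta3`;
#'   theta1 = theta2 = 1 fixed).
#' @param d_topdown For structure `"d"` only: if `TRUE`, keep the
#'   feature-to-exemplar excitation (bidirectional coupling); default `FALSE`
#'   keeps only bottom-up excitation from exemplars to features.
#' @return An object of class `wcst_model`.
#' @export
#' @examples
#' wcst_model("w1", bayesian = TRUE, response = "reduced")
wcst_model <- function(structure = c("w1", "w2", "w3", "d", "rw", "rd"),
                       bayesian = TRUE,
                       response = c("reduced", "full"),
                       baseline = FALSE,
                       d_topdown = FALSE) {
  if (baseline) {
    m <- structure(
      list(id = "BM", structure = NA_character_, bayesian = FALSE,
           reduced = FALSE, response = "reduced", baseline = TRUE,
           d_topdown = FALSE),
      class = "wcst_model"
    )
    return(m)
  }
  structure <- match.arg(structure)
  response <- match.arg(response)
  reduced <- structure %in% c("rw", "rd")
  if (response == "full" && (!bayesian || reduced)) {
    stop("the full response model requires a Bayesian full-hierarchy ",
         "perceptual model (dynamic feature-level uncertainty)")
  }
  id <- paste0(if (bayesian) "B" else "NB", "_", structure, "_",
               if (response == "full") "f" else "r")
  structure(
    list(id = id, structure = structure, bayesian = bayesian,
         reduced = reduced, response = response, baseline = FALSE,
         d_topdown = isTRUE(d_topdown)),
    class = "wcst_model"
  )
}

#' @export
print.wcst_model <- function(x, ...) {
  cat("<wcst_model>", x$id, "-",
      length(model_parameters(x)$name), "free parameters\n")
  invisible(x)
}

#' The full 17-model roster
#'
#' BM; the eight Bayesian full-hierarchy models (d, w1, w2, w3 crossed with
#' the full and reduced response models); the two Bayesian reduced models
#' (rw, rd, reduced response only); and the six non-Bayesian models (all
#' structures, reduced response only).
#'
#' @return A named list of 17 [wcst_model()] objects, in canonical order.
#' @export
wcst_models <- function() {
  full_structs <- c("w1", "w2", "w3", "d")
  models <- list(wcst_model(baseline = TRUE))
  for (s in full_structs) {
    for (resp in c("full", "reduced")) {
      models <- c(models, list(wcst_model(s, TRUE, resp)))
    }
  }
  for (s in c("rw", "rd")) {
    models <- c(models, list(wcst_model(s, TRUE, "reduced")))
  }
  for (s in c("w1", "w2", "w3", "d", "rw", "rd")) {
    models <- c(models, list(wcst_model(s, FALSE, "reduced")))
  }
  names(models) <- vapply(models, `[[`, character(1), "id")
  models
}

#' Free parameters of a model
#'
#' Each model is fit in a transformed space where every parameter lives on
#' the whole real line. The transform depends on the native domain:
#' `log` for positive parameters (kappa, q, w_dist, sigma0, alpha, theta),
#' `eps` (`log(2z / (1 - 2z))`) for probabilities in (0, 1/2),
#' `tau` (`log((2z - 1) / (2 (1 - z)))`) for decay constants in (1/2, 1),
#' and `identity` for the unconstrained initial means.
#'
#' @param model A [wcst_model()].
#' @return A tibble with columns `name` and `transform`, in the canonical
#'   order used by the transformed parameter vector.
#' @export
#' @examples
#' model_parameters(wcst_model("rd"))
model_parameters <- function(model) {
  stopifnot(inherits(model, "wcst_model"))
  if (model$baseline) {
    return(tibble::tibble(
      name = c("mu_f0_1", "mu_f0_2", "mu_f0_3", "theta3"),
      transform = c("identity", "identity", "identity", "log")
    ))
  }
  s <- model$structure
  nm <- character(0); tr <- character(0)
  add <- function(n, t) {
    nm <<- c(nm, n); tr <<- c(tr, t)
  }
  add(if (model$bayesian) "eps" else "eps_nb", "eps")
  if (!model$bayesian) add("alpha", "log")
  add("tau_e", "tau")
  if (!model$reduced) add("tau_f", "tau")
  if (s %in% c("w1", "w3", "rw")) add("kappa_e", "log")
  if (s %in% c("w1", "w2")) add("kappa_f", "log")
  if (model$bayesian) {
    add("q_e", "log")
    if (!model$reduced) add("q_f", "log")
  }
  if (!model$reduced) add("w_dist", "log")
  add("mu_e0", "identity")
  if (!model$reduced) add("mu_f0", "identity")
  if (model$bayesian) {
    add("sigma_e0", "log")
    if (!model$reduced) add("sigma_f0", "log")
  }
  add("theta1", "log")
  add("theta2", "log")
  if (model$response == "full") add("theta3", "log")
  tibble::tibble(name = nm, transform = tr)
}

# scalar forward/inverse transforms
#' @keywords internal
.fwd_transform <- function(z, kind) {
  switch(kind,
    log = log(z),
    eps = log(2 * z / (1 - 2 * z)),
    tau = log((2 * z - 1) / (2 * (1 - z))),
    identity = z,
    stop("unknown transform: ", kind)
  )
}

#' @keywords internal
.inv_transform <- function(x, kind) {
  switch(kind,
    log = exp(x),
    eps = stats::plogis(x) / 2,
    tau = (2 * exp(x) + 1) / (2 * exp(x) + 2),
    identity = x,
    stop("unknown transform: ", kind)
  )
}

#' Map native parameters to the unconstrained fitting space
#'
#' @param params Named list or vector of native-scale parameters; must
#'   contain every free parameter of `model` within its domain.
#' @param model A [wcst_model()].
#' @return Named numeric vector chi in the canonical parameter order.
#' @export
#' @examples
#' to_unconstrained(list(eps = 0.25, tau_e = 0.75, q_e = 1, mu_e0 = 0,
#'                       sigma_e0 = 1, theta1 = 1, theta2 = 1),
#'                  wcst_model("rd"))
to_unconstrained <- function(params, model) {
  info <- model_parameters(model)
  params <- as.list(params)
  missing <- setdiff(info$name, names(params))
  if (length(missing) > 0) {
    stop("missing parameters: ", paste(missing, collapse = ", "))
  }
  chi <- vapply(seq_len(nrow(info)), function(i) {
    z <- params[[info$name[i]]]
    x <- .fwd_transform(z, info$transform[i])
    if (!is.finite(x)) stop("parameter out of domain: ", info$name[i],
                            " = ", z)
    x
  }, numeric(1))
  stats::setNames(chi, info$name)
}

#' Map an unconstrained vector back to native parameters
#'
#' @param chi Numeric vector in canonical order (names optional).
#' @param model A [wcst_model()].
#' @return Named list of native-scale parameters, with the model's fixed
#'   parameters (structural zeros; baseline theta1 = theta2 = 1) filled in.
#' @export
from_unconstrained <- function(chi, model) {
  info <- model_parameters(model)
  stopifnot(length(chi) == nrow(info))
  out <- lapply(seq_len(nrow(info)), function(i) {
    .inv_transform(chi[[i]], info$transform[i])
  })
  names(out) <- info$name
  complete_parameters(out, model)
}

#' Fill in a model's fixed parameters
#'
#' Adds the structurally fixed values (zeros for absent couplings and noise
#' terms, `theta3 = 0` for the reduced response model, `theta1 = theta2 = 1`
#' for the baseline model) so the result can drive the belief filter.
#'
#' @param params Named list of the model's free parameters.
#' @param model A [wcst_model()].
#' @return Named list covering the full parameter set.
#' @export
complete_parameters <- function(params, model) {
  p <- as.list(params)
  defaults <- list(
    eps = 0.25, eps_nb = 0.25, alpha = 0, tau_e = 1, tau_f = 1,
    kappa_e = 0, kappa_f = 0, q_e = 0, q_f = 0, w_dist = 0,
    mu_e0 = 0, mu_f0 = 0, sigma_e0 = 1, sigma_f0 = 1,
    theta1 = 1, theta2 = 1, theta3 = 0,
    mu_f0_1 = 0, mu_f0_2 = 0, mu_f0_3 = 0
  )
  for (nm in names(defaults)) {
    if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  }
  p
}
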