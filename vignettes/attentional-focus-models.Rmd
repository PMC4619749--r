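---
title: "Belief updating under attentional focus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief updating under attentional focus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcstfocus)
```

## The task and what the package models

In a probabilistic Wisconsin card sorting task with belief solicitation, a
subject watches an experimenter choose between two cards. Each card carries
one exemplar of each of three binary visual features (red/green color,
left/right motion, circle/square shape), and the two cards are complementary,
so there are eight stimulus configurations. A hidden selection rule — one of
six exemplar–feature pairs — determines which card the experimenter "should"
pick; the experimenter errs with probability $\varepsilon$ (0.2 in the
no-switch condition, 0.3 in the switch condition). In switch blocks the
relevant feature changes with probability $p = 0.35$ per trial once at least
8 trials have passed since the last change; blocks have $T = 40$ trials. The
subject reports beliefs each trial by distributing \$20 over the three
features (a point on the 2-simplex), and is paid by the money placed on the
truly relevant feature of one randomly selected trial.

`wcstfocus` implements the full analysis stack for such data: the task
simulator, seventeen competing behavioral models that map the observation
sequence to responses, per-block Laplace model evidence via derivative-free
optimization, and random-effects Bayesian model selection across subjects,
with family-wise comparisons.

## Perceptual models

Beliefs are carried by a hidden state $h = (h^{(e)}, h^{(f)})$ with six
exemplar-relevance and (in full-hierarchy variants) three feature-relevance
components. The deterministic part of the state transition is

$$ g_e(h) = \tau_e h^{(e)} + \kappa_e + W^{(e)}_{lat}\,\varphi(h^{(e)} - \kappa_e)
   + W_{dist}^{(fe)}\,\varphi(h^{(f)} - \kappa_f), $$

with the analogous feature-level map and $\varphi$ the logistic function.
Lateral inhibition of strength $w_{lat} = 2\kappa$ (zero diagonal, constant
negative off-diagonal) implements winner-take-all competition — the
attentional-focus mechanism: one high component suppresses the others, and
process noise of variance $q$ mediates switching between attractors.
Symmetric excitation $w_{dist}$ couples each exemplar to its feature.

Six structures are distinguished by which couplings exist:

* `w1`: inhibition on both levels ($\kappa_e, \kappa_f$ free);
* `w2`: feature-level inhibition only ($\kappa_e = 0$);
* `w3`: exemplar-level inhibition only ($\kappa_f = 0$);
* `d`: diffusive (both $\kappa = 0$) — no attentional focus;
* `rw`, `rd`: reduced variants without the feature level (with and without
  inhibition).

For the diffusive structure the connectivity figure of record shows
bottom-up excitation only, while the transition equations at $\kappa = 0$
would keep both directions; we default to the bottom-up-only reading and
expose `d_topdown = TRUE` on `wcst_model()` for the literal bidirectional
variant. Both are implemented; nothing in the package depends on which is
chosen.

**Bayesian updates.** Observing the chosen card as a binary 6-vector $e$
with likelihood $(1-\varepsilon)$ per selected exemplar and $\varepsilon$
otherwise, the filter forms the predicted state
$\hat b = \{g(\mu), J \Sigma J^\top + Q\}$ by linearization, the hypothesis
posterior $\rho_k \propto p(e_k|\varepsilon)\, e^{g_k}$, and the update

$$ \Sigma_t = (\hat\Sigma^{-1} + Y)^{-1}, \qquad
   \mu_t = g(\mu_{t-1}) + \Sigma_t\,\delta, $$

with $\delta = (\rho - \pi, 0_3)$ the prediction error against
$\pi = \mathrm{softmax}(g_e)$ and $Y = (\mathrm{diag}\,\pi - \pi\pi^\top)
\oplus 0$. This is exactly one Newton step on the quadratic expansion of the
variational energy around the predicted mean — the test suite checks the
implementation against a numerically computed Newton step at $10^{-8}$.
The covariance update is computed in the symmetric form above
(algebraically equal to the matrix-fraction form
$\hat\Sigma(I + Y\hat\Sigma)^{-1}$; the equivalence is a test), symmetrized,
with a $10^{-8}$ diagonal jitter retry if a Cholesky factorization fails.

**Non-Bayesian updates.** Fixing the covariance at $\alpha I$ yields a
Rescorla–Wagner-like rule
$\mu^{(e)} \leftarrow g_e(\mu) + \alpha(\rho - \mathrm{softmax}(g_e(\mu)))$
with evidence $\rho_k = 1 - \epsilon$ or $\epsilon$ (kept unnormalized, as
the update rule defines it; `eps_nb` is a free parameter distinct from the
Bayesian $\varepsilon$).

## Response models

Feature-relevance probabilities come from the feature level
($p = \mathrm{softmax}(\mu_f)$) or, in reduced variants, from exemplar sums.
The risk-adjusted optimal allocation is $r = p^{\theta_1}/\sum_j
p_j^{\theta_1}$; $\theta_1$ is an inverse risk factor ($\theta_1 \to 0$
yields uniform hedging). Stochastic responses perturb this on log scale with
$\xi \sim N(0, P)$, $P = \theta_2 I + \theta_3 \Sigma^{(f)}$: constant
response noise plus a component proportional to posterior uncertainty. The
*full* response model frees $\theta_3$; the *reduced* one fixes
$\theta_3 = 0$. The likelihood of an observed allocation is the
logistic-normal density

$$ p(r \mid b, \theta) = \frac{N(\mathrm{clr}(r);\, m, P)}
   {3\, r_1 r_2 r_3\, Z(m, P)}, \qquad
   Z = (2\pi\, a^\top P a)^{-1/2} \exp\!\left(-\frac{(a^\top m)^2}
   {2\, a^\top P a}\right), $$

with $m = \theta_1 \mu_f$ (full hierarchy) or $\theta_1\,\mathrm{clr}(p)$
(reduced), $a = (1,1,1)^\top$, and clr the centered log-ratio transform.
$Z$ is the Gaussian mass on the zero-sum plane; dividing by it makes the
density integrate to one over the simplex, which the test suite verifies by
quadrature ($\pm 0.01$). Observed responses are clamped to the simplex
interior (floor $10^{-3}$, renormalized) before taking log-ratios, since
cursor responses can touch the corners of the response triangle; the floor
is a `floor_at` argument throughout.

The roster of seventeen models (`wcst_models()`) pairs every Bayesian
full-hierarchy structure with both response models, the Bayesian reduced and
all non-Bayesian structures with the reduced response model only (their
feature-level uncertainty is not dynamic), and adds a static baseline `BM`
whose only parameters are a free 3-vector location `mu_f0` and extra
isotropic variance $\theta_3$ (with $\theta_1 = \theta_2 = 1$ fixed). The
baseline location is a vector rather than a shared scalar because a
symmetric location would pin the baseline to the simplex center and make it
useless as a null model; all dynamic models use shared per-level scalar
initial means, which avoids building a feature bias into the prior state.

## Model inversion

Parameters are fitted in a transformed space where every parameter is
real-valued: $\ln$ for positive parameters, $\ln(2z/(1-2z))$ for error rates
in $(0, 1/2)$, and $\ln((2z-1)/(2(1-z)))$ for the decay constants — the
latter is the sign-corrected form; the alternative sign convention is not
real-valued on $(1/2, 1)$, which fixes the domain of $\tau$. The prior is
$N(\eta_0, s_o I)$ with $\eta_0 = 0$ (native scale: $\varepsilon = 0.25$,
$\tau = 0.75$, positive parameters at 1, initial means 0) and $s_o = 2$: wide
enough to be weakly informative, tight enough that the Laplace approximation
stays well-behaved. Both are arguments of `prior_spec()`.

The log-joint (response log-likelihood summed over trials plus the log
prior) is maximized by CMA-ES, restarted `n_restarts` times (the study
setting is 50; desk-scale analyses here use 5) from starts drawn around the
prior mean at half the prior scale — starts in the far prior tails routinely
place the belief filter in a numerically explosive regime and waste the
restart. Each restart's solution is polished by two short CMA-ES runs with
step sizes $\sigma_0/5$ and $\sigma_0/25$, which sharpens the mode before
curvature is measured. For every restart the Hessian at the mode is
estimated by Richardson-extrapolated central differences and the Laplace
log-evidence $l(\beta) + \tfrac12 \ln |2\pi S|$, $S = -H^{-1}$, is computed;
the restart with the largest evidence is kept. Because the log-joint
contains the Gaussian prior, its true curvature can never be flatter than
the prior precision $1/s_o$ in any direction; eigenvalues of $-H$ below
that floor — which arise from genuinely soft likelihood ridges and from
derivative noise on the filter's rough likelihood surface, and whose
minimal repair would inflate the evidence by several nats per direction —
are floored at $1/s_o$ and the fit is flagged as regularized. The belief filter and response likelihood are
fused in C++ for the optimizer's inner loop; a pure-R reference path
composes the exported functions, and a test pins the two to $10^{-8}$
agreement across all seventeen models.

## Random-effects model selection

Per-subject, per-condition evidences (block evidences summed within
condition) enter a variational Dirichlet model of model frequencies:
iterate subject responsibilities
$z_{nk} \propto \exp(\mathrm{lev}_{nk} + \psi(\alpha_k) - \psi(\sum\alpha))$
and counts $\alpha = \alpha_0 + \sum_n z_n$ to convergence ($10^{-6}$).
Expected probabilities are $\alpha/\sum\alpha$; exceedance probabilities are
Monte-Carlo frequencies of being the largest frequency in $10^6$ seeded
Dirichlet draws (for $K = 2$ the analytic Beta tail is the cross-check).
The Bayes omnibus risk compares the variational free energy of this
alternative against the exact evidence of the null model in which all models
are equally frequent, $\mathrm{BOR} = (1 + e^{F_1 - F_0})^{-1}$, and the
protected exceedance probability is
$(1-\mathrm{BOR})\,\mathrm{XP} + \mathrm{BOR}/K$. For identical evidence
columns the exact null-vs-alternative Bayes factor is 1, so BOR sits above
$1/2$ (approaching 1 slowly with the number of subjects through the
variational bound) and the protected probabilities are pulled to uniform.
Family comparisons use family-balanced prior counts
($\alpha_{0k} = 1/|\mathrm{family}(k)|$) and aggregate Dirichlet mass within
families; the four roster partitions (Bayesian vs non-Bayesian, reduced vs
full hierarchy, structure-free vs structured, reduced vs full response) are
in `model_families()`.

## The synthetic-data generator

`generate_cohort()` emulates the study design: 22 subjects by default, each
with three switch and three no-switch blocks of 40 trials under the design
settings above, responses generated by any roster model acting as a forward
agent. Ground-truth parameters are drawn per subject;
`default_parameter_sampler()` uses uniform ranges chosen so that agents
actually learn without saturating: subjective error rates 0.2–0.3
(bracketing the design values), decay constants 0.65–0.8, inhibition
thresholds and inter-level excitation 0.3–0.6, process noise 0.05–0.15,
inverse risk factor 1.2–2, response noise 0.05–0.15. Outside this regime the
dynamics either barely move (beliefs stay near the simplex center and the
response parameters lose identifiability) or saturate hard (states grow to
$|h| \sim 10$, responses pin to the triangle corners and the clamped
likelihood degrades); the chosen ranges reproduce the qualitative behavioral
signature of the task — higher earnings in no-switch than switch blocks.

What the generator does *not* emulate: reaction times, cursor kinematics,
training effects across blocks, or any discreteness in the money
allocation. Passing recovery tests on this generator therefore show that
the inversion machinery is self-consistent, not that real subjects satisfy
the model's assumptions.

## Numerical choices and degenerate inputs

* Covariance updates are symmetrized at every step; Cholesky failures fall
  back to a $10^{-8}$ diagonal jitter.
* Softmax and feature-probability computations are max-shifted against
  overflow.
* Non-finite log-likelihoods (explosive dynamics under extreme candidate
  parameters) are returned as $-\infty$ and treated by the optimizer as
  rejected candidates.
* A zero response covariance is honored as the deterministic limit in
  `sample_response()`.
* Empty blocks are legal: the filter returns its initial state and the
  log-joint reduces to the prior density.
* The exceedance sampler uses $10^6$ draws (resolution $\sim 10^{-3}$);
  seeded.

## Problem sizes used in the checks

The package's own validation studies are run at desk scale: simulator
frequencies use 5,000 rule sequences and 250-block stimulus sets; the
parameter-recovery study uses 10 subjects with six 40-trial blocks each,
fitted with 5 optimizer restarts; the model-recovery study uses 16 subjects
with two blocks each and two candidate models. Quadrature checks of the
response likelihood use midpoint grids of about 250 points per simplex
edge.

## Known limitations

* **Ridge-limited identifiability of the full structured model.** For the
  12-parameter `w1` perceptual model (plus two response parameters), the
  log-joint has soft ridges along which the subjective error rate trades
  off against process noise and inhibition strength: fits of six blocks per
  agent recover the decay constant $\tau_e$ reliably, but posterior modes of
  $\varepsilon$ (and, less severely, $\theta_1$) scatter well beyond
  $\pm 20\%$ of the generating values even when the optimizer demonstrably
  reaches the global mode. The reduced models do not show this (the
  7-parameter `rd` recovery test pins $\varepsilon$ within $\pm 0.1$). This
  is a property of the model-data geometry at realistic data sizes, not of
  the optimizer; recovering sharp per-subject estimates of $\varepsilon$
  under `w1` would need substantially more data or informative priors.
* The full response model's generative draw perturbs the optimal response
  by a projected Gaussian, while its likelihood conditions the Gaussian on
  the zero-sum plane; for anisotropic $P$ these differ slightly. This is
  inherited from the model definition and only affects `_f` variants.
* CMA-ES restarts at the study's published setting (50) are expensive; the
  desk-scale default here is 5 restarts with a local refinement chain,
  which empirically matters more than raw restart count on these surfaces.
* Model evidences are Laplace approximations; strongly non-Gaussian
  posteriors (boundary modes) are flagged via the regularization indicator
  rather than corrected.

## A worked example

```{r example, eval = FALSE}
library(wcstfocus)

# simulate one agent with attentional-focus dynamics
model <- wcst_model("w1", bayesian = TRUE, response = "reduced")
params <- list(eps = 0.25, tau_e = 0.75, tau_f = 0.75, kappa_e = 0.5,
               kappa_f = 0.5, q_e = 0.1, q_f = 0.1, w_dist = 0.5,
               mu_e0 = 0, mu_f0 = 0, sigma_e0 = 1, sigma_f0 = 1,
               theta1 = 1.6, theta2 = 0.05)
set.seed(1)
block <- generate_block(task_config("no-switch")) |>
  simulate_agent(model, params)

# invert a competing pair of models and compare
fit_w1 <- fit_block(block, model,
                    config = optimizer_config(n_restarts = 5,
                                              max_eval = 3000, seed = 1))
fit_rd <- fit_block(block, wcst_model("rd"),
                    config = optimizer_config(n_restarts = 5,
                                              max_eval = 3000, seed = 1))
glance(fit_w1)$log_evidence - glance(fit_rd)$log_evidence

# beliefs under the fitted parameters
autoplot(run_filter(block, model, fit_w1$params))
```
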