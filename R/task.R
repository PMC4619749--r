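# Task structure: 3 binary visual features (color, motion, shape), each with
# two exemplars. The canonical exemplar order is fixed so that the binary
# observation vector e and the connectivity layout are bit-exact everywhere:
# exemplars (red, green, left, right, circle, square), features
# (color, motion, shape); exemplars 2j-1, 2j belong to feature j.

#' @keywords internal
.exemplars <- c("red", "green", "left", "right", "circle", "square")

#' @keywords internal
.features <- c("color", "motion", "shape")

# feature index of each exemplar: v(i)
#' @keywords internal
.exemplar_feature <- rep(1:3, each = 2L)

#' The six selection-rule hypotheses
#'
#' Each hypothesis states that the experimenter selects cards containing one
#' specific exemplar. With three binary features there are six hypotheses.
#'
#' @return A tibble with columns `hypothesis` (1..6), `exemplar` (label) and
#'   `feature` (the feature the exemplar belongs to).
#' @export
#' @examples
#' hypotheses()
hypotheses <- function() {
  tibble::tibble(
    hypothesis = 1:6,
    exemplar = .exemplars,
    feature = .features[.exemplar_feature]
  )
}

#' Enumerate the eight card-pair configurations
#'
#' A visual stimulus is a pair of cards (top, bottom); each card carries one
#' exemplar of every feature and the two cards are complementary, giving
#' 2^3 = 8 distinct configurations. The top card's exemplar indices identify a
#' configuration; the bottom card carries the complementary exemplars.
#'
#' @return A tibble with 8 rows and columns `pair_id`, `top_color`,
#'   `top_motion`, `top_shape` (exemplar labels on the top card). Bottom-card
#'   exemplars are the complements within each feature.
#' @export
#' @examples
#' card_configurations()
card_configurations <- function() {
  grid <- expand.grid(
    top_shape = .exemplars[5:6],
    top_motion = .exemplars[3:4],
    top_color = .exemplars[1:2],
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    pair_id = 1:8,
    top_color = grid$top_color,
    top_motion = grid$top_motion,
    top_shape = grid$top_shape
  )
}

# exemplar indices (1..6) on the top card of configuration `pair_id`
#' @keywords internal
.top_exemplars <- function(pair_id) {
  cfg <- card_configurations()[pair_id, ]
  c(
    match(cfg$top_color, .exemplars),
    match(cfg$top_motion, .exemplars),
    match(cfg$top_shape, .exemplars)
  )
}

#' Encode a card choice as a binary exemplar-presence vector
#'
#' The observation shown to the subject is which card the experimenter chose;
#' it is encoded as a binary 6-vector e whose k-th component is 1 iff
#' exemplar k is present on the chosen card. Exactly three components are 1
#' (one exemplar per feature).
#'
#' @param pair_id Configuration index in 1..8 (see [card_configurations()]).
#' @param chosen_card `"top"` or `"bottom"`.
#' @return Integer vector of length 6 in canonical exemplar order
#'   (red, green, left, right, circle, square).
#' @export
#' @examples
#' encode_choice(1, "top") + encode_choice(1, "bottom")  # complementary cards
encode_choice <- function(pair_id, chosen_card = c("top", "bottom")) {
  chosen_card <- match.arg(chosen_card)
  top <- .top_exemplars(pair_id)
  e <- integer(6)
  e[top] <- 1L
  if (chosen_card == "bottom") e <- 1L - e
  e
}

#' Task design configuration
#'
#' Bundles the design parameters of one experimental block. Defaults follow
#' the study design: blocks of 40 trials; in the switch condition the
#' relevant feature changes with probability 0.35 once at least 8 trials have
#' elapsed since the last change, and the experimenter errs with probability
#' 0.3; in the no-switch condition the rule is constant and the error rate is
#' 0.2.
#'
#' @param condition `"switch"` or `"no-switch"`.
#' @param n_trials Trials per block (default 40).
#' @param error_rate Experimenter error probability in (0, 1/2); default 0.3
#'   for switch, 0.2 for no-switch.
#' @param switch_prob Per-eligible-trial rule-change probability in `[0, 1)`;
#'   default 0.35 for switch, 0 for no-switch.
#' @param min_run Refractory period: minimum number of trials the rule stays
#'   fixed after a change (block start counts as a change). Default 8.
#' @param switch_within_feature If `TRUE`, a rule change may re-select the
#'   other exemplar of the currently relevant feature; the default `FALSE`
#'   changes the relevant feature, drawing uniformly among the four
#'   hypotheses of the other two features.
#' @return A list of class `wcst_task_config`.
#' @export
task_config <- function(condition = c("switch", "no-switch"),
                        n_trials = 40L,
                        error_rate = NULL,
                        switch_prob = NULL,
                        min_run = 8L,
                        switch_within_feature = FALSE) {
  condition <- match.arg(condition)
  if (is.null(error_rate)) error_rate <- if (condition == "switch") 0.3 else 0.2
  if (is.null(switch_prob)) switch_prob <- if (condition == "switch") 0.35 else 0
  stopifnot(
    n_trials >= 0, min_run >= 1,
    error_rate > 0, error_rate < 0.5,
    switch_prob >= 0, switch_prob < 1
  )
  structure(
    list(
      condition = condition, n_trials = as.integer(n_trials),
      error_rate = error_rate, switch_prob = switch_prob,
      min_run = as.integer(min_run),
      switch_within_feature = isTRUE(switch_within_feature)
    ),
    class = "wcst_task_config"
  )
}

#' Generate a hidden rule sequence
#'
#' The initial hypothesis is uniform over the six rules. On every trial at
#' which at least `min_run` trials have elapsed since the last change (the
#' block start counts as a change, so the earliest possible change is trial
#' `min_run + 1`), the rule changes with probability `switch_prob`. A change
#' draws the new hypothesis uniformly among the four hypotheses whose feature
#' differs from the current one (or among all five others if
#' `switch_within_feature`).
#'
#' @param config A [task_config()].
#' @return Integer vector of hypothesis indices (1..6), length `n_trials`.
#' @export
generate_rule_sequence <- function(config) {
  stopifnot(inherits(config, "wcst_task_config"))
  n <- config$n_trials
  if (n == 0L) return(integer(0))
  h <- integer(n)
  h[1] <- sample.int(6L, 1L)
  since_change <- 1L
  for (t in seq_len(n - 1L) + 1L) {
    if (since_change >= config$min_run &&
        stats::runif(1) < config$switch_prob) {
      cur_feature <- .exemplar_feature[h[t - 1L]]
      cand <- if (config$switch_within_feature) {
        setdiff(1:6, h[t - 1L])
      } else {
        which(.exemplar_feature != cur_feature)
      }
      h[t] <- cand[sample.int(length(cand), 1L)]
      since_change <- 1L
    } else {
      h[t] <- h[t - 1L]
      since_change <- since_change + 1L
    }
  }
  h
}

#' Generate one experimental block
#'
#' Draws, per trial, a card-pair configuration uniformly from the eight, an
#' experimenter error with probability `error_rate`, and the chosen card: the
#' card containing the currently relevant exemplar when no error occurs, the
#' other card otherwise. Responses are absent (`NA`) until an agent is
#' simulated with [simulate_agent()].
#'
#' @param config A [task_config()].
#' @param block Integer block label.
#' @param subject Subject label.
#' @return A tibble with one row per trial: `subject`, `condition`, `block`,
#'   `trial`, `pair_id`, `top_color`, `top_motion`, `top_shape`,
#'   `chosen_card`, `e_red` ... `e_square`, `true_hypothesis`,
#'   `relevant_feature`, `experimenter_error`, `r_color`, `r_motion`,
#'   `r_shape`.
#' @export
#' @examples
#' set.seed(1)
#' generate_block(task_config("no-switch", n_trials = 5))
generate_block <- function(config, block = 1L, subject = 1L) {
  stopifnot(inherits(config, "wcst_task_config"))
  n <- config$n_trials
  hyp <- generate_rule_sequence(config)
  pair_id <- sample.int(8L, n, replace = TRUE)
  err <- stats::runif(n) < config$error_rate
  cfg <- card_configurations()
  top_mat <- vapply(pair_id, .top_exemplars, integer(3))
  # relevant exemplar on top card?
  rel_on_top <- vapply(seq_len(n), function(t) hyp[t] %in% top_mat[, t], logical(1))
  chosen <- ifelse(xor(rel_on_top, err), "top", "bottom")
  e <- t(vapply(seq_len(n), function(t) encode_choice(pair_id[t], chosen[t]),
                integer(6)))
  colnames(e) <- paste0("e_", .exemplars)
  tibble::tibble(
    subject = subject,
    condition = config$condition,
    block = as.integer(block),
    trial = seq_len(n),
    pair_id = pair_id,
    top_color = cfg$top_color[pair_id],
    top_motion = cfg$top_motion[pair_id],
    top_shape = cfg$top_shape[pair_id],
    chosen_card = chosen,
    tibble::as_tibble(e),
    true_hypothesis = hyp,
    relevant_feature = .exemplar_feature[hyp],
    experimenter_error = err,
    r_color = NA_real_, r_motion = NA_real_, r_shape = NA_real_
  )
}

#' Convert simplex responses to money allocations
#'
#' Subjects distribute $20 over the three visual features; a response on the
#' 2-simplex maps to dollars by scaling, so every allocation sums to $20.
#'
#' @param r A length-3 simplex vector, or an n x 3 matrix / data frame of
#'   simplex rows.
#' @return Numeric vector or matrix of dollar amounts (rows sum to 20).
#' @export
#' @examples
#' response_to_money(c(1 / 3, 1 / 3, 1 / 3))
response_to_money <- function(r) {
  if (is.data.frame(r)) r <- as.matrix(r)
  20 * r
}

# e-columns of a trial tibble as a T x 6 integer matrix
#' @keywords internal
block_e_matrix <- function(trials) {
  as.matrix(trials[paste0("e_", .exemplars)])
}

# response columns as a T x 3 matrix
#' @keywords internal
block_r_matrix <- function(trials) {
  as.matrix(trials[c("r_color", "r_motion", "r_shape")])
}
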