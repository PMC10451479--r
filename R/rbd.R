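# Economic (ideal-observer) scoring of PRT behavior. The task is modelled
# as equal-variance Gaussian signal detection: evidence ~ N(+d'/2, 1) on
# rich trials and N(-d'/2, 1) on lean trials, respond "rich" iff evidence
# exceeds the criterion c. Positive c favors "lean" responses; the
# reward-maximizing criterion under the asymmetric payoff lies below zero.

#' Payoff structure of the probabilistic reward task
#'
#' Describes the economic environment of one PRT block: reward magnitude,
#' the per-stimulus probabilities that a correct response is rewarded, the
#' stimulus presentation probability, and an optional per-trial effort cost.
#' The default 3:1 asymmetry (0.6 vs 0.2) corresponds to 30 rich and 10 lean
#' rewards scheduled per 100-trial block with equiprobable stimuli.
#'
#' @param reward_cents reward magnitude in cents (default 20).
#' @param p_reward_given_correct_rich,p_reward_given_correct_lean
#'   probability that a correct rich (lean) identification is rewarded.
#' @param stimulus_probability_rich probability a trial shows the rich
#'   stimulus (default 0.5).
#' @param effort_cost_cents flat per-trial effort cost in cents (default 0;
#'   it cancels from expected-value differences).
#' @return An object of class `payoff_structure`.
#' @export
payoff_structure <- function(reward_cents = 20,
                             p_reward_given_correct_rich = 0.6,
                             p_reward_given_correct_lean = 0.2,
                             stimulus_probability_rich = 0.5,
                             effort_cost_cents = 0) {
  probs <- c(p_reward_given_correct_rich, p_reward_given_correct_lean,
             stimulus_probability_rich)
  if (any(probs < 0 | probs > 1))
    stop("payoff probabilities must lie in [0, 1]", call. = FALSE)
  if (reward_cents < 0 || effort_cost_cents < 0)
    stop("reward and effort cost must be nonnegative", call. = FALSE)
  structure(list(
    reward_cents = reward_cents,
    p_reward_given_correct_rich = p_reward_given_correct_rich,
    p_reward_given_correct_lean = p_reward_given_correct_lean,
    stimulus_probability_rich = stimulus_probability_rich,
    effort_cost_cents = effort_cost_cents), class = "payoff_structure")
}

# Per-response values: expected cents for a correct response to each
# stimulus. The effort differential between the two responses is zero in
# this task, so only the reward term enters.
.payoff_values <- function(payoff) {
  list(v_rich = payoff$reward_cents * payoff$p_reward_given_correct_rich,
       v_lean = payoff$reward_cents * payoff$p_reward_given_correct_lean,
       p_rich = payoff$stimulus_probability_rich,
       p_lean = 1 - payoff$stimulus_probability_rich)
}

#' Reward-maximizing decision criterion
#'
#' The evidence value at which the expected payoffs of the two responses
#' are equal. For equal-variance Gaussian signal detection this is
#' `c* = log(beta*) / d'` with
#' `beta* = (P(lean) V_lean) / (P(rich) V_rich)`, where `V_s` is the
#' expected reward of a correct response to stimulus `s`. Under the 3:1
#' schedule `beta* < 1`, so the optimal criterion is shifted toward
#' responding "rich".
#'
#' @param payoff a [payoff_structure()].
#' @param d_prime perceptual sensitivity, must be strictly positive.
#' @return The optimal criterion (scalar).
#' @export
optimal_criterion <- function(payoff, d_prime) {
  if (!is.finite(d_prime) || d_prime <= 0)
    stop("optimal criterion is undefined for d' <= 0 ",
         "(all criteria yield equal expected value)", call. = FALSE)
  v <- .payoff_values(payoff)
  if (v$v_rich <= 0 || v$v_lean <= 0 || v$p_rich <= 0 || v$p_lean <= 0)
    stop("payoff must give both responses positive expected reward",
         call. = FALSE)
  beta_star <- (v$p_lean * v$v_lean) / (v$p_rich * v$v_rich)
  log(beta_star) / d_prime
}

#' Expected value of a decision criterion
#'
#' Exact Gaussian-tail expected payoff per trial of responding with
#' criterion `criterion` at sensitivity `d_prime`:
#' `EV = P(rich) P(respond rich | rich) V_rich +
#'       P(lean) P(respond lean | lean) V_lean - effort`.
#' No simulation is involved.
#'
#' @param criterion decision criterion (vectorized).
#' @param payoff a [payoff_structure()].
#' @param d_prime perceptual sensitivity (nonnegative).
#' @return Expected cents per trial, one per criterion.
#' @export
expected_value <- function(criterion, payoff, d_prime) {
  if (d_prime < 0) stop("d_prime must be nonnegative", call. = FALSE)
  v <- .payoff_values(payoff)
  p_hit <- stats::pnorm(d_prime / 2 - criterion)       # respond rich | rich
  p_crj <- stats::pnorm(criterion + d_prime / 2)       # respond lean | lean
  v$p_rich * p_hit * v$v_rich + v$p_lean * p_crj * v$v_lean -
    payoff$effort_cost_cents
}

#' Empirical signal-detection operating point
#'
#' Estimates `d'` and the criterion from a block's hit and false-alarm
#' rates by the usual z-transform, with the all-or-none 0.5 cell
#' correction of [response_bias()]. The hit rate is the probability of
#' responding "rich" on rich trials; the false-alarm rate is the
#' probability of responding "rich" on lean trials.
#'
#' @param counts block count rows as from [tabulate_blocks()].
#' @return Data frame with columns `hit_rate`, `fa_rate`, `d_hat`, `c_hat`.
#' @export
operating_point <- function(counts) {
  s <- .sdt_cells(counts)
  hit <- s$cells[, 1L] / (s$cells[, 1L] + s$cells[, 2L])
  fa  <- s$cells[, 4L] / (s$cells[, 3L] + s$cells[, 4L])
  zh <- stats::qnorm(hit)
  zf <- stats::qnorm(fa)
  data.frame(hit_rate = hit, fa_rate = fa,
             d_hat = zh - zf, c_hat = -(zh + zf) / 2)
}

#' Expected-value shortfall of an operating point
#'
#' The core of the default RBD form: how many cents per trial the observed
#' policy forgoes relative to the reward-maximizing criterion at the same
#' sensitivity, `EV(c*) - EV(c_hat)`. Zero iff the observed criterion is
#' optimal; strictly increasing as the criterion moves away from `c*` on
#' either side.
#'
#' @param c_hat observed criterion (vectorized).
#' @param d_hat sensitivity at which the policy operates; must be positive
#'   for the optimum to exist.
#' @param payoff a [payoff_structure()].
#' @return Shortfall in cents per trial (nonnegative).
#' @export
rbd_shortfall <- function(c_hat, d_hat, payoff) {
  c_opt <- optimal_criterion(payoff, d_hat)
  expected_value(c_opt, payoff, d_hat) - expected_value(c_hat, payoff, d_hat)
}

#' Expected value of an empirical operating point
#'
#' Expected cents per trial implied directly by observed response rates:
#' `EV = P(rich) hit V_rich + P(lean) (1 - fa) V_lean - effort`. When the
#' rates are consistent with a Gaussian operating point `(c_hat, d_hat)`,
#' this equals `expected_value(c_hat, payoff, d_hat)` exactly.
#'
#' @param hit_rate probability of responding "rich" on rich trials.
#' @param fa_rate probability of responding "rich" on lean trials.
#' @param payoff a [payoff_structure()].
#' @return Expected cents per trial.
#' @export
empirical_ev <- function(hit_rate, fa_rate, payoff) {
  v <- .payoff_values(payoff)
  v$p_rich * hit_rate * v$v_rich + v$p_lean * (1 - fa_rate) * v$v_lean -
    payoff$effort_cost_cents
}

# Registry of RBD functional forms. Each method maps an operating point and
# payoff to a scalar per block. Additional forms (for example a transcribed
# closed-form variant) can be registered at run time without touching any
# downstream stage: the classifier and outcome model consume one scalar per
# block regardless of the form that produced it.
.rbd_registry <- new.env(parent = emptyenv())

#' Register or list RBD scoring methods
#'
#' `rbd_methods()` lists registered method tags; `register_rbd_method()`
#' adds one. A method is a function `f(op, d_used, payoff)` — `op` a
#' one-row operating point (see [operating_point()]), `d_used` the
#' sensitivity at which the engaged reference policy is evaluated —
#' returning a finite scalar that is minimal when the observed criterion
#' equals the optimal one.
#'
#' @param name method tag (string).
#' @param fn scoring function.
#' @return `rbd_methods()` returns a character vector of tags;
#'   `register_rbd_method()` returns `name` invisibly.
#' @export
rbd_methods <- function() sort(ls(.rbd_registry))

#' @rdname rbd_methods
#' @export
register_rbd_method <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .rbd_registry)
  invisible(name)
}

.init_rbd_registry <- function() {
  register_rbd_method("ev_shortfall", function(op, d_used, payoff) {
    c_opt <- optimal_criterion(payoff, d_used)
    expected_value(c_opt, payoff, d_used) -
      empirical_ev(op$hit_rate, op$fa_rate, payoff)
  })
}

#' Reward Behavior Disengagement per block
#'
#' Scores each block by how far observed responding departs from the
#' reward-maximizing policy given the task's payoff structure. The default
#' `ev_shortfall` form is `RBD = EV(c*(payoff, d_hat)) - EV(c_hat)`: the
#' expected cents per trial forgone by the observed criterion, using the
#' empirical operating point from the block's zero-cell-corrected hit and
#' false-alarm rates. Because the operating point reproduces the observed
#' response rates exactly, `EV(c_hat)` equals the expected earnings implied
#' by the empirical rates themselves.
#'
#' Sensitivities at or below `d_floor` carry no exploitable signal (the
#' expected-value curve is flat), so `d_hat` is floored there and the
#' shortfall is correspondingly near zero.
#'
#' @param counts block counts from [tabulate_blocks()].
#' @param payoff a [payoff_structure()].
#' @param method registered method tag (see [rbd_methods()]).
#' @param d_prime optional fixed sensitivity overriding the empirical
#'   `d_hat` (used, for example, to score a chance-level responder against
#'   a reference sensitivity).
#' @param d_floor lower bound applied to the sensitivity (default 0.05).
#' @return Data frame `subject_id`, `block`, `rbd`, `method_tag`.
#' @export
compute_rbd <- function(counts, payoff = payoff_structure(),
                        method = "ev_shortfall", d_prime = NULL,
                        d_floor = 0.05) {
  if (!method %in% rbd_methods())
    stop("unknown RBD method tag: ", method, call. = FALSE)
  n_rich <- counts$rich_correct + counts$rich_incorrect
  n_lean <- counts$lean_correct + counts$lean_incorrect
  if (any(n_rich == 0 | n_lean == 0))
    stop("insufficient data: a stimulus was never presented in some block",
         call. = FALSE)
  op <- operating_point(counts)
  d_used <- if (is.null(d_prime)) pmax(op$d_hat, d_floor)
            else rep_len(d_prime, nrow(counts))
  fn <- get(method, envir = .rbd_registry)
  rbd <- vapply(seq_len(nrow(counts)),
                function(i) fn(op[i, ], d_used[i], payoff), numeric(1L))
  data.frame(subject_id = counts$subject_id, block = counts$block,
             rbd = rbd, method_tag = method, stringsAsFactors = FALSE)
}
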