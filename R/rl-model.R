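#' Reward prediction error of the standard trial-level RL model
#'
#' `delta = r - V(s)`: the observed (normalized) reward minus the current
#' value of the state.
#'
#' @param reward Normalized reward(s) in `[0, 1]`.
#' @param value Current state value(s) on the same scale.
#' @return `reward - value`.
#' @export
standard_rpe <- function(reward, value) {
  reward - value
}

#' Delta-rule value update
#'
#' `V <- V + alpha * delta`, the Rescorla-Wagner update applied at the trial
#' level.
#'
#' @param value Current value.
#' @param alpha Learning rate in `[0, 0.3]`.
#' @param delta Reward prediction error.
#' @return Updated value.
#' @export
standard_value_update <- function(value, alpha, delta) {
  if (any(alpha < 0 | alpha > 0.3)) abort("`alpha` must lie in [0, 0.3].")
  value + alpha * delta
}

#' Simulate the single-state delta rule over a reward sequence
#'
#' Runs `V <- V + alpha * (r - V)` over a sequence of rewards without any
#' block resets — the single-state model whose long-run mean value under
#' equiprobable normalized rewards {0, 1} is 0.5. Implemented as a recursive
#' linear filter.
#'
#' @param rewards Numeric reward sequence; if `NULL`, `n_trials` rewards are
#'   drawn as 0/1 with probability 0.5 each.
#' @param n_trials Number of trials when `rewards` is `NULL`.
#' @param alpha Learning rate.
#' @param v0 Initial value (default 0.5).
#' @param seed Seed used when drawing rewards.
#' @return Tibble with columns `trial`, `reward`, `value` (the value *after*
#'   the trial's update) and `rpe`.
#' @export
simulate_delta_rule <- function(rewards = NULL, n_trials = 10000, alpha = 0.1,
                                v0 = 0.5, seed = 1) {
  if (is.null(rewards)) {
    rewards <- with_seed(seed, function() rbinom(n_trials, 1L, 0.5))
  }
  v <- as.numeric(stats::filter(alpha * rewards, 1 - alpha,
    method = "recursive", init = v0
  ))
  v_pre <- c(v0, v[-length(v)])
  tibble::tibble(
    trial = seq_along(rewards), reward = as.numeric(rewards),
    value = v, rpe = rewards - v_pre
  )
}

#' Bayesian belief update over hidden states from an observed reward
#'
#' Computes the posterior `b(s) = P(r | s) P(s) / P(r)` where the likelihood
#' is Gaussian, `P(r | s) = N(r; mean_s, sigma2)`. Evaluated in log space so
#' extreme rewards never underflow to an all-zero posterior.
#'
#' @param prior Numeric probability vector over states (sums to 1).
#' @param reward Observed normalized reward.
#' @param state_means Reward mean of each hidden state.
#' @param sigma2 Sensory noise variance (> 0).
#' @return Posterior probability vector over states.
#' @examples
#' belief_posterior(c(0.5, 0.5), reward = 0, state_means = c(0, 1), sigma2 = 0.1)
#' @export
belief_posterior <- function(prior, reward, state_means, sigma2) {
  if (length(prior) != length(state_means)) {
    abort("`prior` and `state_means` must have the same length.")
  }
  if (any(prior < 0) || abs(sum(prior) - 1) > 1e-8) {
    abort("`prior` must be a probability vector.")
  }
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  log_post <- log(prior) - (reward - state_means)^2 / (2 * sigma2)
  log_post[prior == 0] <- -Inf
  w <- exp(log_post - max(log_post))
  w / sum(w)
}

#' Value of a belief state
#'
#' The reward expectation implied by a belief is the belief-weighted sum of
#' per-state weights, `V(b) = sum_s w_s b(s)`.
#'
#' @param belief Probability vector over states.
#' @param weights Per-state value weights, same length as `belief`.
#' @return Scalar value.
#' @export
belief_value <- function(belief, weights) {
  if (length(belief) != length(weights)) {
    abort("`belief` and `weights` must have the same length.")
  }
  sum(belief * weights)
}

#' Belief-weighted delta-rule weight update
#'
#' `w <- w + alpha * delta * b`: the prediction error is credited to each
#' hidden state in proportion to its probability.
#'
#' @param weights Per-state weights.
#' @param alpha Learning rate.
#' @param delta Reward prediction error.
#' @param belief Probability vector over states.
#' @return Updated weight vector.
#' @export
belief_weight_update <- function(weights, alpha, delta, belief) {
  if (length(weights) != length(belief)) {
    abort("`weights` and `belief` must have the same length.")
  }
  weights + alpha * delta * belief
}

ctx_codes <- c(none = 0L, s1 = 1L, s2 = 2L)

#' Run an RL model over a trial schedule
#'
#' Forward-simulates a model variant over a trial table, producing per-trial
#' values, beliefs, reward prediction errors and predicted dopamine
#' responses (`gain * rpe + offset`).
#'
#' Standard variants reset the value at every block start to the initial
#' value conditioned on the previous block's type, then update it by the
#' delta rule within the block. Belief variants reset the belief at every
#' block start to the variant's (context-conditioned) prior; the value on
#' trial `t` uses the *pre-outcome* belief — the prior on trial 1, thereafter
#' the posterior given rewards of trials `1..t-1` of the current block — and
#' the current weights. After each outcome the belief is updated by Bayes'
#' rule and the weights by the belief-weighted delta rule (by default
#' crediting the post-outcome belief; see `credit_belief`). Weights carry
#' across blocks.
#'
#' @param trials Trial-level tibble with columns `trial_in_block`,
#'   `reward_norm` and `prev_block_type` (see [schedule_trials()]).
#' @param params An [rl_params()] object.
#' @param weights_init Initial per-state weights for belief variants. The
#'   default, `"asymptotic"`, starts at the training asymptote `(0, 1)`
#'   (third state, if any, at its state mean) — appropriate when the history
#'   starts after extended training. `"naive"` starts at `(0.5, 0.5)` (0.5
#'   for a third state). A numeric vector gives explicit weights.
#' @param credit_belief Which belief the weight update uses:
#'   `"posterior"` (default; the reward has disambiguated the state) or
#'   `"prior"` (the pre-outcome belief).
#' @return The input tibble with added columns `value_pre`, `rpe`,
#'   `predicted_da`, per-state pre/post beliefs (`b1_pre`, `b1_post`, ...;
#'   belief variants) and the weights used on each trial (`w1`, ...).
#' @export
run_model <- function(trials, params, weights_init = c("asymptotic", "naive"),
                      credit_belief = c("posterior", "prior")) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0, inherits(params, "rl_params"))
  credit_belief <- match.arg(credit_belief)
  needed <- c("trial_in_block", "reward_norm", "prev_block_type")
  if (!all(needed %in% names(trials))) {
    abort(paste0("`trials` must contain columns: ", paste(needed, collapse = ", "), "."))
  }
  ctx <- ctx_codes[trials$prev_block_type]
  if (anyNA(ctx)) abort("`prev_block_type` must be one of \"none\", \"s1\", \"s2\".")

  belief <- is_belief_variant(params$variant)
  if (belief) {
    k <- length(params$state_means)
    w0 <- if (is.numeric(weights_init)) {
      if (length(weights_init) != k) abort("`weights_init` has the wrong length.")
      weights_init
    } else {
      switch(match.arg(weights_init),
        asymptotic = params$state_means,
        naive = rep(mean(params$state_means[1:2]), k)
      )
    }
    pri <- prior_matrix(params)
    res <- rl_forward_belief(
      trials$trial_in_block, trials$reward_norm, unname(ctx),
      params$alpha, params$gain, params$offset,
      pri, params$state_means, params$sigma2, w0,
      credit_belief == "posterior"
    )
    out <- dplyr::mutate(
      tibble::as_tibble(trials),
      value_pre = res$value_pre, rpe = res$rpe, predicted_da = res$predicted_da
    )
    for (j in seq_len(k)) {
      out[[paste0("b", j, "_pre")]] <- res$belief_pre[, j]
      out[[paste0("b", j, "_post")]] <- res$belief_post[, j]
      out[[paste0("w", j)]] <- res$weights[, j]
    }
  } else {
    inits <- c(
      mean(c(params$init_after_s1, params$init_after_s2)),
      params$init_after_s1, params$init_after_s2
    )
    res <- rl_forward_standard(
      trials$trial_in_block, trials$reward_norm, unname(ctx),
      params$alpha, params$gain, params$offset, inits
    )
    out <- dplyr::mutate(
      tibble::as_tibble(trials),
      value_pre = res$value_pre, rpe = res$rpe, predicted_da = res$predicted_da
    )
  }
  out
}
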