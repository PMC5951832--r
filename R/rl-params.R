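#' Model variants
#'
#' The six model variants compared in the analysis:
#' * `std_single` — standard trial-level RL, one free initial value at block
#'   start (no previous-block influence).
#' * `std_dual` — standard RL with two free initial values conditioned on the
#'   previous block.
#' * `bs_fixed` — belief-state RL with the prior fixed at 0.5/0.5.
#' * `bs_one_prior` — belief-state RL with one free, context-independent
#'   prior `p1 = P(s1)`.
#' * `bs_two_prior` — belief-state RL with two free priors: `p1 = P(s1)`
#'   following an `s1` block and `p2 = P(s2)` following an `s2` block.
#' * `bs_three_state` — belief-state RL with an additional intermediate
#'   hidden state (reward mean 0.5) holding prior mass `p3`.
#'
#' @return Character vector of variant labels.
#' @export
model_variants <- function() {
  c("std_single", "std_dual", "bs_fixed", "bs_one_prior", "bs_two_prior", "bs_three_state")
}

is_belief_variant <- function(variant) startsWith(variant, "bs_")

#' Construct a parameter set for an RL model variant
#'
#' Builds a validated parameter object for [run_model()] and the fitting
#' routines. Standard-model variants use `alpha`, initial values and `gain`;
#' belief-state variants use `alpha`, `sigma2`, `gain` and (depending on the
#' variant) free priors. All models share the learning rate `alpha` (bounded
#' `[0, 0.3]`) and the response gain `gain` that maps model RPEs linearly to
#' dopamine (dF/F-scale) responses, `predicted_da = gain * rpe + offset`
#' (`offset` defaults to 0).
#'
#' @param variant One of [model_variants()].
#' @param alpha Learning rate in `[0, 0.3]`.
#' @param gain Response gain (>= 0).
#' @param offset Additive response offset (default 0; kept for the optional
#'   shifted-response parameterisation).
#' @param init_value,init_after_s1,init_after_s2 Standard-model initial
#'   values at block start, in `[0, 1]`. `std_single` uses `init_value`;
#'   `std_dual` uses the two context-conditioned values.
#' @param sigma2 Sensory noise variance of the reward likelihood, in
#'   `[0.01, 0.5]` (belief variants).
#' @param prior_after_s1,prior_after_s2,prior_intermediate Free priors in
#'   `[0.001, 0.999]`: `prior_after_s1` is the probability of state `s1`
#'   when the previous block was `s1` (a "stay" prior), `prior_after_s2` the
#'   probability of `s2` after an `s2` block, and `prior_intermediate` the
#'   mass on the third state (`bs_three_state` only).
#' @param state_means Reward means of the hidden states on the normalized
#'   scale; defaults `(0, 1)` or `(0, 1, 0.5)` for the three-state variant.
#' @return An object of class `rl_params`.
#' @examples
#' rl_params("bs_two_prior", alpha = 0.1, sigma2 = 0.05, gain = 2,
#'           prior_after_s1 = 0.7, prior_after_s2 = 0.7)
#' @export
rl_params <- function(variant, alpha = 0.1, gain = 1, offset = 0,
                      init_value = 0.5, init_after_s1 = NULL, init_after_s2 = NULL,
                      sigma2 = 0.05, prior_after_s1 = 0.5, prior_after_s2 = 0.5,
                      prior_intermediate = 0.1, state_means = NULL) {
  variant <- match.arg(variant, model_variants())
  check_range <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
      abort(sprintf("`%s` must be a single value in [%g, %g].", name, lo, hi))
    }
  }
  check_range(alpha, 0, 0.3, "alpha")
  check_range(gain, 0, Inf, "gain")

  p <- list(variant = variant, alpha = alpha, gain = gain, offset = offset)

  if (!is_belief_variant(variant)) {
    if (variant == "std_single") {
      check_range(init_value, 0, 1, "init_value")
      p$init_after_s1 <- p$init_after_s2 <- init_value
    } else {
      init_after_s1 <- init_after_s1 %||% init_value
      init_after_s2 <- init_after_s2 %||% init_value
      check_range(init_after_s1, 0, 1, "init_after_s1")
      check_range(init_after_s2, 0, 1, "init_after_s2")
      p$init_after_s1 <- init_after_s1
      p$init_after_s2 <- init_after_s2
    }
    class(p) <- c("std_rl_params", "rl_params")
    return(p)
  }

  check_range(sigma2, 0.01, 0.5, "sigma2")
  p$sigma2 <- sigma2
  p$state_means <- state_means %||%
    (if (variant == "bs_three_state") c(0, 1, 0.5) else c(0, 1))
  n_states <- if (variant == "bs_three_state") 3L else 2L
  if (length(p$state_means) != n_states) {
    abort(sprintf("`state_means` must have %d entries for %s.", n_states, variant))
  }
  if (variant != "bs_fixed") {
    check_range(prior_after_s1, 0.001, 0.999, "prior_after_s1")
    check_range(prior_after_s2, 0.001, 0.999, "prior_after_s2")
  }
  p$prior_after_s1 <- if (variant == "bs_fixed") 0.5 else prior_after_s1
  p$prior_after_s2 <- if (variant == "bs_fixed") 0.5 else {
    if (variant == "bs_one_prior") 1 - prior_after_s1 else prior_after_s2
  }
  if (variant == "bs_three_state") {
    check_range(prior_intermediate, 0.001, 0.999, "prior_intermediate")
    p$prior_intermediate <- prior_intermediate
  }
  class(p) <- c("belief_rl_params", "rl_params")
  p
}

#' @export
print.rl_params <- function(x, ...) {
  cat("<rl_params:", x$variant, ">\n")
  vals <- x[setdiff(names(x), c("variant", "state_means"))]
  cat(paste0("  ", names(vals), " = ", vapply(vals, format, ""), collapse = "\n"), "\n")
  if (!is.null(x$state_means)) {
    cat("  state_means =", paste(x$state_means, collapse = ", "), "\n")
  }
  invisible(x)
}

# prior over hidden states for each context (rows: none, s1, s2)
prior_matrix <- function(params) {
  p1 <- params$prior_after_s1  # P(s1 | prev s1)
  p2 <- params$prior_after_s2  # P(s2 | prev s2)
  after_s1 <- c(p1, 1 - p1)
  after_s2 <- c(1 - p2, p2)
  if (params$variant == "bs_three_state") {
    p3 <- params$prior_intermediate
    after_s1 <- c(after_s1 * (1 - p3), p3)
    after_s2 <- c(after_s2 * (1 - p3), p3)
  }
  rbind(none = (after_s1 + after_s2) / 2, s1 = after_s1, s2 = after_s2)
}

# free-parameter layout per variant, with the fitting bounds of the study
param_layout <- function(variant) {
  variant <- match.arg(variant, model_variants())
  base <- tibble::tribble(
    ~term, ~lower, ~upper,
    "alpha", 0, 0.3,
    "gain", 0, 100
  )
  extra <- switch(variant,
    std_single = tibble::tribble(~term, ~lower, ~upper, "init_value", 0, 1),
    std_dual = tibble::tribble(
      ~term, ~lower, ~upper,
      "init_after_s1", 0, 1, "init_after_s2", 0, 1
    ),
    bs_fixed = tibble::tribble(~term, ~lower, ~upper, "sigma2", 0.01, 0.5),
    bs_one_prior = tibble::tribble(
      ~term, ~lower, ~upper,
      "sigma2", 0.01, 0.5, "prior_after_s1", 0.001, 0.999
    ),
    bs_two_prior = tibble::tribble(
      ~term, ~lower, ~upper,
      "sigma2", 0.01, 0.5, "prior_after_s1", 0.001, 0.999,
      "prior_after_s2", 0.001, 0.999
    ),
    bs_three_state = tibble::tribble(
      ~term, ~lower, ~upper,
      "sigma2", 0.01, 0.5, "prior_after_s1", 0.001, 0.999,
      "prior_after_s2", 0.001, 0.999, "prior_intermediate", 0.001, 0.999
    )
  )
  dplyr::bind_rows(base, extra)
}

params_from_vector <- function(variant, theta) {
  layout <- param_layout(variant)
  stopifnot(length(theta) == nrow(layout))
  args <- as.list(theta)
  names(args) <- layout$term
  do.call(rl_params, c(list(variant = variant), args))
}

params_to_vector <- function(params) {
  layout <- param_layout(params$variant)
  vapply(layout$term, function(t) params[[t]] %||% params$init_after_s1, numeric(1))
}
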