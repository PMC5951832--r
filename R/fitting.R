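#' Condition-average dopamine responses
#'
#' Averages a per-trial response for each condition key — reward size,
#' trial-in-block (1 to 5) and previous block type — the summary the models
#' are fitted to. Keys with no trials are simply absent.
#'
#' @param trials Trial-level tibble.
#' @param response Name of the response column (default `"da_response"`).
#' @return Tibble with columns `reward_volume_ul`, `trial_in_block`,
#'   `prev_block_type`, `mean_da`, `n_trials`.
#' @export
condition_average <- function(trials, response = "da_response") {
  if (!response %in% names(trials)) {
    abort(sprintf("`trials` has no column \"%s\".", response))
  }
  if (anyNA(trials[[response]])) abort("Every trial must have a response.")
  trials |>
    dplyr::group_by(.data$reward_volume_ul, .data$trial_in_block, .data$prev_block_type) |>
    dplyr::summarise(
      mean_da = mean(.data[[response]]),
      n_trials = dplyr::n(), .groups = "drop"
    )
}

# align each trial with its row in the condition-average table
condition_group_index <- function(trials, conditions) {
  key <- function(d) paste(d$reward_volume_ul, d$trial_in_block, d$prev_block_type)
  g <- match(key(trials), key(conditions))
  if (anyNA(g)) abort("Some trials have no matching condition-average row.")
  g
}

# Gaussian NLL with residual variance profiled at its MLE; floored so a
# perfect (zero-residual) fit stays finite
profiled_gaussian_nll <- function(rss, n) {
  s2 <- max(rss / n, 1e-12)
  0.5 * n * (log(2 * pi * s2) + 1)
}

resolve_weights_init <- function(weights_init, params) {
  if (is.numeric(weights_init)) {
    return(weights_init)
  }
  switch(match.arg(weights_init, c("asymptotic", "naive")),
    asymptotic = params$state_means,
    naive = rep(mean(params$state_means[1:2]), length(params$state_means))
  )
}

# fast objective over the free-parameter vector; avoids rl_params validation
# in the optimizer's inner loop
make_objective <- function(variant, trials, conditions, weights_init, credit_belief) {
  g <- condition_group_index(trials, conditions)
  ng <- nrow(conditions)
  obs <- conditions$mean_da
  tib <- as.integer(trials$trial_in_block)
  r <- trials$reward_norm
  ctx <- unname(ctx_codes[trials$prev_block_type])
  belief <- is_belief_variant(variant)
  state_means <- if (variant == "bs_three_state") c(0, 1, 0.5) else c(0, 1)
  w0 <- if (belief) {
    resolve_weights_init(weights_init, list(state_means = state_means))
  }
  credit_post <- identical(credit_belief, "posterior")

  function(theta) {
    pred <- if (belief) {
      p1 <- switch(variant,
        bs_fixed = 0.5,
        theta[4]
      )
      p2 <- switch(variant,
        bs_fixed = 0.5,
        bs_one_prior = 1 - theta[4],
        theta[5]
      )
      a1 <- c(p1, 1 - p1)
      a2 <- c(1 - p2, p2)
      if (variant == "bs_three_state") {
        p3 <- theta[6]
        a1 <- c(a1 * (1 - p3), p3)
        a2 <- c(a2 * (1 - p3), p3)
      }
      pri <- rbind((a1 + a2) / 2, a1, a2)
      rl_forward_belief(
        tib, r, ctx, theta[1], theta[2], 0, pri, state_means,
        theta[3], w0, credit_post
      )$predicted_da
    } else {
      inits <- if (variant == "std_single") {
        rep(theta[3], 3)
      } else {
        c((theta[3] + theta[4]) / 2, theta[3], theta[4])
      }
      rl_forward_standard(tib, r, ctx, theta[1], theta[2], 0, inits)$predicted_da
    }
    mu <- group_means_cpp(pred, g, ng)
    rss <- sum((obs - mu)^2)
    if (!is.finite(rss)) {
      return(1e10)
    } # large finite penalty
    profiled_gaussian_nll(rss, ng)
  }
}

#' Negative log-likelihood of a model for condition-averaged responses
#'
#' Runs the model forward over the trial schedule, averages its predicted
#' dopamine responses into the observed condition cells, and returns the
#' Gaussian negative log-likelihood with the residual variance profiled at
#' its maximum-likelihood value (monotone in the residual sum of squares,
#' i.e. equivalent to least squares).
#'
#' @param params An [rl_params()] object.
#' @param trials Trial-level tibble (the schedule the data came from).
#' @param conditions Condition-average tibble ([condition_average()]).
#' @param weights_init,credit_belief Passed to [run_model()].
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, trials, conditions,
                                    weights_init = "asymptotic",
                                    credit_belief = "posterior") {
  obj <- make_objective(params$variant, trials, conditions, weights_init, credit_belief)
  obj(params_to_vector(params))
}

random_start <- function(layout) {
  vapply(seq_len(nrow(layout)), function(i) {
    lo <- layout$lower[i]
    hi <- layout$upper[i]
    if (layout$term[i] == "gain") {
      # response gain has no natural scale; spread starts log-uniformly
      min(10^runif(1, -1, 2), hi - 0.01 * (hi - lo))
    } else {
      runif(1, lo + 0.01 * (hi - lo), hi - 0.01 * (hi - lo))
    }
  }, numeric(1))
}

#' Fit an RL model variant to dopamine responses by maximum likelihood
#'
#' Bounded multi-start maximum-likelihood fit of a model variant to
#' condition-averaged per-trial responses. The optimizer is started at
#' `n_starts` random interior points of the parameter box (the study's
#' bounds: learning rate in `[0, 0.3]`, sensory noise variance in
#' `[0.01, 0.5]`, initial values in `[0, 1]`, priors in `[0.001, 0.999]`,
#' gain in `[0, 100]` with log-spaced starts); the best start is reported
#' and all starts are recorded. L-BFGS-B is used with a gradient-free
#' bounded fallback (`nlminb`) if it fails.
#'
#' @param trials Trial-level tibble containing the response column.
#' @param variant One of [model_variants()].
#' @param response Response column name (default `"da_response"`; use
#'   `"us_peak"`-style columns to fit peak responses).
#' @param n_starts Number of random starts (default 5).
#' @param seed Integer seed for the starts.
#' @param weights_init,credit_belief Passed to [run_model()].
#' @return An object of class `rl_fit`: fitted parameters (`$params`),
#'   `$nll`, `$bic`, `$n_obs`, `$n_params`, the per-start table `$starts`,
#'   and bookkeeping (`$variant`, `$seed`, `$converged`).
#' @export
fit_model <- function(trials, variant, response = "da_response", n_starts = 5,
                      seed = 1, weights_init = "asymptotic",
                      credit_belief = "posterior") {
  variant <- match.arg(variant, model_variants())
  conditions <- condition_average(trials, response)
  if (nrow(conditions) == 0) abort("No condition averages to fit.")
  layout <- param_layout(variant)
  obj <- make_objective(variant, trials, conditions, weights_init, credit_belief)

  starts <- with_seed(seed, function() {
    purrr::map(seq_len(n_starts), function(s) {
      theta0 <- random_start(layout)
      res <- tryCatch(
        optim(theta0, obj,
          method = "L-BFGS-B", lower = layout$lower,
          upper = layout$upper, control = list(maxit = 1000, factr = 1e7)
        ),
        error = function(e) NULL
      )
      if (is.null(res)) {
        res2 <- tryCatch(
          nlminb(theta0, obj,
            lower = layout$lower, upper = layout$upper,
            control = list(iter.max = 1000, rel.tol = 1e-10)
          ),
          error = function(e) NULL
        )
        if (is.null(res2)) {
          return(list(init = theta0, par = NULL, nll = Inf, converged = FALSE))
        }
        return(list(
          init = theta0, par = res2$par, nll = res2$objective,
          converged = res2$convergence == 0
        ))
      }
      list(
        init = theta0, par = res$par, nll = res$value,
        converged = res$convergence == 0
      )
    })
  })

  nlls <- vapply(starts, function(s) s$nll, numeric(1))
  if (all(!is.finite(nlls))) {
    abort(sprintf(
      "All %d optimization starts failed for %s (inits recorded).",
      n_starts, variant
    ))
  }
  best <- starts[[which.min(nlls)]]
  par <- pmin(pmax(best$par, layout$lower), layout$upper)
  params <- params_from_vector(variant, par)
  start_tbl <- purrr::map_dfr(seq_along(starts), function(i) {
    s <- starts[[i]]
    tibble::tibble(
      start = i, nll = s$nll, converged = s$converged,
      init = list(s$init), par = list(s$par)
    )
  })
  n_obs <- nrow(conditions)
  k <- nrow(layout)
  structure(
    list(
      variant = variant, params = params, par = stats::setNames(par, layout$term),
      nll = best$nll, n_obs = n_obs, n_params = k,
      bic = bic(best$nll, k, n_obs), starts = start_tbl, seed = seed,
      converged = best$converged, response = response,
      conditions = conditions, weights_init = weights_init,
      credit_belief = credit_belief
    ),
    class = "rl_fit"
  )
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(
    "<rl_fit:", x$variant, "| nll", format(x$nll, digits = 6), "| BIC",
    format(x$bic, digits = 6), "|", x$n_obs, "conditions >\n"
  )
  print(tidy(x))
  invisible(x)
}

#' Tidy the fitted parameters of an `rl_fit`
#'
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `lower`, `upper`.
#' @export
tidy.rl_fit <- function(x, ...) {
  dplyr::mutate(param_layout(x$variant), estimate = unname(x$par), .after = "term")
}

#' One-row model-level summary of an `rl_fit`
#'
#' @param x An `rl_fit` object.
#' @param ... Unused.
#' @return Tibble with `variant`, `nll`, `n_obs`, `n_params`, `bic`,
#'   `converged`, `n_starts`.
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, nll = x$nll, n_obs = x$n_obs, n_params = x$n_params,
    bic = x$bic, converged = x$converged, n_starts = nrow(x$starts)
  )
}

#' Fit all model variants to every mouse of a cohort
#'
#' @param cohort List of `synthetic_mouse` objects (or any list of objects
#'   with a `$trials` tibble and `$mouse_id`).
#' @param variants Variants to fit (default all six).
#' @param seed Base seed; each (mouse, variant) pair gets a distinct seed.
#' @param ... Passed to [fit_model()].
#' @return Tibble with columns `mouse_id`, `variant`, `fit` (list-column of
#'   `rl_fit`), `nll`, `n_obs`, `n_params`, `bic`.
#' @export
fit_cohort <- function(cohort, variants = model_variants(), seed = 1, ...) {
  grid <- tidyr::expand_grid(
    mouse = seq_along(cohort),
    variant = variants
  )
  purrr::pmap_dfr(grid, function(mouse, variant) {
    m <- cohort[[mouse]]
    f <- fit_model(m$trials, variant,
      seed = seed + 131L * mouse + match(variant, model_variants()), ...
    )
    tibble::tibble(
      mouse_id = m$mouse_id, variant = variant, fit = list(f),
      nll = f$nll, n_obs = f$n_obs, n_params = f$n_params, bic = f$bic
    )
  })
}
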