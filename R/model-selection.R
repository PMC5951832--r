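#' Bayesian Information Criterion
#'
#' `BIC = k * ln(n) + 2 * nll`, penalizing parameter count so models with
#' different numbers of parameters can be compared directly.
#'
#' @param nll Negative log-likelihood at the optimum.
#' @param k Number of free parameters.
#' @param n Number of observations.
#' @return Scalar BIC.
#' @export
bic <- function(nll, k, n) {
  if (any(n < 1)) abort("`n` must be at least 1.")
  if (any(k < 0)) abort("`k` must be non-negative.")
  k * log(n) + 2 * nll
}

# log Gamma-function shorthand
lB <- function(a) sum(lgamma(a)) - lgamma(sum(a))

#' Random-effects Bayesian model selection
#'
#' Estimates, for a cohort in which each subject may use a different model,
#' the population frequency of each model and the probability that each
#' model is the most frequent (exceedance probability, xp). A variational
#' Dirichlet scheme iterates the subject-level model responsibilities
#' `u[n,k] proportional to exp(log_evidence[n,k] + psi(alpha_k) -
#' psi(sum(alpha)))` and counts `alpha_k = alpha0 + sum_n u[n,k]` to
#' convergence. Exceedance probabilities are Monte-Carlo estimates from
#' Dirichlet(alpha) draws (ties split uniformly); the Bayes omnibus risk
#' (BOR) compares the random-effects model's variational free energy with
#' the equal-frequency null, and the protected exceedance probability is
#' `pxp = (1 - BOR) * xp + BOR / K`.
#'
#' @param log_evidence Numeric matrix, subjects x models, of per-subject log
#'   model evidences (e.g. `-BIC/2`); column names label the models.
#' @param alpha0 Dirichlet prior count per model (default 1, flat).
#' @param mc_samples Monte-Carlo draws for the exceedance probabilities
#'   (default 1e6, giving xp standard errors below 1e-3).
#' @param seed Integer seed for the draws.
#' @param tol Convergence tolerance on the alpha vector.
#' @return An object of class `bms`: list with `alpha` (Dirichlet
#'   posterior), `expected_freq`, `xp`, `pxp`, `bor`, `responsibilities`
#'   (the `u` matrix), `free_energy`, `f0`, `mc_samples`, `seed`.
#' @export
bms_random_effects <- function(log_evidence, alpha0 = 1, mc_samples = 1e6,
                               seed = 1, tol = 1e-8) {
  lev <- as.matrix(log_evidence)
  if (ncol(lev) < 2) abort("At least two models are required.")
  if (nrow(lev) < 1) abort("At least one subject is required.")
  if (!all(is.finite(lev))) {
    bad <- which(!is.finite(lev), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-finite log evidence for subject %d, model %s.",
      bad[1], colnames(lev)[bad[2]] %||% bad[2]
    ))
  }
  n <- nrow(lev)
  k <- ncol(lev)
  models <- colnames(lev) %||% paste0("model", seq_len(k))

  alpha <- rep(alpha0, k)
  u <- matrix(1 / k, n, k)
  for (it in seq_len(10000)) {
    lw <- sweep(lev, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    u <- exp(lw)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (sum(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  # variational free energy of the random-effects model
  elnr <- digamma(alpha) - digamma(sum(alpha))
  f1 <- sum(u * sweep(lev, 2, elnr, "+")) - sum(u * log(pmax(u, 1e-300))) +
    sum((alpha0 - 1) * elnr) - lB(rep(alpha0, k)) -
    (sum((alpha - 1) * elnr) - lB(alpha))
  # evidence of the equal-frequency null
  f0 <- sum(apply(lev, 1, function(x) {
    m <- max(x)
    m + log(mean(exp(x - m)))
  }))
  bor <- 1 / (1 + exp(f1 - f0))

  xp <- with_seed(seed, function() {
    draws <- matrix(rgamma(mc_samples * k, shape = rep(alpha, each = mc_samples)),
      nrow = mc_samples
    )
    mx <- draws == apply(draws, 1, max)
    wins <- mx / rowSums(mx) # ties split uniformly
    colMeans(wins)
  })
  pxp <- (1 - bor) * xp + bor / k

  structure(
    list(
      models = models, alpha = stats::setNames(alpha, models),
      expected_freq = stats::setNames(alpha / sum(alpha), models),
      xp = stats::setNames(xp, models), pxp = stats::setNames(pxp, models),
      bor = bor, responsibilities = u, free_energy = f1, f0 = f0,
      n_subjects = n, alpha0 = alpha0, mc_samples = mc_samples, seed = seed
    ),
    class = "bms"
  )
}

#' @export
print.bms <- function(x, ...) {
  cat("<bms |", x$n_subjects, "subjects |", length(x$models), "models | BOR",
    format(x$bor, digits = 4), ">\n",
    sep = " "
  )
  print(tidy(x))
  invisible(x)
}

#' Tidy per-model results of a `bms` object
#'
#' @param x A `bms` object.
#' @param ... Unused.
#' @return Tibble with `model`, `alpha`, `expected_freq`, `xp`, `pxp`.
#' @export
tidy.bms <- function(x, ...) {
  tibble::tibble(
    model = x$models, alpha = unname(x$alpha),
    expected_freq = unname(x$expected_freq),
    xp = unname(x$xp), pxp = unname(x$pxp)
  )
}

#' One-row summary of a `bms` object
#'
#' @param x A `bms` object.
#' @param ... Unused.
#' @return Tibble with `n_subjects`, `n_models`, `bor`, `free_energy`,
#'   `best_model`, `best_pxp`.
#' @export
glance.bms <- function(x, ...) {
  best <- which.max(x$pxp)
  tibble::tibble(
    n_subjects = x$n_subjects, n_models = length(x$models), bor = x$bor,
    free_energy = x$free_energy, best_model = x$models[best],
    best_pxp = unname(x$pxp[best])
  )
}

#' Compare fitted models across a cohort
#'
#' Builds per-mouse BIC scores from a cohort fit table, converts them to
#' approximate log evidences (`-BIC/2`), runs random-effects Bayesian model
#' selection, and returns a ranked report over the variants.
#'
#' @param fits Tibble from [fit_cohort()] (columns `mouse_id`, `variant`,
#'   `nll`, `n_obs`, `n_params`; `bic` recomputed if absent).
#' @param mc_samples,seed,alpha0 Passed to [bms_random_effects()].
#' @return An object of class `cohort_selection`: list with the `ranking`
#'   tibble (model, mean BIC, delta mean BIC, expected frequency, xp, pxp),
#'   the underlying `bms` object, and the per-mouse `bic` matrix.
#' @export
select_cohort <- function(fits, mc_samples = 1e6, seed = 1, alpha0 = 1) {
  needed <- c("mouse_id", "variant", "nll", "n_obs", "n_params")
  if (!all(needed %in% names(fits))) {
    abort(paste0("`fits` must contain columns: ", paste(needed, collapse = ", "), "."))
  }
  full <- tidyr::expand_grid(
    mouse_id = unique(fits$mouse_id),
    variant = unique(fits$variant)
  )
  missing <- dplyr::anti_join(full, fits, by = c("mouse_id", "variant"))
  if (nrow(missing) > 0) {
    abort(paste0(
      "Missing (mouse, model) fits: ",
      paste(missing$mouse_id, missing$variant, sep = "/", collapse = ", ")
    ))
  }
  scored <- dplyr::mutate(fits, bic = bic(.data$nll, .data$n_params, .data$n_obs))
  bic_mat <- scored |>
    dplyr::select("mouse_id", "variant", "bic") |>
    tidyr::pivot_wider(names_from = "variant", values_from = "bic") |>
    tibble::column_to_rownames("mouse_id") |>
    as.matrix()
  bms <- bms_random_effects(-bic_mat / 2,
    alpha0 = alpha0,
    mc_samples = mc_samples, seed = seed
  )
  ranking <- tibble::tibble(
    model = colnames(bic_mat),
    mean_bic = unname(colMeans(bic_mat)),
    expected_freq = unname(bms$expected_freq[colnames(bic_mat)]),
    xp = unname(bms$xp[colnames(bic_mat)]),
    pxp = unname(bms$pxp[colnames(bic_mat)])
  ) |>
    dplyr::mutate(delta_mean_bic = .data$mean_bic - min(.data$mean_bic), .after = "mean_bic") |>
    dplyr::arrange(.data$mean_bic)
  structure(
    list(ranking = ranking, bms = bms, bic = bic_mat),
    class = "cohort_selection"
  )
}

#' @export
print.cohort_selection <- function(x, ...) {
  cat("<cohort_selection |", nrow(x$bic), "mice | BOR",
    format(x$bms$bor, digits = 4), ">\n",
    sep = " "
  )
  print(x$ranking)
  invisible(x)
}

#' @export
tidy.cohort_selection <- function(x, ...) x$ranking

#' @export
glance.cohort_selection <- function(x, ...) glance(x$bms)
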