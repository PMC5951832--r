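# exact null distribution of the signed-rank sum for n pairs: counts[w + 1]
# = number of the 2^n equiprobable sign assignments whose positive-rank sum
# equals w, built by dynamic programming over subset sums of {1..n}
signed_rank_null_counts <- function(n) {
  counts <- numeric(n * (n + 1) / 2 + 1)
  counts[1] <- 1
  for (k in seq_len(n)) {
    shifted <- c(numeric(k), counts[seq_len(length(counts) - k)])
    counts <- counts + shifted
  }
  counts
}

#' Exact Wilcoxon signed-rank test
#'
#' Computes the exact two-sided signed-rank test for paired differences by
#' full enumeration of the `2^n` equiprobable sign assignments (dynamic
#' programming over subset sums of ranks `1..n`). The reported statistic is
#' `min(W+, W-)` — the rank sum of the less frequent sign — and the
#' two-sided p-value is `2 * P(W <= w)`, capped at 1. The exact method
#' requires no zero differences and no ties among the absolute differences;
#' either raises an error suggesting a mid-rank fallback.
#'
#' The statistic can be supplied directly via `w` and `n` to evaluate a
#' reported test.
#'
#' @param differences Paired differences (used when `w` is `NULL`).
#' @param w Signed-rank statistic `min(W+, W-)`.
#' @param n Number of pairs (required with `w`); must be at most 30, the
#'   exact-enumeration regime.
#' @return One-row tibble: `n`, `w_statistic`, `p_two_sided`, `method`.
#' @examples
#' wilcoxon_exact(w = 9, n = 11) # p = 0.0322...
#' @export
wilcoxon_exact <- function(differences = NULL, w = NULL, n = NULL) {
  if (is.null(w)) {
    if (is.null(differences)) abort("Provide either `differences` or (`w`, `n`).")
    if (any(differences == 0)) {
      abort("Zero differences: the exact method is invalid. Drop zeros or use a mid-rank method.")
    }
    if (anyDuplicated(abs(differences))) {
      abort("Tied |differences|: the exact method is invalid. Use a mid-rank method.")
    }
    n <- length(differences)
    ranks <- rank(abs(differences))
    w_plus <- sum(ranks[differences > 0])
    w <- min(w_plus, n * (n + 1) / 2 - w_plus)
  }
  if (is.null(n)) abort("`n` is required with `w`.")
  if (n > 30) abort("Exact enumeration supports n <= 30.")
  if (w < 0 || w > n * (n + 1) / 2) abort("`w` must lie in [0, n(n+1)/2].")
  counts <- signed_rank_null_counts(n)
  p <- min(1, 2 * sum(counts[seq_len(w + 1)]) / 2^n)
  tibble::tibble(n = n, w_statistic = w, p_two_sided = p, method = "exact")
}

#' Pearson correlation with a t-test
#'
#' Pearson correlation between paired observations with its t-test,
#' `t = r * sqrt((n - 2) / (1 - r^2))`, either two-tailed or one-tailed for
#' a positive correlation.
#'
#' @param x,y Paired numeric vectors (length >= 3, finite, non-constant).
#' @param alternative `"two_tailed"` or `"one_tailed_positive"`.
#' @return One-row tibble: `n`, `r`, `t`, `p`, `alternative`.
#' @export
corr_with_test <- function(x, y, alternative = c("two_tailed", "one_tailed_positive")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must be paired vectors of length at least 3.")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("Values must be finite.")
  if (sd(x) == 0 || sd(y) == 0) abort("Zero variance in `x` or `y`.")
  ct <- stats::cor.test(x, y,
    method = "pearson",
    alternative = if (alternative == "one_tailed_positive") "greater" else "two.sided"
  )
  tibble::tibble(
    n = length(x), r = unname(ct$estimate), t = unname(ct$statistic),
    p = ct$p.value, alternative = alternative
  )
}

#' Polynomial least-squares fit with adjusted r-squared
#'
#' Fits a degree-`degree` polynomial by least squares and reports the
#' adjusted coefficient of determination,
#' `1 - (1 - r^2) * (n - 1) / (n - degree - 1)`.
#'
#' @param x,y Numeric vectors; requires `length(x) > degree + 1`.
#' @param degree Polynomial degree (>= 1).
#' @return List with `coefficients` (intercept first), `r_squared`,
#'   `adj_r_squared`, `degree`, and the underlying `lm` fit.
#' @export
polyfit_adjusted_r2 <- function(x, y, degree) {
  stopifnot(degree >= 1)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) <= degree + 1) {
    abort("Underdetermined: need more than `degree + 1` points.")
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  s <- summary(fit)
  list(
    coefficients = stats::setNames(
      unname(stats::coef(fit)),
      paste0("x^", 0:degree)
    ),
    r_squared = s$r.squared, adj_r_squared = s$adj.r.squared,
    degree = degree, fit = fit
  )
}

#' Change in anticipatory licking between consecutive trials
#'
#' Computes the differential lick rate, `delta = lick(t+1) - lick(t)`, for
#' consecutive trials within a training day. By default transitions are
#' taken within blocks (trial 1 to 2 through 4 to 5); `within_block = FALSE`
#' also pairs the last trial of a block with the first of the next block on
#' the same day.
#'
#' @param trials Trial-level tibble with `day`, `block_index`,
#'   `trial_in_block`, `lick_rate` (and any condition columns, carried
#'   through from the earlier trial of each pair).
#' @param within_block Restrict transitions to consecutive trials of the
#'   same block (default `TRUE`).
#' @return Tibble with the pair's keys, `from_trial`, `to_trial`,
#'   `delta_lick`.
#' @export
delta_lick <- function(trials, within_block = TRUE) {
  if (!"lick_rate" %in% names(trials)) abort("`trials` must contain `lick_rate`.")
  ordered <- dplyr::arrange(trials, .data$day, .data$block_index, .data$trial_in_block)
  n <- nrow(ordered)
  if (n < 2) abort("Need at least two trials.")
  i <- seq_len(n - 1)
  j <- i + 1L
  keep <- ordered$day[i] == ordered$day[j] & !is.na(ordered$lick_rate[j])
  if (within_block) keep <- keep & ordered$block_index[i] == ordered$block_index[j]
  out <- ordered[i[keep], , drop = FALSE]
  dplyr::mutate(out,
    from_trial = .data$trial_in_block,
    to_trial = ordered$trial_in_block[j[keep]],
    delta_lick = ordered$lick_rate[j[keep]] - .data$lick_rate
  ) |>
    dplyr::select(-dplyr::any_of(c(
      "lick_rate", "trial_in_block", "da_response", "predicted_da",
      "rpe", "value_pre"
    )))
}
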