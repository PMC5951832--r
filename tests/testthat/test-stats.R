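test_that("the exact signed-rank null matches brute-force enumeration", {
  for (n in 3:8) {
    counts <- beliefrl:::signed_rank_null_counts(n)
    expect_equal(sum(counts), 2^n) # distribution sums to one over 2^n
    # enumerate every sign assignment directly
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    brute <- as.numeric(table(factor(signs %*% seq_len(n),
      levels = 0:(n * (n + 1) / 2)
    )))
    expect_equal(counts, brute)
  }
  # and the distribution function matches base R's for n up to 12
  for (n in 9:12) {
    counts <- beliefrl:::signed_rank_null_counts(n)
    expect_equal(cumsum(counts) / 2^n, psignrank(0:(n * (n + 1) / 2), n))
  }
})

test_that("reported signed-rank statistics reproduce their p-values", {
  expect_equal(wilcoxon_exact(w = 9, n = 11)$p_two_sided, 66 / 2048)
  expect_equal(round(wilcoxon_exact(w = 9, n = 11)$p_two_sided, 3), 0.032)
  expect_equal(wilcoxon_exact(w = 21, n = 11)$p_two_sided, 656 / 2048)
  expect_equal(round(wilcoxon_exact(w = 21, n = 11)$p_two_sided, 2), 0.32)
  # p is monotone non-decreasing in w below the null median, capped at 1
  ps <- vapply(0:33, function(w) wilcoxon_exact(w = w, n = 11)$p_two_sided, 1)
  expect_true(all(diff(ps) >= 0))
  expect_equal(max(ps), 1)
})

test_that("raw differences yield min(W+, W-) and exactness is guarded", {
  d <- c(1.2, -0.4, 2.5, 0.3, -3.1)
  res <- wilcoxon_exact(differences = d)
  # ranks of |d|: 0.3 < 0.4 < 1.2 < 2.5 < 3.1; W+ = 1 + 3 + 4 = 8, W- = 7
  expect_equal(res$w_statistic, 7)
  expect_equal(res$n, 5)
  expect_equal(
    res$p_two_sided,
    suppressWarnings(wilcox.test(d, exact = TRUE)$p.value)
  )
  expect_error(wilcoxon_exact(differences = c(1, 0, -2)), "Zero")
  expect_error(wilcoxon_exact(differences = c(1, -1, 2)), "Tied")
  expect_error(wilcoxon_exact(w = 5, n = 31), "n <= 30")
})

test_that("correlation tests match a hand computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.0, 2.9, 4.2, 4.8, 6.1)
  # hand oracle from the definition of Pearson's r
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  res <- corr_with_test(x, y, "one_tailed_positive")
  expect_equal(res$r, r_hand)
  expect_equal(res$t, t_hand)
  expect_equal(res$p, pt(t_hand, 3, lower.tail = FALSE))
  expect_equal(corr_with_test(x, x + 0:4 * 0.001)$r, cor(x, x + 0:4 * 0.001))
  expect_equal(corr_with_test(x, 2 * x + 1, "one_tailed_positive")$r, 1)
  set.seed(2)
  null <- corr_with_test(rnorm(500), rnorm(500))
  expect_lt(abs(null$r), 0.15)
  expect_error(corr_with_test(x, rep(1, 5)), "variance")
  expect_error(corr_with_test(1:2, 1:2), "length")
})

test_that("polynomial fits report honest adjusted r-squared", {
  x <- seq(-1, 1, length.out = 9)
  y <- 2 - x + 0.5 * x^3
  cub <- suppressWarnings(polyfit_adjusted_r2(x, y, 3))
  expect_equal(cub$adj_r_squared, 1)
  expect_equal(unname(cub$coefficients), c(2, -1, 0, 0.5), tolerance = 1e-8)
  # on exactly linear data the cubic gains nothing and cannot beat the
  # degree-1 fit after the adjustment penalty
  yl <- 1 + 2 * x
  expect_gte(
    suppressWarnings(polyfit_adjusted_r2(x, yl, 1))$adj_r_squared,
    suppressWarnings(polyfit_adjusted_r2(x, yl, 3))$adj_r_squared
  )
  expect_error(polyfit_adjusted_r2(x[1:4], y[1:4], 3), "Underdetermined")
  # belief-model trial-2 predictions are better described by a cubic
  vols <- c(1, 2, 4, 6, 8, 10)
  out <- run_model(toy_blocks(vols), rl_params("bs_fixed", sigma2 = 0.05))
  d2 <- out$rpe[out$trial_in_block == 2]
  expect_gt(
    polyfit_adjusted_r2(vols, d2, 3)$adj_r_squared,
    polyfit_adjusted_r2(vols, d2, 1)$adj_r_squared
  )
})

test_that("lick-rate deltas respect day and block boundaries", {
  trials <- tibble::tibble(
    day = c(1, 1, 1, 1, 2, 2), block_index = c(1, 1, 2, 2, 1, 1),
    trial_in_block = c(1, 2, 1, 2, 1, 2),
    lick_rate = c(2, 5, 1, 1, 4, 7)
  )
  d <- delta_lick(trials)
  expect_equal(d$delta_lick, c(3, 0, 3))
  expect_equal(d$from_trial, c(1, 1, 1))
  # across-block transitions only when requested, never across days
  d2 <- delta_lick(trials, within_block = FALSE)
  expect_equal(nrow(d2), 4)
  expect_equal(d2$delta_lick, c(3, -4, 0, 3))
  # constant licking gives all-zero deltas
  expect_true(all(delta_lick(dplyr::mutate(trials, lick_rate = 3))$delta_lick == 0))
})

test_that("model-driven licking changes mirror the RPE pattern", {
  p <- rl_params("bs_two_prior",
    alpha = 0.2, sigma2 = 0.05, gain = 2,
    prior_after_s1 = 0.7, prior_after_s2 = 0.7
  )
  m <- generate_mouse(p,
    schedule_config = list(include = "probe", n_days_probe = 12),
    noise_sd_da = 0, lick_noise_sd = 0, seed = 31
  )
  deltas <- delta_lick(m$trials) |>
    dplyr::group_by(reward_volume_ul, from_trial) |>
    dplyr::summarise(delta = mean(delta_lick), .groups = "drop")
  t12 <- dplyr::filter(deltas, from_trial == 1) |> dplyr::arrange(reward_volume_ul)
  t23 <- dplyr::filter(deltas, from_trial == 2) |> dplyr::arrange(reward_volume_ul)
  # trial 1 -> 2: licking increases after large rewards and decreases after
  # small ones, separating the volume groups
  expect_gt(min(t12$delta[t12$reward_volume_ul >= 6]), 0)
  expect_lt(max(t12$delta[t12$reward_volume_ul <= 4]), 0)
  # trial 2 -> 3: non-monotonic, positive for small intermediates and
  # negative for large ones
  expect_gt(t23$delta[t23$reward_volume_ul == 2], 0)
  expect_lt(t23$delta[t23$reward_volume_ul == 8], 0)
  expect_false(all(diff(t23$delta) > 0) || all(diff(t23$delta) < 0))
  # the underlying expected value change from trial 1 to 2 is strictly
  # increasing in reward at a fixed context and frozen asymptotic weights
  p0 <- rl_params("bs_two_prior",
    alpha = 0, sigma2 = 0.05,
    prior_after_s1 = 0.7, prior_after_s2 = 0.7
  )
  vchange <- vapply(c(1, 2, 4, 6, 8, 10), function(v) {
    out <- run_model(toy_blocks(v, prev = "s1"), p0, weights_init = "asymptotic")
    out$value_pre[2] - out$value_pre[1]
  }, numeric(1))
  expect_true(all(diff(vchange) > 0))
})
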