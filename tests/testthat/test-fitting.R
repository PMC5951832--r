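test_that("condition averages are plain per-key means", {
  trials <- tibble::tibble(
    reward_volume_ul = c(10, 10, 1, 2),
    trial_in_block = c(1L, 1L, 2L, 1L),
    prev_block_type = c("s1", "s1", "s1", "s2"),
    da_response = c(0.4, 0.6, -0.1, 0.25)
  )
  ca <- condition_average(trials)
  expect_equal(nrow(ca), 3)
  expect_equal(ca$mean_da[ca$reward_volume_ul == 10], 0.5)
  expect_equal(ca$mean_da[ca$reward_volume_ul == 1], -0.1) # singleton passes through
  # n-weighted grand mean of condition means equals the overall mean
  expect_equal(
    sum(ca$mean_da * ca$n_trials) / sum(ca$n_trials),
    mean(trials$da_response)
  )
  expect_error(condition_average(dplyr::mutate(trials, da_response = NA)), "response")
})

test_that("the profiled-Gaussian NLL matches a direct RSS computation", {
  m <- small_probe_mouse(noise_sd_da = 0.2, seed = 6, n_days_probe = 2)
  cond <- condition_average(m$trials)
  p <- rl_params("bs_two_prior",
    alpha = 0.1, sigma2 = 0.05, gain = 1.5,
    prior_after_s1 = 0.6, prior_after_s2 = 0.6
  )
  nll <- negative_log_likelihood(p, m$trials, cond)
  # independent oracle: predicted condition means via run_model + dplyr,
  # then the closed-form concentrated Gaussian likelihood
  pred <- condition_average(run_model(m$trials, p), "predicted_da")
  both <- dplyr::inner_join(cond, pred,
    by = c("reward_volume_ul", "trial_in_block", "prev_block_type"),
    suffix = c("_obs", "_pred")
  )
  expect_equal(nrow(both), nrow(cond))
  rss <- sum((both$mean_da_obs - both$mean_da_pred)^2)
  n <- nrow(both)
  expect_equal(nll, n / 2 * (log(2 * pi * rss / n) + 1), tolerance = 1e-12)
  # monotone in the residual scale: doubling all residuals increases NLL
  infl <- cond
  infl$mean_da <- both$mean_da_pred + 2 * (both$mean_da_obs - both$mean_da_pred)
  expect_gt(negative_log_likelihood(p, m$trials, infl), nll)
  # a perfect fit hits the floored analytic minimum and stays finite
  perfect <- cond
  perfect$mean_da <- both$mean_da_pred
  expect_true(is.finite(negative_log_likelihood(p, m$trials, perfect)))
})

test_that("zero-noise fits recover the generating parameters", {
  truth_b <- rl_params("bs_two_prior",
    alpha = 0.15, sigma2 = 0.07, gain = 2.5,
    prior_after_s1 = 0.7, prior_after_s2 = 0.62
  )
  mb <- generate_mouse(truth_b,
    schedule_config = list(include = "probe", n_days_probe = 12),
    noise_sd_da = 0, seed = 5
  )
  fb <- fit_model(mb$trials, "bs_two_prior", seed = 11)
  want <- c(
    alpha = 0.15, gain = 2.5, sigma2 = 0.07,
    prior_after_s1 = 0.7, prior_after_s2 = 0.62
  )
  expect_true(all(abs(fb$par[names(want)] - want) / want < 0.02))

  truth_s <- rl_params("std_dual",
    alpha = 0.2, gain = 1.8,
    init_after_s1 = 0.25, init_after_s2 = 0.8
  )
  ms <- generate_mouse(truth_s,
    schedule_config = list(include = "probe", n_days_probe = 12),
    noise_sd_da = 0, seed = 6
  )
  fs <- fit_model(ms$trials, "std_dual", seed = 12)
  want_s <- c(alpha = 0.2, gain = 1.8, init_after_s1 = 0.25, init_after_s2 = 0.8)
  expect_true(all(abs(fs$par[names(want_s)] - want_s) / want_s < 0.02))
})

test_that("fits are seeded, bounded, and report their best start", {
  m <- small_probe_mouse(noise_sd_da = 0.3, seed = 9, n_days_probe = 2)
  f1 <- fit_model(m$trials, "bs_one_prior", seed = 4)
  f2 <- fit_model(m$trials, "bs_one_prior", seed = 4)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$starts$nll, f2$starts$nll)
  layout <- beliefrl:::param_layout("bs_one_prior")
  expect_true(all(f1$par >= layout$lower & f1$par <= layout$upper))
  expect_equal(f1$nll, min(f1$starts$nll))
  expect_equal(nrow(f1$starts), 5)
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$bic, f1$n_params * log(f1$n_obs) + 2 * f1$nll)
})

test_that("the standard model cannot absorb the belief model's trial-2 pattern", {
  m <- small_probe_mouse(noise_sd_da = 0, seed = 14, n_days_probe = 12)
  f <- fit_model(m$trials, "std_dual", seed = 21)
  trace <- run_model(m$trials, f$params)
  resid <- condition_average(dplyr::mutate(m$trials,
    resid = da_response - trace$predicted_da
  ), "resid") |>
    dplyr::filter(trial_in_block == 2) |>
    dplyr::group_by(reward_volume_ul) |>
    dplyr::summarise(resid = stats::weighted.mean(mean_da, n_trials))
  # the linear model over-predicts small intermediates and under-predicts
  # big ones relative to the non-monotonic data
  expect_gt(resid$resid[resid$reward_volume_ul == 2], 0)
  expect_lt(resid$resid[resid$reward_volume_ul == 8], 0)
})
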