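# build a minimal trial table of single-volume blocks, one per (volume,
# context) pair, for probing per-trial model output
toy_blocks <- function(volumes, prev = "s1", n_trials = 5) {
  purrr::map_dfr(seq_along(volumes), function(i) {
    tibble::tibble(
      day = 1L, block_index = i, trial_in_block = seq_len(n_trials),
      block_type = "intermediate", reward_volume_ul = volumes[i],
      reward_norm = normalize_reward(volumes[i]), prev_block_type = prev,
      phase = "probe"
    )
  })
}

# reference belief-model forward pass built from the exported primitives;
# independent of the compiled path it is used to check
ref_run_belief <- function(trials, params, w0, credit = "posterior") {
  pri <- beliefrl:::prior_matrix(params)
  k <- length(params$state_means)
  n <- nrow(trials)
  out <- matrix(NA_real_, n, 3 + 2 * k)
  w <- w0
  b <- NULL
  for (i in seq_len(n)) {
    if (trials$trial_in_block[i] == 1) {
      b <- pri[match(trials$prev_block_type[i], c("none", "s1", "s2")), ]
    }
    v <- belief_value(b, w)
    d <- standard_rpe(trials$reward_norm[i], v)
    bp <- belief_posterior(b, trials$reward_norm[i], params$state_means, params$sigma2)
    out[i, ] <- c(v, d, params$gain * d + params$offset, b, bp)
    w <- belief_weight_update(w, params$alpha, d, if (credit == "posterior") bp else b)
    b <- bp
  }
  colnames(out) <- c(
    "value_pre", "rpe", "predicted_da",
    paste0("b", seq_len(k), "_pre"), paste0("b", seq_len(k), "_post")
  )
  tibble::as_tibble(out)
}

# reference standard-model forward pass
ref_run_standard <- function(trials, params) {
  n <- nrow(trials)
  inits <- c(
    none = mean(c(params$init_after_s1, params$init_after_s2)),
    s1 = params$init_after_s1, s2 = params$init_after_s2
  )
  v <- NA_real_
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (trials$trial_in_block[i] == 1) v <- inits[[trials$prev_block_type[i]]]
    d <- trials$reward_norm[i] - v
    out[i, ] <- c(v, d, params$gain * d + params$offset)
    v <- standard_value_update(v, params$alpha, d)
  }
  colnames(out) <- c("value_pre", "rpe", "predicted_da")
  tibble::as_tibble(out)
}

# a small probe-phase mouse used by several suites
small_probe_mouse <- function(noise_sd_da = 0, seed = 3, n_days_probe = 4,
                              params = NULL) {
  if (is.null(params)) params <- rl_params("bs_two_prior",
    alpha = 0.12, sigma2 = 0.06,
    gain = 2, prior_after_s1 = 0.7, prior_after_s2 = 0.65
  )
  generate_mouse(params,
    schedule_config = list(include = "probe", n_days_probe = n_days_probe),
    noise_sd_da = noise_sd_da, seed = seed
  )
}
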