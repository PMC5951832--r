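#' Generate a synthetic mouse dataset
#'
#' Simulates one mouse: a trial schedule, a forward model run under known
#' ("true") parameters, and noisy observables — a per-trial dopamine
#' response (`da_response = predicted_da + N(0, noise_sd_da^2)`) and an
#' anticipatory lick rate, modelled as an affine, floor-clipped function of
#' the pre-outcome value, `lick_rate = max(0, lick_intercept + lick_slope *
#' value_pre + N(0, lick_noise_sd^2))`. Everything is reproducible from
#' `seed`.
#'
#' @param params True generating parameters ([rl_params()]).
#' @param trials Optional trial table; by default a full training history is
#'   generated with [generate_task_history()] under `schedule_config`.
#' @param schedule_config Named list of arguments passed to
#'   [generate_task_history()] when `trials` is `NULL`.
#' @param noise_sd_da Per-trial Gaussian noise sd of the dopamine response
#'   (dF/F-scale units).
#' @param lick_slope,lick_intercept,lick_noise_sd Lick model parameters
#'   (licks/s per unit value, licks/s, licks/s).
#' @param weights_init,credit_belief Passed to [run_model()].
#' @param seed Integer seed.
#' @param mouse_id Label for the mouse.
#' @return An object of class `synthetic_mouse`: a list with the trial-level
#'   tibble `$trials` (schedule + model trace + `da_response`, `lick_rate`),
#'   the generating `$true_params`, `$generating_model`, the noise settings
#'   and `$seed`.
#' @export
generate_mouse <- function(params, trials = NULL, schedule_config = list(),
                           noise_sd_da = 0.2, lick_slope = 6, lick_intercept = 1,
                           lick_noise_sd = 0.5, weights_init = "asymptotic",
                           credit_belief = "posterior", seed = 1,
                           mouse_id = "m01") {
  stopifnot(inherits(params, "rl_params"))
  if (noise_sd_da < 0 || lick_noise_sd < 0) abort("Noise sds must be non-negative.")
  if (is.null(trials)) {
    trials <- do.call(
      generate_task_history,
      utils::modifyList(list(seed = seed), schedule_config)
    )
  }
  trace <- run_model(trials, params,
    weights_init = weights_init,
    credit_belief = credit_belief
  )
  trace <- with_seed(seed + 7L, function() {
    n <- nrow(trace)
    dplyr::mutate(trace,
      mouse_id = mouse_id, .before = 1
    ) |>
      dplyr::mutate(
        da_response = .data$predicted_da + rnorm(n, 0, noise_sd_da),
        lick_rate = pmax(0, lick_intercept + lick_slope * .data$value_pre +
          rnorm(n, 0, lick_noise_sd))
      )
  })
  structure(
    list(
      mouse_id = mouse_id, generating_model = params$variant,
      true_params = params, trials = trace,
      noise_sd_da = noise_sd_da,
      lick = list(slope = lick_slope, intercept = lick_intercept, sd = lick_noise_sd),
      weights_init = weights_init, credit_belief = credit_belief, seed = seed
    ),
    class = "synthetic_mouse"
  )
}

#' @export
print.synthetic_mouse <- function(x, ...) {
  cat(
    "<synthetic_mouse", x$mouse_id, "| model", x$generating_model, "|",
    nrow(x$trials), "trials | noise_sd_da", x$noise_sd_da, ">\n"
  )
  invisible(x)
}

# draw per-mouse true parameters inside the fitting bounds; documented in the
# methods vignette
draw_true_params <- function(variant) {
  alpha <- runif(1, 0.05, 0.25)
  gain <- runif(1, 1, 5)
  if (is_belief_variant(variant)) {
    rl_params(variant,
      alpha = alpha, gain = gain,
      sigma2 = runif(1, 0.03, 0.15),
      prior_after_s1 = runif(1, 0.55, 0.8),
      prior_after_s2 = runif(1, 0.55, 0.8),
      prior_intermediate = runif(1, 0.05, 0.3)
    )
  } else if (variant == "std_dual") {
    rl_params(variant,
      alpha = alpha, gain = gain,
      init_after_s1 = runif(1, 0.1, 0.35),
      init_after_s2 = runif(1, 0.65, 0.9)
    )
  } else {
    rl_params(variant, alpha = alpha, gain = gain, init_value = runif(1, 0.3, 0.7))
  }
}

#' Generate a synthetic cohort of mice
#'
#' Draws per-mouse true parameters from realistic ranges inside the fitting
#' bounds and generates each mouse with a distinct seed.
#'
#' @param n_mice Number of mice.
#' @param generating_model Variant label, recycled to length `n_mice` — a
#'   mixed vector gives a mixed cohort, with each mouse's generating model
#'   recorded.
#' @param seed Integer seed; mouse `i` uses `seed + i`.
#' @param noise_sd_da Either a single sd in dF/F units or `NULL`, in which
#'   case each mouse's sd is `0.2 * gain` (noise scales with its response
#'   gain).
#' @param ... Passed on to [generate_mouse()] (e.g. `schedule_config`,
#'   `weights_init`).
#' @return A list of `synthetic_mouse` objects with a `truth` attribute: a
#'   tibble of the true parameter values per mouse.
#' @export
generate_cohort <- function(n_mice, generating_model = "bs_two_prior", seed = 1,
                            noise_sd_da = NULL, ...) {
  stopifnot(n_mice >= 1)
  models <- rep_len(generating_model, n_mice)
  mice <- purrr::map(seq_len(n_mice), function(i) {
    pars <- with_seed(seed + i, function() draw_true_params(models[i]))
    sdda <- noise_sd_da %||% (0.2 * pars$gain)
    generate_mouse(pars,
      noise_sd_da = sdda, seed = seed + i,
      mouse_id = sprintf("m%02d", i), ...
    )
  })
  truth <- purrr::map_dfr(mice, function(m) {
    p <- m$true_params
    tibble::tibble(
      mouse_id = m$mouse_id, generating_model = m$generating_model,
      tibble::as_tibble(p[intersect(
        names(p),
        c(
          "alpha", "gain", "sigma2", "prior_after_s1", "prior_after_s2",
          "prior_intermediate", "init_after_s1", "init_after_s2"
        )
      )]),
      noise_sd_da = m$noise_sd_da
    )
  })
  attr(mice, "truth") <- truth
  mice
}

#' Bind the trial tables of a cohort into one tibble
#'
#' @param cohort List of `synthetic_mouse` objects.
#' @return Trial-level tibble across mice.
#' @export
cohort_trials <- function(cohort) {
  purrr::map_dfr(cohort, "trials")
}

# difference-of-exponentials calcium-indicator kernel, peak-normalized
calcium_kernel <- function(fs, rise = 0.05, decay = 0.4, duration = 3) {
  t <- seq(0, duration, by = 1 / fs)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

#' Generate a raw fluorescence trace fixture for a synthetic mouse
#'
#' Builds a 1 kHz-style raw photometry trace for the first `n_trials` trials
#' of a mouse: a slowly bleaching multiplicative baseline modulated by
#' calcium-kernel transients at cue (CS) and reward (US) onsets, plus white
#' noise. US transient amplitudes equal the model-predicted dopamine
#' response (`gain * rpe`), CS amplitudes scale with the pre-outcome value,
#' so the photometry pipeline can be validated against known injected
#' amplitudes. Trial timing follows the task: a 2 s block-start tone ending
#' 3 s before the first odor, 1 s odor, 1 s delay, reward, then an
#' inter-trial interval of a fixed 4 s plus an Exponential(mean 4.7 s) tail
#' (mean ITI 8.7 s).
#'
#' @param mouse A `synthetic_mouse` object.
#' @param n_trials Number of trials to render (default 25; traces are
#'   generated at `fs` samples/s, so long fixtures are large).
#' @param fs Sampling rate in Hz (default 1000).
#' @param f_base Baseline fluorescence level (arbitrary units).
#' @param bleach_tau Bleaching time constant in seconds (`Inf` disables
#'   bleaching).
#' @param kernel_rise,kernel_decay Kernel time constants in seconds.
#' @param cs_scale Scaling from pre-outcome value to CS transient amplitude.
#' @param noise_sd White-noise sd on the raw trace (same units as `f_base`).
#' @param seed Integer seed for the ITI draws and noise.
#' @return An object of class `raw_trace`: list with `fluorescence` (numeric
#'   vector), `fs`, and `events` — a tibble per trial with `trial`,
#'   `sound_on` (block starts, `NA` otherwise), `odor_on`, `us_on` (times in
#'   s) and the injected `cs_amp`, `us_amp`.
#' @export
generate_raw_trace <- function(mouse, n_trials = 25, fs = 1000, f_base = 100,
                               bleach_tau = Inf, kernel_rise = 0.05,
                               kernel_decay = 0.4, cs_scale = 0.5,
                               noise_sd = 0, seed = 1) {
  stopifnot(inherits(mouse, "synthetic_mouse"))
  trials <- utils::head(mouse$trials, n_trials)
  if (nrow(trials) == 0) abort("`mouse` has an empty trial table.")

  with_seed(seed, function() {
    n <- nrow(trials)
    itis <- 4 + rexp(n, 1 / 4.7)
    block_start <- trials$trial_in_block == 1
    # tone lasts 2 s and ends 3 s before the first odor of the block
    pre <- ifelse(block_start, 6, 1) # seconds of lead-in before odor onset
    odor_on <- numeric(n)
    t0 <- 1 # leave 1 s of trace before anything happens
    for (i in seq_len(n)) {
      # event timestamps live on the acquisition clock: snap to the grid
      odor_on[i] <- round((t0 + pre[i]) * fs) / fs
      t0 <- odor_on[i] + 2 + itis[i] # odor 1 s + delay 1 s + ITI
    }
    us_on <- odor_on + 2
    sound_on <- ifelse(block_start, odor_on - 5, NA_real_)

    total_t <- max(us_on) + 3
    nsamp <- ceiling(total_t * fs) + 1L
    tgrid <- (seq_len(nsamp) - 1L) / fs
    kern <- calcium_kernel(fs, kernel_rise, kernel_decay)

    cs_amp <- cs_scale * trials$value_pre
    us_amp <- trials$predicted_da
    modulation <- numeric(nsamp)
    add_event <- function(onset, amp) {
      i0 <- round(onset * fs) + 1L
      idx <- i0:min(nsamp, i0 + length(kern) - 1L)
      modulation[idx] <<- modulation[idx] + amp * kern[seq_along(idx)]
    }
    for (i in seq_len(n)) {
      add_event(odor_on[i], cs_amp[i])
      add_event(us_on[i], us_amp[i])
    }
    baseline <- if (is.finite(bleach_tau)) f_base * exp(-tgrid / bleach_tau) else rep(f_base, nsamp)
    fluor <- baseline * (1 + modulation) + rnorm(nsamp, 0, noise_sd)

    structure(
      list(
        fluorescence = fluor, fs = fs,
        events = tibble::tibble(
          trial = seq_len(n), sound_on = sound_on, odor_on = odor_on,
          us_on = us_on, cs_amp = cs_amp, us_amp = us_amp
        ),
        config = list(
          f_base = f_base, bleach_tau = bleach_tau, kernel_rise = kernel_rise,
          kernel_decay = kernel_decay, cs_scale = cs_scale,
          noise_sd = noise_sd, seed = seed
        )
      ),
      class = "raw_trace"
    )
  })
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(
    "<raw_trace |", length(x$fluorescence), "samples @", x$fs, "Hz |",
    nrow(x$events), "trials >\n"
  )
  invisible(x)
}
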