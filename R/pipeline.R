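#' Theoretical RPE curves of the two model classes
#'
#' Emits the reference prediction curves over the reward grid: the standard
#' single-state model's linear trial-1/trial-2 RPE, `delta(r) = r - 0.5`
#' (state value 0.5, the average of the two training rewards), and the
#' belief-state model's trial-2 RPE at training asymptote,
#' `delta(r) = r - b(s2 | r)` with the logistic posterior
#' `b(s2 | r) = 1 / (1 + exp((1 - 2r) / (2 sigma2)))` implied by a flat
#' prior and unit-separated Gaussian reward likelihoods. The belief curve is
#' non-monotonic: positive below the midpoint, negative above it.
#'
#' @param sigma2 Sensory noise variance for the belief curve (default 0.05).
#' @param volumes Reward volumes (uL) at which to tabulate, in addition to a
#'   dense normalized grid.
#' @param n_grid Size of the dense grid over `[0, 1]`.
#' @return Tibble with columns `model`, `reward_norm`, `reward_volume_ul`
#'   (`NA` on grid-only points), `trial`, `rpe`.
#' @export
reproduce_predictions <- function(sigma2 = 0.05, volumes = c(1, 2, 4, 6, 8, 10),
                                  n_grid = 101) {
  grid <- sort(unique(c(seq(0, 1, length.out = n_grid), normalize_reward(volumes))))
  vol <- (grid * 9) + 1
  vol[!vol %in% volumes] <- NA_real_
  belief_b2 <- 1 / (1 + exp((1 - 2 * grid) / (2 * sigma2)))
  dplyr::bind_rows(
    tibble::tibble(
      model = "standard", reward_norm = grid, reward_volume_ul = vol,
      trial = 2L, rpe = grid - 0.5
    ),
    tibble::tibble(
      model = "belief", reward_norm = grid, reward_volume_ul = vol,
      trial = 2L, rpe = grid - belief_b2
    )
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML or JSON configuration for [run_pipeline()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list.
#' @examples
#' cfg <- read_pipeline_config(
#'   system.file("extdata", "example-config.yaml", package = "beliefrl")
#' )
#' cfg$variants
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("Config must be a .yaml/.yml or .json file.")
  }
}

#' Default pipeline configuration
#'
#' @param ... Overrides merged over the defaults.
#' @return Named list: cohort size and generating model, schedule settings,
#'   noise, fitting options, model set, seed.
#' @export
default_pipeline_config <- function(...) {
  utils::modifyList(list(
    n_mice = 11,
    generating_model = "bs_two_prior",
    schedule_config = list(include = "probe", n_days_probe = 24),
    noise_sd_da = NULL,
    weights_init = "asymptotic",
    variants = model_variants(),
    n_starts = 5,
    mc_samples = 1e6,
    seed = 1
  ), list(...))
}

#' Run the full simulation-to-selection pipeline
#'
#' Ties the stages together: generate a synthetic cohort, fit every model
#' variant to each mouse's condition-averaged dopamine responses, compare
#' the variants across the cohort (BIC + random-effects Bayesian model
#' selection), and compute the summary statistics — per-mouse correlations
#' between anticipatory licking and the fitted belief-state vs standard
#' values with the signed-rank comparison, and linear/cubic fits to the
#' trial-1 and trial-2 RPE patterns. Optionally writes CSV/JSON outputs,
#' figures and the resolved configuration to `out_dir`.
#'
#' @param config List from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param quiet Suppress per-stage messages.
#' @return List with `cohort`, `fits`, `selection`, `stats` (list of
#'   `lick_value`, `signed_rank`, `trial_curves`), `predictions`, `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what, expr) {
    say("[%s] %s ...", format(Sys.time() - t0, digits = 3), what)
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage \"%s\" failed: %s", what, conditionMessage(e)))
    })
  }

  cohort <- stage("simulate cohort", generate_cohort(
    config$n_mice, config$generating_model,
    seed = config$seed, noise_sd_da = config$noise_sd_da,
    schedule_config = config$schedule_config,
    weights_init = config$weights_init
  ))
  fits <- stage("fit models", fit_cohort(cohort,
    variants = config$variants,
    seed = config$seed, n_starts = config$n_starts,
    weights_init = config$weights_init
  ))
  selection <- stage("model selection", select_cohort(fits,
    mc_samples = config$mc_samples, seed = config$seed
  ))
  stats <- stage("statistics", pipeline_stats(cohort, fits))
  predictions <- reproduce_predictions()

  result <- list(
    cohort = cohort, fits = fits, selection = selection, stats = stats,
    predictions = predictions, config = config
  )
  if (!is.null(out_dir)) {
    stage("write outputs", write_pipeline_outputs(result, out_dir))
  }
  say("[%s] done", format(Sys.time() - t0, digits = 3))
  result
}

# per-mouse lick-value correlations for the two headline variants, plus the
# signed-rank comparison of the correlation coefficients
pipeline_stats <- function(cohort, fits) {
  variants <- intersect(c("bs_two_prior", "std_dual"), unique(fits$variant))
  lick_value <- purrr::map_dfr(cohort, function(m) {
    purrr::map_dfr(variants, function(v) {
      f <- fits$fit[fits$mouse_id == m$mouse_id & fits$variant == v][[1]]
      trace <- run_model(m$trials, f$params,
        weights_init = f$weights_init,
        credit_belief = f$credit_belief
      )
      ct <- corr_with_test(trace$value_pre, m$trials$lick_rate, "one_tailed_positive")
      dplyr::mutate(ct, mouse_id = m$mouse_id, variant = v, .before = 1)
    })
  })
  signed_rank <- NULL
  if (length(variants) == 2) {
    wide <- tidyr::pivot_wider(
      dplyr::select(lick_value, "mouse_id", "variant", "r"),
      names_from = "variant", values_from = "r"
    )
    d <- wide$bs_two_prior - wide$std_dual
    signed_rank <- tryCatch(wilcoxon_exact(differences = d), error = function(e) NULL)
  }

  trial_curves <- purrr::map_dfr(cohort, function(m) {
    condition_average(m$trials) |>
      dplyr::filter(.data$trial_in_block <= 2) |>
      dplyr::group_by(.data$reward_volume_ul, .data$trial_in_block) |>
      dplyr::summarise(
        mean_da = stats::weighted.mean(.data$mean_da, .data$n_trials),
        .groups = "drop"
      ) |>
      dplyr::mutate(mouse_id = m$mouse_id, .before = 1)
  })
  curve_fits <- trial_curves |>
    dplyr::group_by(.data$reward_volume_ul, .data$trial_in_block) |>
    dplyr::summarise(mean_da = mean(.data$mean_da), .groups = "drop") |>
    dplyr::group_by(.data$trial_in_block) |>
    dplyr::group_modify(function(d, key) {
      lin <- polyfit_adjusted_r2(d$reward_volume_ul, d$mean_da, 1)
      cub <- polyfit_adjusted_r2(d$reward_volume_ul, d$mean_da, 3)
      tibble::tibble(
        adj_r2_linear = lin$adj_r_squared,
        adj_r2_cubic = cub$adj_r_squared
      )
    }) |>
    dplyr::ungroup()

  list(
    lick_value = lick_value, signed_rank = signed_rank,
    trial_curves = trial_curves, curve_fits = curve_fits
  )
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  utils::write.csv(cohort_trials(result$cohort),
    file.path(out_dir, "trials.csv"),
    row.names = FALSE
  )
  utils::write.csv(dplyr::select(result$fits, -"fit"),
    file.path(out_dir, "fits.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$selection$ranking,
    file.path(out_dir, "model_ranking.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$predictions,
    file.path(out_dir, "predicted_rpe_curves.csv"),
    row.names = FALSE
  )
  if (!is.null(result$stats$signed_rank)) {
    jsonlite::write_json(as.list(result$stats$signed_rank),
      file.path(out_dir, "signed_rank.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  figs <- list(
    rpe_curves = plot_rpe_curves(result$predictions),
    trial_responses = plot_trial_responses(result$stats$trial_curves),
    model_ranking = autoplot(result$selection)
  )
  for (nm in names(figs)) {
    ggplot2::ggsave(file.path(out_dir, paste0(nm, ".pdf")), figs[[nm]],
      width = 6, height = 4
    )
  }
  invisible(out_dir)
}
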