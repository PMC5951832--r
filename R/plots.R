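#' Plot theoretical RPE curves
#'
#' Reward prediction error versus normalized reward for the standard and
#' belief-state models (see [reproduce_predictions()]).
#'
#' @param predictions Tibble from [reproduce_predictions()].
#' @return A ggplot object.
#' @export
plot_rpe_curves <- function(predictions = reproduce_predictions()) {
  ggplot2::ggplot(
    predictions,
    ggplot2::aes(.data$reward_norm, .data$rpe, colour = .data$model)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, !is.na(.data$reward_volume_ul))) +
    ggplot2::labs(
      x = "normalized reward", y = "reward prediction error",
      colour = NULL, title = "Trial-2 RPE: linear vs belief-state"
    ) +
    ggplot2::theme_minimal()
}

#' Plot condition-averaged responses across rewards by trial
#'
#' @param trial_curves Tibble with `reward_volume_ul`, `trial_in_block`,
#'   `mean_da` (and optionally `mouse_id`, averaged over).
#' @return A ggplot object.
#' @export
plot_trial_responses <- function(trial_curves) {
  summarised <- trial_curves |>
    dplyr::group_by(.data$reward_volume_ul, .data$trial_in_block) |>
    dplyr::summarise(mean_da = mean(.data$mean_da), .groups = "drop")
  ggplot2::ggplot(
    summarised,
    ggplot2::aes(.data$reward_volume_ul, .data$mean_da)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~trial_in_block, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "reward volume (µL)", y = "mean dopamine response",
      title = "Reward responses across volumes by trial"
    ) +
    ggplot2::theme_minimal()
}

#' Plot observed vs fitted condition averages of an `rl_fit`
#'
#' Shows the fitted model's predicted condition averages against the
#' observed ones, by trial-in-block.
#'
#' @param object An `rl_fit` object.
#' @param trials The trial table the fit used.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rl_fit <- function(object, trials, ...) {
  trace <- run_model(trials, object$params,
    weights_init = object$weights_init, credit_belief = object$credit_belief
  )
  pred <- condition_average(trace, "predicted_da") |>
    dplyr::rename(predicted = "mean_da")
  both <- dplyr::left_join(object$conditions, pred,
    by = c("reward_volume_ul", "trial_in_block", "prev_block_type")
  )
  ggplot2::ggplot(both, ggplot2::aes(.data$reward_volume_ul)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_da, shape = .data$prev_block_type)) +
    ggplot2::geom_line(ggplot2::aes(
      y = .data$predicted,
      linetype = .data$prev_block_type
    )) +
    ggplot2::facet_wrap(~trial_in_block, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "reward volume (µL)", y = "dopamine response",
      title = paste("Observed vs fitted:", object$variant)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a cohort model comparison
#'
#' Bar chart of protected exceedance probabilities over model variants,
#' annotated with mean BIC.
#'
#' @param object A `cohort_selection` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_selection <- function(object, ...) {
  d <- dplyr::mutate(object$ranking,
    model = factor(.data$model, levels = .data$model)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$model, .data$pxp)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("BIC %.1f", .data$mean_bic)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(
      x = NULL, y = "protected exceedance probability",
      title = "Cohort model comparison"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot anticipatory licking against model value
#'
#' Scatter of per-trial anticipatory lick rate against the model's
#' pre-outcome value for one mouse.
#'
#' @param mouse A `synthetic_mouse` object.
#' @param fit Optional `rl_fit`; if supplied its fitted values are used,
#'   otherwise the generating model's.
#' @return A ggplot object.
#' @export
plot_value_licking <- function(mouse, fit = NULL) {
  value <- if (is.null(fit)) {
    mouse$trials$value_pre
  } else {
    run_model(mouse$trials, fit$params,
      weights_init = fit$weights_init,
      credit_belief = fit$credit_belief
    )$value_pre
  }
  d <- tibble::tibble(value = value, lick_rate = mouse$trials$lick_rate)
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$lick_rate)) +
    ggplot2::geom_point(alpha = 0.2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(
      x = "model value (pre-outcome)", y = "anticipatory licking (licks/s)",
      title = paste("Value vs licking:", mouse$mouse_id)
    ) +
    ggplot2::theme_minimal()
}
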