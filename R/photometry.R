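# sample index of a time point (1-based, floor: sample i covers
# [ (i-1)/fs, i/fs ) )
t_to_idx <- function(t, fs) as.integer(floor(t * fs + 1e-9)) + 1L

# mean of x over the half-open time window [from, to); truncates at trace
# boundaries with a warning
window_mean <- function(x, fs, from, to, what = "window", warn_truncate = TRUE) {
  i0 <- t_to_idx(from, fs)
  i1 <- t_to_idx(to, fs) - 1L
  if (i0 < 1L || i1 > length(x)) {
    if (warn_truncate) {
      warn(sprintf("%s [%.3f, %.3f) extends past the trace boundary; truncated.", what, from, to))
    }
    i0 <- max(i0, 1L)
    i1 <- min(i1, length(x))
  }
  if (i1 < i0) abort(sprintf("%s [%.3f, %.3f) contains no samples.", what, from, to))
  mean(x[i0:i1])
}

# running median with a centered window of `width` seconds; interior samples
# use stats::runmed, edge samples are recomputed with truncated windows
running_median <- function(x, fs, width = 60) {
  k <- 2L * as.integer(round(width * fs / 2)) + 1L # odd sample count
  if (k >= length(x)) {
    return(vapply(seq_along(x), function(i) {
      h <- (k - 1L) %/% 2L
      stats::median(x[max(1L, i - h):min(length(x), i + h)])
    }, numeric(1)))
  }
  out <- as.numeric(stats::runmed(x, k, endrule = "keep"))
  h <- (k - 1L) %/% 2L
  edge <- c(seq_len(h), seq(length(x) - h + 1L, length(x)))
  for (i in edge) {
    out[i] <- stats::median(x[max(1L, i - h):min(length(x), i + h)])
  }
  out
}

#' Compute dF/F from a raw fluorescence trace
#'
#' `dF/F = (F - F0) / F0`, with three baseline (`F0`) conventions:
#' * `pretrial` — for each trial, `F0` is the mean fluorescence over the 1 s
#'   before odor onset; every sample from that trial's start (1 s before
#'   odor) up to the next trial is corrected by it.
#' * `preblock` — `F0` is the mean over the 1 s before the block-start
#'   sound; all five trials of the block share it.
#' * `running_median` — `F0` at each sample is the median over a 60 s window
#'   centered on it (truncated at the trace edges).
#'
#' @param trace A `raw_trace` object (or list with `fluorescence`, `fs`,
#'   `events`).
#' @param method Baseline method.
#' @param median_window Window width in seconds for `running_median`.
#' @return The trace object with an added `dff` numeric vector and
#'   `baseline_method` recorded.
#' @export
compute_dff <- function(trace, method = c("pretrial", "preblock", "running_median"),
                        median_window = 60) {
  method <- match.arg(method)
  f <- trace$fluorescence
  fs <- trace$fs
  ev <- trace$events
  if (method == "running_median") {
    f0 <- running_median(f, fs, median_window)
  } else {
    # segment boundaries: each trial's correction applies from its segment
    # start to the next segment start
    if (method == "pretrial") {
      anchor <- ev$odor_on
      seg_f0 <- vapply(anchor, function(a) {
        window_mean(f, fs, a - 1, a, "pre-odor baseline window")
      }, numeric(1))
    } else {
      sound <- ev$sound_on
      if (all(is.na(sound))) abort("`preblock` baseline requires sound_on event times.")
      blk <- cumsum(!is.na(sound))
      if (any(blk == 0)) abort("Trials occur before the first block start.")
      block_f0 <- vapply(sound[!is.na(sound)], function(a) {
        window_mean(f, fs, a - 1, a, "pre-sound baseline window")
      }, numeric(1))
      seg_f0 <- block_f0[blk]
      anchor <- ifelse(is.na(sound), ev$odor_on, sound)
    }
    starts <- t_to_idx(anchor - 1, fs)
    starts[1] <- 1L
    ends <- c(starts[-1] - 1L, length(f))
    f0 <- numeric(length(f))
    for (i in seq_along(starts)) f0[starts[i]:ends[i]] <- seg_f0[i]
  }
  trace$dff <- (f - f0) / f0
  trace$baseline_method <- method
  trace
}

#' Quantify the reward (US) response of a dF/F trace
#'
#' The US response is baseline-corrected by subtracting the mean dF/F over
#' the 100 ms window centered on US onset; `us_mean` is then the mean and
#' `us_peak` the single-sample maximum of the corrected trace over the 1 s
#' half-open window `[onset, onset + 1 s)`.
#'
#' @param trace A trace with a `dff` component (see [compute_dff()]).
#' @param us_on US onset time(s) in seconds; defaults to the trace's events.
#' @return Tibble with columns `trial`, `us_mean`, `us_peak`,
#'   `baseline_method`.
#' @export
quantify_us <- function(trace, us_on = NULL) {
  us_on <- us_on %||% trace$events$us_on
  dff <- trace$dff
  fs <- trace$fs
  if (is.null(dff)) abort("Run `compute_dff()` first.")
  res <- purrr::map_dfr(seq_along(us_on), function(i) {
    on <- us_on[i]
    if (t_to_idx(on + 1, fs) - 1L > length(dff) || t_to_idx(on - 0.05, fs) < 1L) {
      abort(sprintf("Trace too short around US onset at %.3f s (need 50 ms before and 1 s after).", on))
    }
    base <- window_mean(dff, fs, on - 0.05, on + 0.05, "US baseline window")
    i0 <- t_to_idx(on, fs)
    i1 <- t_to_idx(on + 1, fs) - 1L
    seg <- dff[i0:i1] - base
    tibble::tibble(trial = i, us_mean = mean(seg), us_peak = max(seg))
  })
  res$baseline_method <- trace$baseline_method %||% NA_character_
  res
}

#' Quantify the cue (CS) response of a dF/F trace
#'
#' `cs_mean` is the mean dF/F over the 1 s half-open window after odor
#' onset, with no additional baseline correction.
#'
#' @inheritParams quantify_us
#' @param odor_on Odor onset time(s) in seconds; defaults to the trace's
#'   events.
#' @return Tibble with columns `trial`, `cs_mean`, `baseline_method`.
#' @export
quantify_cs <- function(trace, odor_on = NULL) {
  odor_on <- odor_on %||% trace$events$odor_on
  dff <- trace$dff
  fs <- trace$fs
  if (is.null(dff)) abort("Run `compute_dff()` first.")
  res <- purrr::map_dfr(seq_along(odor_on), function(i) {
    on <- odor_on[i]
    if (t_to_idx(on + 1, fs) - 1L > length(dff)) {
      abort(sprintf("Trace too short after odor onset at %.3f s.", on))
    }
    tibble::tibble(
      trial = i,
      cs_mean = window_mean(dff, fs, on, on + 1, "CS window")
    )
  })
  res$baseline_method <- trace$baseline_method %||% NA_character_
  res
}

#' Extract per-trial CS/US responses from a raw trace
#'
#' Convenience wrapper: computes dF/F with the chosen baseline method and
#' quantifies CS and US responses for every trial.
#'
#' @inheritParams compute_dff
#' @return Tibble with one row per trial: `trial`, `cs_mean`, `us_mean`,
#'   `us_peak`, `baseline_method`.
#' @export
extract_trial_responses <- function(trace, method = "pretrial", median_window = 60) {
  trace <- compute_dff(trace, method, median_window)
  dplyr::left_join(
    quantify_cs(trace),
    quantify_us(trace),
    by = c("trial", "baseline_method")
  ) |>
    dplyr::select("trial", "cs_mean", "us_mean", "us_peak", "baseline_method")
}

#' Min-max normalization against trial-1 responses
#'
#' Rescales responses by a reference condition's range:
#' `y = (x - min(trial1)) / (max(trial1) - min(trial1))`, so the trial-1
#' minimum maps to 0 and the trial-1 maximum to 1. Other trials may fall
#' outside `[0, 1]`. Used only for cross-animal display, never for fitting.
#'
#' @param x Responses to rescale.
#' @param trial1_responses Reference responses (>= 2 distinct values).
#' @return Rescaled numeric vector.
#' @export
minmax_normalize <- function(x, trial1_responses) {
  rng <- range(trial1_responses)
  if (length(trial1_responses) < 2 || diff(rng) == 0) {
    abort("`trial1_responses` must contain at least two distinct values.")
  }
  (x - rng[1]) / diff(rng)
}
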