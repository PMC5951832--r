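#' Map a reward volume to the model's normalized reward scale
#'
#' The two training blocks anchor the scale: the small block (1 uL) maps to a
#' normalized reward of 0 and the big block (10 uL) to 1. Intermediate volumes
#' map linearly, `(volume - 1) / 9`.
#'
#' @param volume Reward volume in microlitres; vectorized. Must lie in
#'   `[1, 10]`.
#' @return Numeric vector of normalized rewards in `[0, 1]`.
#' @examples
#' normalize_reward(c(1, 5.5, 10))
#' @export
normalize_reward <- function(volume) {
  if (!is.numeric(volume) || anyNA(volume)) {
    abort("`volume` must be numeric with no missing values.")
  }
  if (any(volume < 1 | volume > 10)) {
    abort("`volume` must lie in [1, 10] microlitres.")
  }
  (volume - 1) / 9
}

block_volume <- function(block_type) {
  # training block identity fixes the volume; intermediate volumes are chosen
  # by the probe scheduler
  dplyr::case_match(block_type, "s1" ~ 1, "s2" ~ 10)
}

#' Generate one phase of the blocked conditioning schedule
#'
#' Builds a block-level schedule for `n_days` days of training. Each day holds
#' `blocks_per_day` blocks of five identical trials. In the `deterministic`
#' phase, small (`s1`, 1 uL) and big (`s2`, 10 uL) blocks strictly alternate;
#' in the `probabilistic` phase the block type switches with probability 0.5
#' at every block start.
#'
#' @param n_days Number of days to generate (>= 1).
#' @param phase `"deterministic"` or `"probabilistic"`.
#' @param blocks_per_day Blocks per day (default 30, i.e. 150 trials/day).
#' @param seed Integer seed; all randomness in the schedule flows from it.
#' @param start_block Block type of the first block of each deterministic day
#'   (`"s1"` or `"s2"`); ignored in the probabilistic phase, where the first
#'   type of the history is drawn at random.
#' @param day_offset Added to the day index, so that phases can be
#'   concatenated into one history.
#' @return A block-level tibble with columns `day`, `block_index`,
#'   `block_type`, `reward_volume_ul`, `phase`.
#' @seealso [generate_probe_schedule()], [schedule_trials()]
#' @export
generate_training_schedule <- function(n_days, phase = c("deterministic", "probabilistic"),
                                       blocks_per_day = 30, seed = 1,
                                       start_block = "s1", day_offset = 0) {
  phase <- tryCatch(match.arg(phase), error = function(e) {
    abort("`phase` must be \"deterministic\" or \"probabilistic\".")
  })
  stopifnot(n_days >= 1, blocks_per_day >= 1)
  if (!start_block %in% c("s1", "s2")) abort("`start_block` must be \"s1\" or \"s2\".")

  n_blocks <- n_days * blocks_per_day
  types <- if (phase == "deterministic") {
    first <- match(start_block, c("s1", "s2")) - 1L
    per_day <- c("s1", "s2")[(first + seq_len(blocks_per_day) - 1L) %% 2L + 1L]
    rep(per_day, n_days)
  } else {
    with_seed(seed, function() {
      switches <- rbinom(n_blocks, 1L, 0.5)
      # first draw sets the initial type; later draws are block-change coin flips
      cumsum(switches) %% 2L
    }) |>
      (\(idx) c("s1", "s2")[idx + 1L])()
  }

  tibble::tibble(
    day = rep(seq_len(n_days), each = blocks_per_day) + day_offset,
    block_index = rep(seq_len(blocks_per_day), n_days),
    block_type = types,
    reward_volume_ul = block_volume(types),
    phase = phase
  )
}

#' Insert intermediate-reward probe blocks into a schedule
#'
#' On each probe day, three training blocks (10% of a 30-block day) are
#' replaced by intermediate reward blocks with distinct volumes drawn from
#' {2, 4, 6, 8} uL, so that no intermediate volume appears more than once per
#' day. By default probe days are every other day of the input schedule,
#' starting with its first day. Replacement positions are uniform among
#' non-first blocks of the day.
#'
#' @param base Block-level schedule tibble (see
#'   [generate_training_schedule()]).
#' @param seed Integer seed controlling volume choice and placement.
#' @param probe_days Which days of `base` are probe days; defaults to every
#'   other day starting at the first.
#' @param n_probe_blocks Number of blocks replaced per probe day (default 3).
#' @return The schedule with replaced blocks marked `block_type =
#'   "intermediate"` and `phase = "probe"` on probe days.
#' @export
generate_probe_schedule <- function(base, seed = 1, probe_days = NULL,
                                    n_probe_blocks = 3) {
  stopifnot(is.data.frame(base))
  days <- sort(unique(base$day))
  probe_days <- probe_days %||% days[seq(1, length(days), by = 2)]
  if (n_probe_blocks > length(INTERMEDIATE_VOLUMES)) {
    abort("At most one probe block per intermediate volume per day is allowed.")
  }

  with_seed(seed, function() {
    out <- dplyr::mutate(base, phase = ifelse(.data$day %in% probe_days, "probe", .data$phase))
    for (d in probe_days) {
      idx <- which(out$day == d)
      candidates <- idx[out$block_index[idx] != 1L]
      if (length(candidates) < n_probe_blocks) {
        abort("Fewer replaceable (non-first) blocks than probe blocks requested.")
      }
      pos <- sample(candidates, n_probe_blocks)
      vols <- sample(INTERMEDIATE_VOLUMES, n_probe_blocks)
      out$block_type[pos] <- "intermediate"
      out$reward_volume_ul[pos] <- vols
    }
    out
  })
}

#' Expand a block-level schedule into a trial table
#'
#' Each block becomes `n_trials` rows (five identical trials). The previous
#' block's type is carried onto every trial as the context `prev_block_type`;
#' the first block of a history has context `"none"`. A preceding
#' intermediate block is assigned the training state nearest in volume
#' (2, 4 uL -> `"s1"`; 6, 8 uL -> `"s2"`), since the spec of the context is a
#' training-state label.
#'
#' @param schedule Block-level schedule tibble.
#' @param n_trials Trials per block (default 5).
#' @return Trial-level tibble with columns `day`, `block_index`,
#'   `trial_in_block`, `block_type`, `reward_volume_ul`, `reward_norm`,
#'   `prev_block_type`, `phase`.
#' @export
schedule_trials <- function(schedule, n_trials = 5) {
  stopifnot(is.data.frame(schedule), n_trials >= 1)
  prev_type <- dplyr::lag(schedule$block_type)
  prev_vol <- dplyr::lag(schedule$reward_volume_ul)
  ctx <- dplyr::case_when(
    is.na(prev_type) ~ "none",
    prev_type == "intermediate" & prev_vol <= 5 ~ "s1",
    prev_type == "intermediate" ~ "s2",
    TRUE ~ prev_type
  )
  blocks <- dplyr::mutate(schedule, prev_block_type = ctx)
  tidyr::uncount(blocks, n_trials, .id = "trial_in_block") |>
    dplyr::mutate(
      trial_in_block = as.integer(.data$trial_in_block),
      reward_norm = normalize_reward(.data$reward_volume_ul)
    ) |>
    dplyr::select(
      "day", "block_index", "trial_in_block", "block_type",
      "reward_volume_ul", "reward_norm", "prev_block_type", "phase"
    )
}

#' Generate a full multi-phase training history
#'
#' Concatenates the three phases of the paradigm into one trial table:
#' an initial deterministic phase with strictly alternating blocks, a
#' probabilistic phase (block change with probability 0.5), and a probe phase
#' in which every other day contains three intermediate-reward blocks. The
#' defaults reproduce the exposure statistics of the study design (about
#' 3,960 trials of each training block and about 45 trials per intermediate
#' volume per mouse).
#'
#' @param n_days_deterministic,n_days_probabilistic,n_days_probe Days per
#'   phase (defaults 10, 20, 24).
#' @param blocks_per_day Blocks per day (default 30).
#' @param seed Integer seed.
#' @param include Character vector of phases to include; e.g. `"probe"` alone
#'   yields a probe-phase-only history (useful for fitting at training
#'   asymptote).
#' @return Trial-level tibble (see [schedule_trials()]).
#' @export
generate_task_history <- function(n_days_deterministic = 10,
                                  n_days_probabilistic = 20,
                                  n_days_probe = 24,
                                  blocks_per_day = 30, seed = 1,
                                  include = c("deterministic", "probabilistic", "probe")) {
  include <- match.arg(include, several.ok = TRUE)
  parts <- list()
  offset <- 0
  if ("deterministic" %in% include && n_days_deterministic > 0) {
    parts$det <- generate_training_schedule(
      n_days_deterministic, "deterministic", blocks_per_day,
      seed = seed, day_offset = offset
    )
    offset <- offset + n_days_deterministic
  }
  if ("probabilistic" %in% include && n_days_probabilistic > 0) {
    parts$prob <- generate_training_schedule(
      n_days_probabilistic, "probabilistic", blocks_per_day,
      seed = seed + 1L, day_offset = offset
    )
    offset <- offset + n_days_probabilistic
  }
  if ("probe" %in% include && n_days_probe > 0) {
    base <- generate_training_schedule(
      n_days_probe, "probabilistic", blocks_per_day,
      seed = seed + 2L, day_offset = offset
    )
    parts$probe <- generate_probe_schedule(base, seed = seed + 3L)
  }
  if (!length(parts)) abort("No phase selected.")
  schedule_trials(dplyr::bind_rows(parts))
}
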