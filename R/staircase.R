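#' Staircase configuration
#'
#' Parameters of one interleaved dual-staircase calibration. The material
#' staircase moves one step at a time in both directions; the colour staircase
#' (50 steps) uses accelerated schedules: progression jumps of 5, 4, 2, then 1
#' step indexed by the number of prior incorrect identifications, and
#' regression jumps of 4, 3, 2, then 1. Both schedules floor at 1. Two
#' consecutive correct identifications are required per progression; after
#' five reversals (incorrect identifications) the staircase asks for one final
#' correct confirmation before terminating.
#'
#' @param kind `"material"` or `"colour"`; fills in the standard defaults.
#' @param n_steps Continuum length (default 10 for material, 50 for colour).
#' @param consecutive_correct_required Correct responses needed to progress (2).
#' @param progression_schedule Jump sizes indexed (1-based) by number of prior
#'   incorrect identifications; values past the end repeat the last entry.
#' @param regression_schedule Jump sizes indexed likewise by which incorrect
#'   identification this is.
#' @param reversals_to_terminate Reversals before the confirmation phase (5).
#' @param high_disc_max_step Largest step index eligible as a
#'   high-discriminability stimulus (2).
#' @return A list of class `staircase_config`.
#' @export
staircase_config <- function(kind = c("material", "colour"),
                             n_steps = NULL,
                             consecutive_correct_required = 2L,
                             progression_schedule = NULL,
                             regression_schedule = NULL,
                             reversals_to_terminate = 5L,
                             high_disc_max_step = 2L) {
  kind <- match.arg(kind)
  if (is.null(n_steps)) n_steps <- if (kind == "material") 10L else 50L
  if (is.null(progression_schedule)) {
    progression_schedule <- if (kind == "material") 1L else c(5L, 4L, 2L, 1L)
  }
  if (is.null(regression_schedule)) {
    regression_schedule <- if (kind == "material") 1L else c(4L, 3L, 2L, 1L)
  }
  stopifnot(
    n_steps >= 2, consecutive_correct_required >= 1,
    all(progression_schedule >= 1), all(regression_schedule >= 1),
    all(diff(progression_schedule) <= 0), all(diff(regression_schedule) <= 0),
    reversals_to_terminate >= 1, high_disc_max_step >= 1
  )
  structure(list(
    kind = kind, n_steps = as.integer(n_steps),
    consecutive_correct_required = as.integer(consecutive_correct_required),
    progression_schedule = as.integer(progression_schedule),
    regression_schedule = as.integer(regression_schedule),
    reversals_to_terminate = as.integer(reversals_to_terminate),
    high_disc_max_step = as.integer(high_disc_max_step)
  ), class = "staircase_config")
}

#' Initialise a staircase
#'
#' Positions are counted from this staircase's own starting end: position 1 is
#' the high-discriminability start stimulus.
#'
#' @param config A `staircase_config`.
#' @return A list of class `staircase_state` with fields `position`,
#'   `n_incorrect`, `n_reversals`, `consecutive_correct`, `terminated`,
#'   `awaiting_confirmation`, and a `history` data frame (append-only records
#'   of position, response label, correctness).
#' @export
new_staircase <- function(config) {
  structure(list(
    position = 1L, n_incorrect = 0L, n_reversals = 0L,
    consecutive_correct = 0L, terminated = FALSE, awaiting_confirmation = FALSE,
    history = tibble::tibble(
      position = integer(), label = character(), correct = logical()
    )
  ), class = "staircase_state")
}

# schedule lookup: k prior incorrects (0-based count) -> jump size, floored at
# the final schedule entry
schedule_jump <- function(schedule, n_prior_incorrect) {
  schedule[min(n_prior_incorrect + 1L, length(schedule))]
}

#' Advance a staircase by one response
#'
#' Core update rule. A correct response increments the consecutive-correct
#' counter; on reaching the required count the position advances by the
#' progression-schedule jump for the current number of prior incorrect
#' identifications (clamped to the continuum) and the counter resets. An
#' incorrect response (a reversal) resets the counter, increments the
#' incorrect/reversal counts, and regresses the position by the
#' regression-schedule jump. After the terminal reversal count the staircase
#' enters a confirmation phase: the next correct response terminates it.
#'
#' @param state A `staircase_state` (not yet terminated).
#' @param correct Logical: was the response the staircase's own category label?
#' @param config The `staircase_config`.
#' @param label Optional response label recorded in the history.
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(state, correct, config, label = NA_character_) {
  if (state$terminated) stop_invalid("cannot update a terminated staircase")
  state$history <- dplyr::bind_rows(
    state$history,
    tibble::tibble(position = state$position, label = label, correct = correct)
  )
  if (correct) {
    if (state$awaiting_confirmation) {
      state$terminated <- TRUE
      return(state)
    }
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= config$consecutive_correct_required) {
      jump <- schedule_jump(config$progression_schedule, state$n_incorrect)
      state$position <- clamp(state$position + jump, 1L, config$n_steps)
      state$consecutive_correct <- 0L
    }
  } else {
    state$consecutive_correct <- 0L
    state$n_incorrect <- state$n_incorrect + 1L
    # the reversal counter saturates at the termination threshold
    state$n_reversals <- min(state$n_reversals + 1L, config$reversals_to_terminate)
    jump <- schedule_jump(config$regression_schedule, state$n_incorrect - 1L)
    state$position <- clamp(state$position - jump, 1L, config$n_steps)
    if (state$n_reversals >= config$reversals_to_terminate) {
      state$awaiting_confirmation <- TRUE
    }
  }
  state
}

#' Extract the low-discriminability stimulus from a terminated staircase
#'
#' The stimulus of the final correct identification, in this staircase's own
#' position coordinates.
#'
#' @param state A terminated `staircase_state`.
#' @return Step index (own coordinates).
#' @export
extract_low_disc <- function(state) {
  if (!state$terminated) stop_invalid("staircase has not terminated")
  ok <- which(state$history$correct)
  if (length(ok) == 0) stop_invalid("calibration failure: no correct identifications")
  state$history$position[max(ok)]
}

#' Extract the high-discriminability stimulus from a staircase run
#'
#' A history record qualifies if (1) no reversal had occurred in the staircase
#' up to that point, (2) the response was correct, and (3) the step index was
#' at most `config$high_disc_max_step`. Returns the position of the last
#' qualifying record, or `NA` if none exists (a calibration failure signalled
#' upstream).
#'
#' @param state A `staircase_state`.
#' @param config The `staircase_config`.
#' @return Step index (own coordinates) or `NA_integer_`.
#' @export
extract_high_disc <- function(state, config) {
  h <- state$history
  if (nrow(h) == 0) return(NA_integer_)
  reversals_before <- cumsum(!h$correct) - (!h$correct)  # reversals strictly before each record
  ok <- h$correct & reversals_before == 0 & h$position <= config$high_disc_max_step
  if (!any(ok)) return(NA_integer_)
  h$position[max(which(ok))]
}

# map a staircase's own position to an absolute continuum index;
# staircase "B" starts from the far end
absolute_position <- function(position, start_end, n_steps) {
  if (start_end == "A") position else n_steps - position + 1L
}

#' Run an interleaved dual staircase
#'
#' Two staircases run simultaneously from opposing ends of one continuum with
#' strictly alternating trials (staircase A on odd trials, B on even); once
#' one terminates, remaining trials go to the other. The responder is asked to
#' label the stimulus at an absolute continuum index; a response is "correct"
#' for a staircase when it matches that staircase's own starting-category
#' label. The run stops when both staircases terminate or the trial cap is
#' reached.
#'
#' @param responder Function `(position, labels)` returning one of
#'   `labels` (a character pair `c(label_A, label_B)` where `label_A` names the
#'   index-1 end). Typically built with [observer_responder()].
#' @param config A `staircase_config`.
#' @param labels Character pair naming the two ends of the continuum.
#' @param trial_cap Maximum total trials before giving up (default 500).
#' @return A list of class `calibration_result`: absolute step indices
#'   `high_disc_A`, `high_disc_B`, `low_disc_A`, `low_disc_B`, a `success`
#'   flag (all four defined), and `log`, a tibble of per-trial records.
#' @export
run_dual_staircase <- function(responder, config, labels = c("A", "B"),
                               trial_cap = 500L) {
  sc <- list(A = new_staircase(config), B = new_staircase(config))
  own_label <- c(A = labels[1], B = labels[2])
  log <- vector("list", trial_cap)
  trial <- 0L
  turn <- "A"
  while (trial < trial_cap && !(sc$A$terminated && sc$B$terminated)) {
    if (sc[[turn]]$terminated) turn <- setdiff(c("A", "B"), turn)
    trial <- trial + 1L
    st <- sc[[turn]]
    abs_pos <- absolute_position(st$position, turn, config$n_steps)
    resp <- responder(abs_pos, labels)
    correct <- identical(resp, own_label[[turn]])
    sc[[turn]] <- update_staircase(st, correct, config, label = resp)
    log[[trial]] <- tibble::tibble(
      trial = trial, staircase = turn, position = st$position,
      abs_position = abs_pos, response = resp, correct = correct,
      n_reversals = sc[[turn]]$n_reversals
    )
    turn <- setdiff(c("A", "B"), turn)
  }
  success <- sc$A$terminated && sc$B$terminated
  res <- list(
    high_disc_A = NA_integer_, high_disc_B = NA_integer_,
    low_disc_A = NA_integer_, low_disc_B = NA_integer_,
    success = FALSE, labels = labels, n_steps = config$n_steps,
    log = dplyr::bind_rows(log[seq_len(trial)]),
    states = sc
  )
  if (success) {
    hA <- extract_high_disc(sc$A, config)
    hB <- extract_high_disc(sc$B, config)
    lA <- tryCatch(extract_low_disc(sc$A), error = function(e) NA_integer_)
    lB <- tryCatch(extract_low_disc(sc$B), error = function(e) NA_integer_)
    res$high_disc_A <- absolute_position(hA, "A", config$n_steps)
    res$high_disc_B <- absolute_position(hB, "B", config$n_steps)
    res$low_disc_A <- absolute_position(lA, "A", config$n_steps)
    res$low_disc_B <- absolute_position(lB, "B", config$n_steps)
    res$success <- !anyNA(c(res$high_disc_A, res$high_disc_B,
                            res$low_disc_A, res$low_disc_B))
  }
  structure(res, class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", x$labels[1], "--", x$labels[2],
      " (", x$n_steps, " steps)\n", sep = "")
  cat("  success:", x$success, "\n")
  cat(sprintf("  high-disc: %s=%s  %s=%s | low-disc: %s=%s  %s=%s\n",
              x$labels[1], x$high_disc_A, x$labels[2], x$high_disc_B,
              x$labels[1], x$low_disc_A, x$labels[2], x$low_disc_B))
  invisible(x)
}

#' Categorisation trials from a calibration log
#'
#' Flattens a dual-staircase log into the per-trial categorisation records
#' used for psychometric curve fitting: absolute continuum position and
#' whether the response was the far-end (`label_B`) category.
#'
#' @param calibration A `calibration_result`.
#' @return A tibble with columns `position` and `toward_B` (logical).
#' @export
staircase_trials <- function(calibration) {
  log <- calibration$log
  tibble::tibble(
    position = log$abs_position,
    toward_B = log$response == calibration$labels[2]
  )
}
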