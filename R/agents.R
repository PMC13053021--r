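#' Simulated psychophysical observer
#'
#' An observer categorises continuum stimuli according to a logistic
#' psychometric function with a lapse rate: the probability of choosing the
#' far-end category at absolute position `x` is
#' `gamma/2 + (1 - gamma) * plogis((x - boundary) / slope)`.
#'
#' @param boundary Real-valued continuum position of the category boundary.
#' @param slope Logistic scale (steps); smaller is steeper. Must be > 0.
#' @param lapse Lapse rate `gamma` in \[0, 0.5): probability of a
#'   stimulus-independent random response.
#' @return A list of class `simulated_observer`.
#' @export
simulated_observer <- function(boundary, slope, lapse = 0.02) {
  if (slope <= 0) stop_invalid("slope must be > 0")
  if (lapse < 0 || lapse >= 0.5) stop_invalid("lapse must be in [0, 0.5)")
  structure(list(boundary = boundary, slope = slope, lapse = lapse),
    class = "simulated_observer"
  )
}

#' Observer response probability
#'
#' Probability that the observer labels the stimulus at `position` with the
#' category of the far end of the continuum (`toward = "B"`), or the near end
#' (`toward = "A"`, the complement).
#'
#' @param o A [simulated_observer()].
#' @param position Absolute continuum step (may be fractional).
#' @param toward `"B"` (far end, index `n_steps`) or `"A"` (index-1 end).
#' @return A probability.
#' @export
observer_response_prob <- function(o, position, toward = c("B", "A")) {
  toward <- match.arg(toward)
  p <- o$lapse / 2 + (1 - o$lapse) * plogis((position - o$boundary) / o$slope)
  if (toward == "B") p else 1 - p
}

#' Build a staircase responder from an observer
#'
#' Returns a function `(position, labels)` drawing a category label for the
#' stimulus at an absolute continuum position, as required by
#' [run_dual_staircase()]. `labels[1]` names the index-1 end.
#'
#' @param o A [simulated_observer()].
#' @return A responder function.
#' @export
observer_responder <- function(o) {
  function(position, labels) {
    p_far <- observer_response_prob(o, position, "B")
    if (runif(1) < p_far) labels[2] else labels[1]
  }
}

#' Generative speaker coefficients for the two experiment designs
#'
#' Default effect sizes, on the log-odds scale, of the simulated speaker's
#' probability of upgrading a minimal expression to an overinformative one.
#' The Experiment-1 design matrix is dummy-coded with colour-redundant and
#' S-Low/R-High as reference levels; the Experiment-2 matrix is dummy-coded
#' with the high-frequency colour condition as reference.
#'
#' @return A named numeric vector of log-odds coefficients.
#' @export
exp1_speaker_coefficients <- function() {
  c(intercept = -2.50, material_redundant = -1.43,
    baseline = -0.94, s_high_r_low = -1.09)
}

#' @rdname exp1_speaker_coefficients
#' @export
exp2_speaker_coefficients <- function() {
  c(intercept = 0.97, colour_lf = -0.20, orientation = -0.97)
}

#' Simulated speaker
#'
#' A speaker produces, for each trial, either a non-demarcating expression
#' (with probability `underinform_rate`), or the minimal sufficient
#' expression, upgraded to the overinformative one with probability
#' `plogis(x'beta + u_j)` where `x` is the trial's dummy coding and `u_j` the
#' subject's random intercept. Attribute terms referring to
#' low-discriminability (boundary) stimuli are mislabelled with a probability
#' derived from the attached observers; nouns are never mislabelled by this
#' mechanism.
#'
#' @param coefficients Named log-odds coefficients
#'   ([exp1_speaker_coefficients()] or [exp2_speaker_coefficients()]).
#' @param subject_intercept_sd SD of the by-subject random intercept (>= 0).
#' @param underinform_rate Probability of producing a non-demarcating
#'   expression (Experiment 1: bare noun; Experiment 2: a mislabelled noun).
#' @param observers Optional named list of [simulated_observer()]s keyed by
#'   attribute, used to derive mislabelling probabilities for
#'   low-discriminability stimuli.
#' @return A list of class `simulated_speaker`.
#' @export
simulated_speaker <- function(coefficients, subject_intercept_sd = 0.8,
                              underinform_rate = 0.01, observers = NULL) {
  if (subject_intercept_sd < 0) stop_invalid("subject_intercept_sd must be >= 0")
  if (underinform_rate < 0 || underinform_rate > 1) {
    stop_invalid("underinform_rate must be a probability")
  }
  structure(list(
    coefficients = coefficients,
    subject_intercept_sd = subject_intercept_sd,
    underinform_rate = underinform_rate,
    observers = observers
  ), class = "simulated_speaker")
}

# probability that the speaker labels the stimulus at absolute step `step`
# (true category `category`, continuum ends named `labels`) with the *wrong*
# category, from the attached observer for that attribute
mislabel_prob <- function(speaker, attribute, step, category, labels) {
  o <- speaker$observers[[attribute]]
  if (is.null(o)) return(0)
  p_correct <- observer_response_prob(o, step,
    toward = if (category == labels[2]) "B" else "A"
  )
  1 - p_correct
}

maybe_mislabel <- function(speaker, attribute, term, trial) {
  low_col <- paste0(attribute, "_lowdisc")
  step_col <- paste0(attribute, "_step")
  if (!low_col %in% names(trial$items)) return(term)
  i <- trial$target
  if (!isTRUE(trial$items[[low_col]][i])) return(term)
  labels <- speaker$labels[[attribute]]
  if (is.null(labels)) return(term)
  p <- mislabel_prob(speaker, attribute, trial$items[[step_col]][i], term, labels)
  if (runif(1) < p) setdiff(labels, term) else term
}

exp1_linear_predictor <- function(beta, trial, u_j) {
  beta[["intercept"]] +
    beta[["material_redundant"]] * (trial$redundant_attribute == "material") +
    beta[["baseline"]] * (trial$display_type == "baseline") +
    beta[["s_high_r_low"]] * (trial$display_type == "s_high_r_low") +
    u_j
}

exp2_linear_predictor <- function(beta, trial, u_j) {
  beta[["intercept"]] +
    beta[["colour_lf"]] * (trial$condition == "colour_lf") +
    beta[["orientation"]] * (trial$condition == "orientation") +
    u_j
}

#' Sample one speaker response
#'
#' @param speaker A [simulated_speaker()].
#' @param trial A `ref_trial`.
#' @param u_j The subject's random intercept (log-odds).
#' @return A [ref_expression()].
#' @export
sample_speaker_response <- function(speaker, trial, u_j = 0) {
  beta <- speaker$coefficients
  exp1 <- !is.null(trial$display_type)
  if (exp1) {
    target <- trial$target
    suff <- trial$sufficient_attribute
    red <- trial$redundant_attribute
    if (runif(1) < speaker$underinform_rate) {
      return(ref_expression(noun = "bat"))
    }
    eta <- if (trial$is_filler) beta[["intercept"]] + u_j
           else exp1_linear_predictor(beta, trial, u_j)
    overinform <- runif(1) < plogis(eta)
    args <- list(noun = "bat")
    args[[suff]] <- maybe_mislabel(speaker, suff, trial$items[[suff]][target], trial)
    if (overinform) {
      args[[red]] <- maybe_mislabel(speaker, red, trial$items[[red]][target], trial)
    }
    do.call(ref_expression, args)
  } else {
    target <- trial$target
    noun <- trial$items$shape[target]
    if (runif(1) < speaker$underinform_rate) {
      noun <- sample(setdiff(exp2_shapes, noun), 1)  # mislabelled noun
    }
    eta <- exp2_linear_predictor(beta, trial, u_j)
    # fillers require the adjective; on critical trials it is the
    # overinformative upgrade
    overinform <- trial$is_filler || runif(1) < plogis(eta)
    args <- list(noun = noun)
    if (overinform) {
      args[[trial$attribute]] <- trial$items[[trial$attribute]][trial$target]
    }
    do.call(ref_expression, args)
  }
}

#' Default simulated-observer parameters
#'
#' Boundaries are drawn uniformly from the middle third of each continuum;
#' slopes are set so that aggregate psychometric curves show a smooth
#' sigmoidal transition over a handful of steps, and the lapse rate is 2%.
#'
#' @return A named list of lists (`colour`, `material`) with `slope`, `lapse`,
#'   and `boundary_range` as a fraction of the continuum.
#' @export
default_observer_params <- function() {
  list(
    colour = list(slope = 2.5, lapse = 0.02, boundary_range = c(1 / 3, 2 / 3)),
    material = list(slope = 0.8, lapse = 0.02, boundary_range = c(1 / 3, 2 / 3))
  )
}

draw_observer <- function(params, n_steps) {
  b <- runif(1, params$boundary_range[1] * n_steps, params$boundary_range[2] * n_steps)
  simulated_observer(boundary = b, slope = params$slope, lapse = params$lapse)
}

# the four colour-material assignment groups; materials are always labelled
# wood/metal from the participant's point of view
exp1_assignment_groups <- function() {
  list(
    list(materials = c("wood", "glass"), colours = c("blue", "green")),
    list(materials = c("cardboard", "metal"), colours = c("blue", "green")),
    list(materials = c("wood", "glass"), colours = c("yellow", "orange")),
    list(materials = c("cardboard", "metal"), colours = c("yellow", "orange"))
  )
}

#' Simulate Experiment 1 end to end
#'
#' For each simulated participant: draw colour and material observers, run the
#' interleaved dual staircases for both attributes, skip participants whose
#' calibration fails to define all four stimuli, generate a 60-trial session,
#' and sample director-task responses from the speaker model. Optional
#' "fatigue" participants answer with a bare noun from a random early trial
#' onwards, exercising the underinformativeness exclusion rule.
#'
#' @param n_subjects Number of recruited simulated participants (default 72).
#' @param coefficients Generative speaker coefficients
#'   (default [exp1_speaker_coefficients()]).
#' @param sigma_u By-subject intercept SD (default 0.8).
#' @param underinform_rate Per-trial probability of a bare-noun response.
#' @param observer_params As [default_observer_params()].
#' @param n_fatigue Number of injected fatigue participants (default 0).
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return A list of class `response_dataset`: `responses` (tibble, one row
#'   per trial per calibrated subject), `trials` (list of sessions keyed by
#'   subject), `calibrations`, `observers`, `excluded_calibration` (subject
#'   ids), `experiment = "exp1"`, and `params`.
#' @export
simulate_experiment1 <- function(n_subjects = 72,
                                 coefficients = exp1_speaker_coefficients(),
                                 sigma_u = 0.8,
                                 underinform_rate = 0.01,
                                 observer_params = default_observer_params(),
                                 n_fatigue = 0,
                                 seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  groups <- exp1_assignment_groups()
  cfg <- list(colour = staircase_config("colour"), material = staircase_config("material"))
  fatigue_ids <- if (n_fatigue > 0) sample.int(n_subjects, n_fatigue) else integer()

  responses <- vector("list", n_subjects)
  trials <- vector("list", n_subjects)
  calibrations <- vector("list", n_subjects)
  observers <- vector("list", n_subjects)
  excluded <- integer()

  for (j in seq_len(n_subjects)) {
    grp <- groups[[(j - 1) %% 4 + 1]]
    obs <- list(
      colour = draw_observer(observer_params$colour, cfg$colour$n_steps),
      material = draw_observer(observer_params$material, cfg$material$n_steps)
    )
    cal <- list(
      colour = run_dual_staircase(observer_responder(obs$colour), cfg$colour,
                                  labels = grp$colours),
      material = run_dual_staircase(observer_responder(obs$material), cfg$material,
                                    labels = c("wood", "metal"))
    )
    observers[[j]] <- obs
    calibrations[[j]] <- cal
    if (!cal$colour$success || !cal$material$success) {
      excluded <- c(excluded, j)
      next
    }
    session <- generate_exp1_session(cal)
    trials[[j]] <- session
    u_j <- rnorm(1, 0, sigma_u)
    speaker <- simulated_speaker(coefficients, sigma_u, underinform_rate, obs)
    speaker$labels <- list(colour = cal$colour$labels, material = cal$material$labels)
    fatigue_from <- if (j %in% fatigue_ids) sample(10:30, 1) else Inf

    responses[[j]] <- dplyr::bind_rows(purrr::map(session, function(tr) {
      expr <- if (tr$trial >= fatigue_from) {
        ref_expression(noun = "bat")
      } else {
        sample_speaker_response(speaker, tr, u_j)
      }
      tibble::tibble(
        subject = j, trial = tr$trial, is_filler = tr$is_filler,
        display_type = tr$display_type,
        redundant_attribute = tr$redundant_attribute,
        sufficient_attribute = tr$sufficient_attribute,
        colour_term = expr$colour %||% NA_character_,
        material_term = expr$material %||% NA_character_,
        noun = expr$noun %||% NA_character_
      )
    }))
  }

  structure(list(
    responses = dplyr::bind_rows(responses),
    trials = trials,
    calibrations = calibrations,
    observers = observers,
    excluded_calibration = excluded,
    experiment = "exp1",
    params = list(
      n_subjects = n_subjects, coefficients = coefficients, sigma_u = sigma_u,
      underinform_rate = underinform_rate, n_fatigue = n_fatigue, seed = seed
    )
  ), class = "response_dataset")
}

#' Simulate Experiment 2 end to end
#'
#' Three between-subject conditions (orientation, high-frequency colour,
#' low-frequency colour), `n_per_condition` simulated participants each, 48
#' trials per participant, responses sampled from the speaker model with
#' condition-level coefficients and by-subject intercepts.
#'
#' @param n_per_condition Participants per condition (default 20).
#' @param coefficients Generative coefficients
#'   (default [exp2_speaker_coefficients()]).
#' @param sigma_u By-subject intercept SD (default 0.8).
#' @param noun_mislabel_rate Per-trial probability of mislabelling the noun
#'   (producing a non-identifiable response).
#' @param seed Optional integer seed.
#' @return A `response_dataset` with `experiment = "exp2"`.
#' @export
simulate_experiment2 <- function(n_per_condition = 20,
                                 coefficients = exp2_speaker_coefficients(),
                                 sigma_u = 0.8,
                                 noun_mislabel_rate = 0.015,
                                 seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  conditions <- rep(c("orientation", "colour_hf", "colour_lf"),
                    each = n_per_condition)
  n <- length(conditions)
  responses <- vector("list", n)
  trials <- vector("list", n)
  for (j in seq_len(n)) {
    cond <- conditions[j]
    session <- generate_exp2_session(cond)
    trials[[j]] <- session
    u_j <- rnorm(1, 0, sigma_u)
    speaker <- simulated_speaker(coefficients, sigma_u, noun_mislabel_rate)
    responses[[j]] <- dplyr::bind_rows(purrr::map(session, function(tr) {
      expr <- sample_speaker_response(speaker, tr, u_j)
      tibble::tibble(
        subject = j, condition = cond, trial = tr$trial,
        is_filler = tr$is_filler, set_size = tr$set_size,
        n_distractors = tr$n_distractors,
        colour_term = expr$colour %||% NA_character_,
        orientation_term = expr$orientation %||% NA_character_,
        noun = expr$noun %||% NA_character_
      )
    }))
  }
  structure(list(
    responses = dplyr::bind_rows(responses),
    trials = trials,
    calibrations = NULL,
    experiment = "exp2",
    params = list(
      n_per_condition = n_per_condition, coefficients = coefficients,
      sigma_u = sigma_u, noun_mislabel_rate = noun_mislabel_rate, seed = seed
    )
  ), class = "response_dataset")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.response_dataset <- function(x, ...) {
  cat("<response_dataset> experiment:", x$experiment,
      "|", nrow(x$responses), "responses from",
      length(unique(x$responses$subject)), "subjects\n")
  if (length(x$excluded_calibration)) {
    cat("  calibration failures:", length(x$excluded_calibration), "\n")
  }
  invisible(x)
}
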