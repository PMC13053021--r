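# shared fixtures and independent oracles used across test files

# brute-force classification oracle: enumerate every subset of mentioned
# attribute terms (noun retained) and compute match sets directly, with no
# shared code with classify_expression's internals beyond the trial layout
brute_force_classify <- function(trial, expr) {
  slots <- c("colour", "material", "orientation")
  terms <- list()
  for (s in slots) if (!is.null(expr[[s]])) terms[[s]] <- expr[[s]]
  matches <- function(tm) {
    ok <- rep(TRUE, nrow(trial$items))
    for (a in names(tm)) {
      ok <- ok & (a %in% names(trial$items)) &
        (if (a %in% names(trial$items)) trial$items[[a]] == tm[[a]] else FALSE)
    }
    if (!is.null(expr$noun)) ok <- ok & trial$items$shape == expr$noun
    which(ok)
  }
  full <- matches(terms)
  identifiable <- length(full) == 1 && full == trial$target
  if (!identifiable) {
    return(list(category = "underinformative", identifiable = FALSE))
  }
  k <- length(terms)
  over <- FALSE
  if (k > 0) {
    for (mask in 0:(2^k - 2)) {  # all proper subsets incl. empty
      sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
      m <- matches(terms[sel])
      if (length(m) == 1 && m == trial$target) { over <- TRUE; break }
    }
  }
  list(category = if (over) "overinformative" else "minimal", identifiable = TRUE)
}

# a deterministic calibration fixture: high-disc at the ends, low-disc
# around the middle of each continuum
fixture_calibration <- function() {
  mk <- function(labels, n, hA, hB, lA, lB) {
    structure(list(
      high_disc_A = hA, high_disc_B = hB, low_disc_A = lA, low_disc_B = lB,
      success = TRUE, labels = labels, n_steps = n,
      log = tibble::tibble(), states = NULL
    ), class = "calibration_result")
  }
  list(
    colour = mk(c("blue", "green"), 50L, 1L, 50L, 24L, 27L),
    material = mk(c("wood", "metal"), 10L, 1L, 10L, 5L, 6L)
  )
}

# scripted responder: replays a fixed correct/incorrect tape for one
# staircase (used with direct update_staircase calls)
play_tape <- function(tape, config) {
  st <- new_staircase(config)
  positions <- integer(0)
  for (correct in tape) {
    positions <- c(positions, st$position)
    st <- update_staircase(st, correct, config)
  }
  list(state = st, positions = c(positions, st$position))
}

# a hand-built three-bat display matching the worked example:
# green/metal target among blue/metal distractors
example_display <- function(target = 1) {
  structure(list(
    items = tibble::tibble(
      shape = "bat",
      colour = c("green", "blue", "blue"),
      material = c("metal", "metal", "metal"),
      colour_step = c(50L, 1L, 1L),
      material_step = c(10L, 10L, 10L),
      colour_lowdisc = FALSE,
      material_lowdisc = FALSE,
      position = c("left", "middle", "right")
    ),
    target = target, display_type = "baseline",
    sufficient_attribute = "colour", redundant_attribute = "material",
    is_filler = FALSE
  ), class = "ref_trial")
}

# build a response_dataset by hand from a list of (trial, expression) pairs
# per subject, for coding/exclusion tests
manual_dataset <- function(subjects, experiment = "exp1") {
  responses <- list()
  trials <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    sess <- subjects[[j]]
    trials[[j]] <- lapply(seq_along(sess), function(i) {
      tr <- sess[[i]]$trial; tr$trial <- i; tr
    })
    for (i in seq_along(sess)) {
      e <- sess[[i]]$expr
      tr <- trials[[j]][[i]]
      responses[[length(responses) + 1]] <- tibble::tibble(
        subject = j, trial = i, is_filler = tr$is_filler,
        display_type = tr$display_type %||% NA_character_,
        redundant_attribute = tr$redundant_attribute %||% NA_character_,
        sufficient_attribute = tr$sufficient_attribute %||% NA_character_,
        colour_term = e$colour %||% NA_character_,
        material_term = e$material %||% NA_character_,
        noun = e$noun %||% NA_character_
      )
    }
  }
  structure(list(
    responses = dplyr::bind_rows(responses), trials = trials,
    experiment = experiment, params = list()
  ), class = "response_dataset")
}

`%||%` <- function(x, y) if (is.null(x)) y else x
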