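#' Referring expression
#'
#' A structured referring expression: at most one term per attribute slot plus
#' an optional noun. Unused slots are `NULL`.
#'
#' @param colour,material,orientation Optional attribute category labels.
#' @param noun Optional noun (object/shape label).
#' @return A list of class `ref_expression`.
#' @examples
#' ref_expression(colour = "green", noun = "bat")
#' @export
ref_expression <- function(colour = NULL, material = NULL, orientation = NULL,
                           noun = NULL) {
  e <- list(colour = colour, material = material, orientation = orientation,
            noun = noun)
  if (all(vapply(e, is.null, logical(1)))) stop_invalid("expression is empty")
  structure(e, class = "ref_expression")
}

expression_terms <- function(expr) {
  slots <- c("colour", "material", "orientation")
  present <- slots[!vapply(expr[slots], is.null, logical(1))]
  if (length(present) == 0) return(setNames(character(0), character(0)))
  setNames(unlist(expr[present]), present)
}

# items matching every mentioned term; noun constrains via the `shape` column
match_set <- function(items, terms, noun) {
  keep <- rep(TRUE, nrow(items))
  for (attr in names(terms)) {
    if (attr %in% names(items)) {
      keep <- keep & items[[attr]] == terms[[attr]]
    } else {
      keep <- rep(FALSE, nrow(items))  # term outside the trial's vocabulary
    }
  }
  if (!is.null(noun)) keep <- keep & items$shape == noun
  which(keep)
}

#' Classify a referring expression against a display
#'
#' An expression denotes the set of display items matching every mentioned
#' term. It is *identifiable* when that set is exactly the target. An
#' identifiable expression is *overinformative* when some proper subset of its
#' attribute terms (the noun, being grammatically obligatory, is always
#' retained) still identifies the target, and *minimal* otherwise. A
#' non-identifiable expression is *underinformative*.
#'
#' @param trial A trial object with `items` (tibble with a `shape` column and
#'   one column per attribute) and `target` (item index).
#' @param expr A [ref_expression()].
#' @return A list: `category` (`"underinformative"`, `"minimal"` or
#'   `"overinformative"`), `identifiable` (logical), `match_set` (item
#'   indices).
#' @export
classify_expression <- function(trial, expr) {
  stopifnot(inherits(expr, "ref_expression"))
  terms <- expression_terms(expr)
  m <- match_set(trial$items, terms, expr$noun)
  identifiable <- length(m) == 1 && m[1] == trial$target
  category <- "underinformative"
  if (identifiable) {
    category <- "minimal"
    k <- length(terms)
    if (k > 0) {
      # every proper subset of the attribute terms, noun retained
      for (size in 0:(k - 1)) {
        combos <- utils::combn(k, size, simplify = FALSE)
        for (idx in combos) {
          ms <- match_set(trial$items, terms[idx], expr$noun)
          if (length(ms) == 1 && ms[1] == trial$target) {
            category <- "overinformative"
            break
          }
        }
        if (category == "overinformative") break
      }
    }
  }
  list(category = category, identifiable = identifiable, match_set = m)
}

#' Listener feedback for a director-task response
#'
#' Thumbs-down when the expression fails to demarcate the target; a shrug when
#' it demarcates but overinforms on a filler trial (signalling graded
#' acceptability without penalising overinformativeness on critical trials);
#' thumbs-up otherwise.
#'
#' @param trial A trial object (with logical `is_filler`).
#' @param expr A [ref_expression()].
#' @return One of `"thumbs_down"`, `"shrug"`, `"thumbs_up"`.
#' @export
feedback <- function(trial, expr) {
  cls <- classify_expression(trial, expr)
  if (!cls$identifiable) return("thumbs_down")
  if (cls$category == "overinformative" && isTRUE(trial$is_filler)) return("shrug")
  "thumbs_up"
}

# -- Experiment 1: bat-factory displays --------------------------------------

# pull the calibrated stimulus (absolute step) for a category at a
# discriminability level from one attribute's calibration_result
calibrated_stimulus <- function(cal, category, level = c("high", "low")) {
  level <- match.arg(level)
  i <- match(category, cal$labels)
  if (is.na(i)) stop_invalid("unknown category label: ", category)
  field <- paste0(level, "_disc_", c("A", "B")[i])
  cal[[field]]
}

exp1_display_types <- c("baseline", "s_high_r_low", "s_low_r_high")

#' Build one Experiment-1 critical display
#'
#' Three bats, each carrying a colour stimulus (visual) and a material
#' stimulus (auditory). The sufficient attribute uniquely demarcates the
#' target: the target takes one category's stimulus and both distractors the
#' other category's high-discriminability stimulus. The redundant attribute is
#' one stimulus shared by all three items. Discriminability levels follow the
#' display type: `baseline` (sufficient high, redundant high),
#' `s_high_r_low`, `s_low_r_high`. Low-discriminability stimuli (the
#' participant's categorisation boundary) are placed on the target (sufficient
#' low) or shared by all items (redundant low).
#'
#' @param display_type One of `"baseline"`, `"s_high_r_low"`, `"s_low_r_high"`.
#' @param sufficient_attribute `"colour"` or `"material"`.
#' @param calibration Named list with `colour` and `material`
#'   [run_dual_staircase()] results, both successful.
#' @return A list of class `ref_trial`: `items` (tibble: shape, colour,
#'   material, colour_step, material_step, colour_lowdisc, material_lowdisc,
#'   position), `target`, `display_type`, `sufficient_attribute`,
#'   `redundant_attribute`, `is_filler`, and presentation `timing` in seconds
#'   (fall 0.8, sound 1.0, dwell 1.7).
#' @export
build_exp1_display <- function(display_type, sufficient_attribute, calibration) {
  display_type <- match.arg(display_type, exp1_display_types)
  sufficient_attribute <- match.arg(sufficient_attribute, c("colour", "material"))
  if (!calibration$colour$success || !calibration$material$success) {
    stop_invalid("calibration did not succeed for both attributes")
  }
  redundant <- setdiff(c("colour", "material"), sufficient_attribute)
  suff_level <- if (display_type == "s_low_r_high") "low" else "high"
  red_level <- if (display_type == "s_high_r_low") "low" else "high"

  suff_cal <- calibration[[sufficient_attribute]]
  red_cal <- calibration[[redundant]]
  target_cat <- sample(suff_cal$labels, 1)
  distractor_cat <- setdiff(suff_cal$labels, target_cat)
  shared_cat <- sample(red_cal$labels, 1)

  target_pos <- sample.int(3, 1)
  suff_cat <- ifelse(seq_len(3) == target_pos, target_cat, distractor_cat)
  suff_step <- ifelse(seq_len(3) == target_pos,
    calibrated_stimulus(suff_cal, target_cat, suff_level),
    calibrated_stimulus(suff_cal, distractor_cat, "high")
  )
  suff_low <- seq_len(3) == target_pos & suff_level == "low"
  red_step <- rep(calibrated_stimulus(red_cal, shared_cat, red_level), 3)
  red_low <- rep(red_level == "low", 3)

  items <- tibble::tibble(
    shape = "bat",
    position = c("left", "middle", "right")
  )
  items[[sufficient_attribute]] <- suff_cat
  items[[redundant]] <- rep(shared_cat, 3)
  items[[paste0(sufficient_attribute, "_step")]] <- as.integer(suff_step)
  items[[paste0(redundant, "_step")]] <- as.integer(red_step)
  items[[paste0(sufficient_attribute, "_lowdisc")]] <- suff_low
  items[[paste0(redundant, "_lowdisc")]] <- red_low

  structure(list(
    items = items[, c("shape", "colour", "material", "colour_step",
                      "material_step", "colour_lowdisc", "material_lowdisc",
                      "position")],
    target = target_pos,
    display_type = display_type,
    sufficient_attribute = sufficient_attribute,
    redundant_attribute = redundant,
    is_filler = FALSE,
    timing = c(fall = 0.8, sound = 1.0, dwell = 1.7)
  ), class = "ref_trial")
}

#' Build one Experiment-1 filler display
#'
#' All three bats are identical high-discriminability stimuli except the
#' target, which differs in exactly one attribute. Such displays make clear
#' that mentioning both attributes is never required.
#'
#' @param differ_attribute The single attribute in which the target differs.
#' @param calibration As in [build_exp1_display()].
#' @return A `ref_trial` with `is_filler = TRUE`.
#' @export
build_exp1_filler <- function(differ_attribute, calibration) {
  differ_attribute <- match.arg(differ_attribute, c("colour", "material"))
  if (!calibration$colour$success || !calibration$material$success) {
    stop_invalid("calibration did not succeed for both attributes")
  }
  same <- setdiff(c("colour", "material"), differ_attribute)
  d_cal <- calibration[[differ_attribute]]
  s_cal <- calibration[[same]]
  target_cat <- sample(d_cal$labels, 1)
  other_cat <- setdiff(d_cal$labels, target_cat)
  shared_cat <- sample(s_cal$labels, 1)
  target_pos <- sample.int(3, 1)

  items <- tibble::tibble(shape = "bat", position = c("left", "middle", "right"))
  items[[differ_attribute]] <- ifelse(seq_len(3) == target_pos, target_cat, other_cat)
  items[[same]] <- shared_cat
  items[[paste0(differ_attribute, "_step")]] <- as.integer(ifelse(
    seq_len(3) == target_pos,
    calibrated_stimulus(d_cal, target_cat, "high"),
    calibrated_stimulus(d_cal, other_cat, "high")
  ))
  items[[paste0(same, "_step")]] <- as.integer(calibrated_stimulus(s_cal, shared_cat, "high"))
  items[[paste0(differ_attribute, "_lowdisc")]] <- FALSE
  items[[paste0(same, "_lowdisc")]] <- FALSE

  structure(list(
    items = items[, c("shape", "colour", "material", "colour_step",
                      "material_step", "colour_lowdisc", "material_lowdisc",
                      "position")],
    target = target_pos,
    display_type = "filler",
    sufficient_attribute = differ_attribute,
    redundant_attribute = same,
    is_filler = TRUE,
    timing = c(fall = 0.8, sound = 1.0, dwell = 1.7)
  ), class = "ref_trial")
}

#' Generate a full Experiment-1 session
#'
#' 48 critical trials balanced over the three display types and the two
#' redundant-attribute assignments (8 per cell), plus 12 filler trials (6 per
#' differing attribute), in fully randomised order.
#'
#' @param calibration Named list with successful `colour` and `material`
#'   calibration results.
#' @return A list of 60 `ref_trial` objects, each with a `$trial` index.
#' @export
generate_exp1_session <- function(calibration) {
  cells <- expand.grid(
    display_type = exp1_display_types,
    sufficient_attribute = c("colour", "material"),
    rep = 1:8, stringsAsFactors = FALSE
  )
  critical <- purrr::pmap(
    cells[, 1:2],
    function(display_type, sufficient_attribute) {
      build_exp1_display(display_type, sufficient_attribute, calibration)
    }
  )
  fillers <- purrr::map(rep(c("colour", "material"), each = 6), function(a) {
    build_exp1_filler(a, calibration)
  })
  trials <- c(critical, fillers)[sample.int(60)]
  purrr::imap(trials, function(tr, i) { tr$trial <- i; tr })
}

# -- Experiment 2: shape-array displays --------------------------------------

exp2_shapes <- c("circle", "square", "pentagon", "hexagon")

exp2_condition_values <- function(condition) {
  switch(condition,
    orientation = list(attribute = "orientation", values = c("horizontal", "vertical")),
    colour_hf = list(attribute = "colour", values = c("green", "blue")),
    colour_lf = list(attribute = "colour", values = c("teal", "jade")),
    stop_invalid("unknown condition: ", condition)
  )
}

#' Build one Experiment-2 display
#'
#' Critical displays give the target a unique shape (so the noun alone
#' demarcates it) with exactly `n_distractors` non-target items sharing the
#' target's attribute value. Filler displays share the target's shape with at
#' least one distractor while its attribute value is unique, so adjective and
#' noun are jointly required.
#'
#' @param set_size Number of display items (3, 6, 9 or 16).
#' @param n_distractors Non-target items sharing the target's attribute value
#'   (0--4; set size 3 supports 0--1).
#' @param condition `"orientation"`, `"colour_hf"` or `"colour_lf"`.
#' @return A `ref_trial`.
#' @export
build_exp2_critical <- function(set_size, n_distractors, condition) {
  cv <- exp2_condition_values(condition)
  target_shape <- sample(exp2_shapes, 1)
  other_shapes <- sample(setdiff(exp2_shapes, target_shape), set_size - 1, replace = TRUE)
  target_value <- sample(cv$values, 1)
  other_value <- setdiff(cv$values, target_value)
  n_other <- set_size - 1
  shares <- c(rep(TRUE, n_distractors), rep(FALSE, n_other - n_distractors))[sample.int(n_other)]
  target_pos <- sample.int(set_size, 1)
  shape <- append(other_shapes, target_shape, after = target_pos - 1)
  value <- append(ifelse(shares, target_value, other_value), target_value,
                  after = target_pos - 1)
  items <- tibble::tibble(shape = shape, position = seq_len(set_size))
  items[[cv$attribute]] <- value
  structure(list(
    items = items, target = target_pos,
    condition = condition, attribute = cv$attribute,
    set_size = as.integer(set_size), n_distractors = as.integer(n_distractors),
    is_filler = FALSE
  ), class = "ref_trial")
}

#' @rdname build_exp2_critical
#' @export
build_exp2_filler <- function(set_size, condition) {
  cv <- exp2_condition_values(condition)
  target_shape <- sample(exp2_shapes, 1)
  # the target's shape is shared with at least one distractor and its
  # attribute value is unique, so adjective + noun are jointly required
  n_other <- set_size - 1
  other_shapes <- sample(c(target_shape,
                           sample(exp2_shapes, n_other - 1, replace = TRUE)))
  target_value <- sample(cv$values, 1)
  other_value <- setdiff(cv$values, target_value)
  target_pos <- sample.int(set_size, 1)
  shape <- append(other_shapes, target_shape, after = target_pos - 1)
  value <- append(rep(other_value, n_other), target_value, after = target_pos - 1)
  items <- tibble::tibble(shape = shape, position = seq_len(set_size))
  items[[cv$attribute]] <- value
  structure(list(
    items = items, target = target_pos,
    condition = condition, attribute = cv$attribute,
    set_size = as.integer(set_size), n_distractors = NA_integer_,
    is_filler = TRUE
  ), class = "ref_trial")
}

#' Generate a full Experiment-2 session
#'
#' 34 critical trials (every set-size by N-distractor combination exactly
#' twice: set size 3 with 0 or 1 distractors; set sizes 6, 9 and 16 with 0-4)
#' and 14 fillers in which adjective and noun are jointly required, in fully
#' randomised order. In critical trials the target's shape is unique, so the
#' noun alone always demarcates the target and any adjective is redundant.
#'
#' @param condition `"orientation"`, `"colour_hf"` (high-frequency colour
#'   terms green/blue) or `"colour_lf"` (low-frequency terms teal/jade).
#' @return A list of 48 `ref_trial` objects, each with a `$trial` index.
#' @export
generate_exp2_session <- function(condition = c("orientation", "colour_hf", "colour_lf")) {
  condition <- match.arg(condition)
  combos <- rbind(
    expand.grid(set_size = 3, n_distractors = 0:1),
    expand.grid(set_size = c(6, 9, 16), n_distractors = 0:4)
  )
  combos <- combos[rep(seq_len(nrow(combos)), 2), ]
  critical <- purrr::pmap(combos, function(set_size, n_distractors) {
    build_exp2_critical(set_size, n_distractors, condition)
  })
  filler_sizes <- rep(c(3, 6, 9, 16), length.out = 14)
  fillers <- purrr::map(filler_sizes, function(s) build_exp2_filler(s, condition))
  trials <- c(critical, fillers)[sample.int(48)]
  purrr::imap(trials, function(tr, i) { tr$trial <- i; tr })
}

#' Flatten a session to a per-item trial table
#'
#' One row per display item, suitable for CSV export.
#'
#' @param trials A list of `ref_trial` objects (one session).
#' @return A tibble with trial metadata and item attributes.
#' @export
session_table <- function(trials) {
  dplyr::bind_rows(purrr::map(trials, function(tr) {
    it <- tr$items
    it$trial <- tr$trial
    it$role <- ifelse(seq_len(nrow(it)) == tr$target, "target", "distractor")
    it$display_type <- if (!is.null(tr$display_type)) tr$display_type else NA_character_
    it$condition <- if (!is.null(tr$condition)) tr$condition else NA_character_
    it$is_filler <- tr$is_filler
    it
  }))
}
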