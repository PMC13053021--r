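test_that("expression classification matches the worked bat-factory example", {
  tr <- example_display(target = 1)
  expect_equal(classify_expression(tr, ref_expression(colour = "green", noun = "bat"))$category,
               "minimal")
  expect_equal(classify_expression(tr, ref_expression(colour = "green",
                                                      material = "metal",
                                                      noun = "bat"))$category,
               "overinformative")
  cls <- classify_expression(tr, ref_expression(material = "metal", noun = "bat"))
  expect_equal(cls$category, "underinformative")
  expect_false(cls$identifiable)
  expect_equal(cls$match_set, 1:3)
  # a term outside the display vocabulary matches nothing
  expect_false(classify_expression(tr, ref_expression(colour = "red", noun = "bat"))$identifiable)
})

test_that("classification agrees with brute-force subset enumeration", {
  set.seed(101)
  cal <- fixture_calibration()
  vocab <- list(colour = c("blue", "green", "red"), material = c("wood", "metal"))
  for (i in 1:40) {
    tr <- if (i %% 2 == 0) {
      build_exp1_display(sample(c("baseline", "s_high_r_low", "s_low_r_high"), 1),
                         sample(c("colour", "material"), 1), cal)
    } else {
      build_exp2_critical(sample(c(3, 6, 9), 1), sample(0:1, 1), "colour_hf")
    }
    for (k in 1:5) {
      args <- list(noun = sample(c("bat", "circle", "square", "pentagon", "hexagon"), 1))
      for (a in intersect(names(vocab), names(tr$items))) {
        if (runif(1) < 0.6) args[[a]] <- sample(vocab[[a]], 1)
      }
      if (runif(1) < 0.2) args$noun <- NULL
      if (length(args) == 0) next
      e <- do.call(ref_expression, args)
      got <- classify_expression(tr, e)
      want <- brute_force_classify(tr, e)
      expect_equal(got$category, want$category)
      expect_equal(got$identifiable, want$identifiable)
    }
  }
})

test_that("feedback follows the thumbs/shrug rules", {
  tr <- example_display()
  over <- ref_expression(colour = "green", material = "metal", noun = "bat")
  expect_equal(feedback(tr, ref_expression(material = "metal", noun = "bat")),
               "thumbs_down")
  expect_equal(feedback(tr, over), "thumbs_up")   # overinforming on critical is fine
  expect_equal(feedback(tr, ref_expression(colour = "green", noun = "bat")),
               "thumbs_up")
  filler <- tr
  filler$is_filler <- TRUE
  expect_equal(feedback(filler, over), "shrug")
})

test_that("experiment-1 displays realise their discriminability structure", {
  cal <- fixture_calibration()
  set.seed(3)
  tr <- build_exp1_display("baseline", "colour", cal)
  t <- tr$target
  expect_true(tr$items$colour_step[t] %in% c(1L, 50L))          # high-disc target
  expect_true(all(tr$items$material_step == tr$items$material_step[1]))
  expect_false(any(tr$items$colour_lowdisc | tr$items$material_lowdisc))
  # sufficient attribute uniquely demarcates the target
  expect_equal(sum(tr$items$colour == tr$items$colour[t]), 1)

  tr2 <- build_exp1_display("s_low_r_high", "colour", cal)
  t2 <- tr2$target
  expect_true(tr2$items$colour_step[t2] %in% c(24L, 27L))       # boundary stimulus
  expect_true(tr2$items$colour_lowdisc[t2])
  expect_true(all(tr2$items$colour_step[-t2] %in% c(1L, 50L)))  # opposing high-disc
  expect_false(any(tr2$items$material_lowdisc))

  tr3 <- build_exp1_display("s_high_r_low", "material", cal)
  expect_true(all(tr3$items$colour_lowdisc))                    # shared redundant low
  expect_true(all(tr3$items$colour_step %in% c(24L, 27L)))

  f <- build_exp1_filler("colour", cal)
  expect_equal(sum(f$items$colour == f$items$colour[f$target]), 1)
  expect_true(all(f$items$material == f$items$material[1]))
  expect_true(f$is_filler)
  expect_equal(unname(f$timing), c(0.8, 1.0, 1.7))

  bad <- cal
  bad$colour$success <- FALSE
  expect_error(build_exp1_display("baseline", "colour", bad), "calibration")
})

test_that("experiment-1 sessions are balanced and randomised", {
  cal <- fixture_calibration()
  counts <- function(seed) {
    set.seed(seed)
    sess <- generate_exp1_session(cal)
    crit <- purrr::keep(sess, ~ !.x$is_filler)
    list(
      total = length(sess),
      critical = length(crit),
      cells = table(vapply(crit, `[[`, "", "display_type"),
                    vapply(crit, `[[`, "", "redundant_attribute")),
      order = vapply(sess, `[[`, "", "display_type")
    )
  }
  a <- counts(1); b <- counts(2)
  expect_equal(a$total, 60)
  expect_equal(a$critical, 48)
  expect_true(all(a$cells == 8))              # 3 display types x 2 attributes
  expect_equal(a$cells, b$cells)              # marginals are seed-invariant
  expect_false(identical(a$order, b$order))   # ordering is not
})

test_that("experiment-2 sessions cover the set-size by distractor grid", {
  set.seed(5)
  sess <- generate_exp2_session("colour_hf")
  expect_equal(length(sess), 48)
  crit <- purrr::keep(sess, ~ !.x$is_filler)
  expect_equal(length(crit), 34)
  grid <- table(vapply(crit, `[[`, 1L, "set_size"),
                vapply(crit, `[[`, 1L, "n_distractors"))
  expect_true(all(grid["3", c("0", "1")] == 2))
  expect_equal(sum(grid["3", ]), 4)                 # set size 3: only 0/1
  for (s in c("6", "9", "16")) expect_true(all(grid[s, ] == 2))
  for (tr in crit) {
    t <- tr$target
    expect_equal(sum(tr$items$shape == tr$items$shape[t]), 1)  # unique shape
    attr_vals <- tr$items[[tr$attribute]]
    expect_equal(sum(attr_vals[-t] == attr_vals[t]), tr$n_distractors)
    # the noun alone demarcates: adjectives are always redundant
    noun_only <- classify_expression(tr, ref_expression(noun = tr$items$shape[t]))
    expect_equal(noun_only$category, "minimal")
    full <- ref_expression(noun = tr$items$shape[t])
    full[[tr$attribute]] <- attr_vals[t]
    expect_equal(classify_expression(tr, full)$category, "overinformative")
  }
  for (tr in purrr::keep(sess, ~ .x$is_filler)) {
    t <- tr$target
    noun_only <- classify_expression(tr, ref_expression(noun = tr$items$shape[t]))
    expect_false(noun_only$identifiable)              # noun alone insufficient
    both <- ref_expression(noun = tr$items$shape[t])
    both[[tr$attribute]] <- tr$items[[tr$attribute]][t]
    expect_equal(classify_expression(tr, both)$category, "minimal")
  }
  # orientation condition carries orientation values
  sess_o <- generate_exp2_session("orientation")
  expect_true(all(purrr::map_lgl(sess_o, ~ "orientation" %in% names(.x$items))))
})

test_that("session tables flatten one row per item", {
  cal <- fixture_calibration()
  set.seed(9)
  sess <- generate_exp1_session(cal)
  tab <- session_table(sess)
  expect_equal(nrow(tab), 60 * 3)
  expect_equal(sum(tab$role == "target"), 60)
})
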