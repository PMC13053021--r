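test_that("response coding marks minimal, overinformative and mislabelled trials", {
  tr_min <- list(trial = example_display(),
                 expr = ref_expression(colour = "green", noun = "bat"))
  tr_over <- list(trial = example_display(),
                  expr = ref_expression(colour = "green", material = "metal",
                                        noun = "bat"))
  tr_under <- list(trial = example_display(),
                   expr = ref_expression(noun = "bat"))
  # a redundant-low display whose shared material stimulus sits at the
  # boundary: the speaker names it with the wrong category
  mis_tr <- example_display()
  mis_tr$display_type <- "s_high_r_low"
  mis_tr$items$material_lowdisc <- TRUE
  mis_tr$items$material_step <- 5L
  tr_mis <- list(trial = mis_tr,
                 expr = ref_expression(colour = "green", material = "wood",
                                       noun = "bat"))
  ds <- manual_dataset(list(list(tr_min, tr_over, tr_under, tr_mis)))
  coded <- code_responses(ds)
  expect_equal(coded$category,
               c("minimal", "overinformative", "underinformative", "overinformative"))
  expect_equal(coded$overinformative, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(coded$identifiable, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(coded$mislabelled_low_disc, c(FALSE, FALSE, FALSE, TRUE))
  # mislabelling a low-disc *sufficient* term whose remainder does not
  # demarcate leaves the trial non-identifiable
  suff_tr <- example_display()
  suff_tr$items$colour_lowdisc[1] <- TRUE
  ds2 <- manual_dataset(list(list(list(
    trial = suff_tr, expr = ref_expression(colour = "blue", noun = "bat")
  ))))
  c2 <- code_responses(ds2)
  expect_true(c2$mislabelled_low_disc)
  expect_false(c2$identifiable)
})

test_that("exclusions drop fatigued subjects strictly above the threshold", {
  make_records <- function(n_under) {
    tibble::tibble(
      subject = rep(seq_along(n_under), each = 60),
      trial = rep(1:60, length(n_under)),
      is_filler = FALSE,
      underinformative = unlist(lapply(n_under, function(k) {
        c(rep(TRUE, k), rep(FALSE, 60 - k))
      })),
      identifiable = !underinformative,
      overinformative = FALSE,
      mislabelled_low_disc = FALSE
    )
  }
  rec <- make_records(c(11, 10, 0))
  out <- apply_exclusions(rec)
  expect_equal(out$report$excluded_subjects, 1)       # 11 underinformative: out
  expect_true(2 %in% out$records$subject)             # 10: retained
  expect_equal(out$report$n_trials_dropped, 10)       # subject 2's bad trials
  expect_equal(out$report$n_kept, 50 + 60)
  # idempotence
  again <- apply_exclusions(out$records)
  expect_equal(again$records, out$records)
  expect_equal(again$report$n_subjects_excluded, 0)
})

test_that("injected fatigue subjects are caught by the exclusion rule", {
  ds <- simulate_experiment1(n_subjects = 5, n_fatigue = 2, seed = 31)
  coded <- code_responses(ds)
  out <- apply_exclusions(coded)
  expect_gte(out$report$n_subjects_excluded, 2)
})

test_that("dummy-coded fit reproduces analytic cell log-odds without random effects", {
  set.seed(88)
  n_per <- 4000
  cells <- c(a = -0.5, b = 0.6, c = -1.2)   # true cell log-odds
  df <- tibble::tibble(
    condition = rep(names(cells), each = n_per),
    subject = rep(1:60, length.out = 3 * n_per),
    overinformative = rbinom(3 * n_per, 1, plogis(cells[rep(names(cells), each = n_per)]))
  )
  spec <- model_spec("overinformative", "condition",
                     references = c(condition = "a"),
                     subject_intercepts = FALSE, chains = 2, iter = 2000)
  fit <- fit_bayes_logistic(df, spec, seed = 4)
  expect_equal(fit$estimate[fit$effect == "(Intercept)"], cells[["a"]],
               tolerance = 0.05 / abs(cells[["a"]]))
  expect_equal(fit$estimate[fit$effect == "conditionb"],
               cells[["b"]] - cells[["a"]], tolerance = 0.05)
  expect_equal(fit$estimate[fit$effect == "conditionc"],
               cells[["c"]] - cells[["a"]], tolerance = 0.08)
  expect_true(all(fit$rhat < 1.05))
  expect_true(all(fit$ci_lower <= fit$estimate & fit$estimate <= fit$ci_upper))
})

test_that("model fitting validates inputs and reports convergence failures", {
  df <- tibble::tibble(subject = 1:20, condition = rep(c("a", "b"), 10),
                       overinformative = 1L)
  spec <- model_spec("overinformative", "condition", subject_intercepts = FALSE)
  expect_error(fit_bayes_logistic(df, spec), "both response classes")
  spec_badref <- model_spec("overinformative", "condition",
                            references = c(condition = "zzz"))
  df$overinformative <- rep(0:1, 10)
  expect_error(fit_bayes_logistic(df, spec_badref), "reference level")
})

test_that("Bayes-factor comparison penalises a spurious interaction", {
  set.seed(12)
  n_per <- 800
  grid <- expand.grid(f1 = c("x", "y"), f2 = c("p", "q", "r"),
                      stringsAsFactors = FALSE)
  df <- grid[rep(seq_len(nrow(grid)), each = n_per), ]
  eta <- -1 + 0.8 * (df$f1 == "y") + 0.5 * (df$f2 == "q") - 0.4 * (df$f2 == "r")
  df$overinformative <- rbinom(nrow(df), 1, plogis(eta))
  df$subject <- rep(1:20, length.out = nrow(df))
  main <- model_spec("overinformative", c("f1", "f2"), subject_intercepts = FALSE)
  inter <- model_spec("overinformative", c("f1", "f2"), interaction = TRUE,
                      subject_intercepts = FALSE)
  expect_equal(compare_models(df, main, main)$bf, 1)
  expect_lt(compare_models(df, main, inter)$bf, 1)
  # a strong generative interaction flips the comparison
  eta2 <- eta + 2.5 * (df$f1 == "y") * (df$f2 == "q")
  df2 <- df
  df2$overinformative <- rbinom(nrow(df2), 1, plogis(eta2))
  expect_gt(compare_models(df2, main, inter)$bf, 1)
})

test_that("psychometric fits recover a known observer boundary", {
  set.seed(21)
  o <- simulated_observer(24, 2.5, 0.02)
  trials <- tibble::tibble(
    position = rep(seq(2, 48, by = 2), each = 12)
  )
  trials$toward_B <- runif(nrow(trials)) < observer_response_prob(o, trials$position)
  fit <- fit_psychometric(trials, bin_trials = 5, B = 300, seed = 2)
  expect_false(fit$pooled$degenerate)
  expect_lt(abs(fit$pooled$boundary - 24), 2)
  expect_true(fit$pooled$ci_lower <= fit$pooled$boundary &
                fit$pooled$boundary <= fit$pooled$ci_upper)
  expect_true(all(fit$points$n[-nrow(fit$points)] == 5))
  # reproducible under a fixed seed
  fit2 <- fit_psychometric(trials, bin_trials = 5, B = 300, seed = 2)
  expect_identical(fit$pooled, fit2$pooled)
  # perfectly separated responses: steep fit, boundary between the steps
  sep <- tibble::tibble(position = rep(c(10, 20), each = 30),
                        toward_B = rep(c(FALSE, TRUE), each = 30))
  fsep <- fit_psychometric(sep, B = 50, seed = 1)
  expect_gt(fsep$pooled$boundary, 10)
  expect_lt(fsep$pooled$boundary, 20)
  # degenerate constant responses flag and sit at the continuum edge
  flat <- tibble::tibble(position = rep(c(5, 10, 15), each = 10), toward_B = TRUE)
  fflat <- fit_psychometric(flat, B = 50, seed = 1)
  expect_true(fflat$pooled$degenerate)
  expect_equal(fflat$pooled$boundary, 5)
  expect_equal(fflat$pooled$ci_lower, fflat$pooled$ci_upper)
  expect_error(fit_psychometric(tibble::tibble(position = 1, toward_B = TRUE)),
               "distinct positions")
})

test_that("proportion summaries bootstrap over subjects", {
  set.seed(14)
  rec <- tibble::tibble(
    subject = rep(1:10, each = 20),
    cell = rep(c("u", "v"), 100)
  )
  rec$overinformative <- ifelse(rec$cell == "u", TRUE, rbinom(200, 1, 0.3) == 1)
  out <- summarise_proportions(rec, "cell", B = 200, seed = 3)
  u <- out[out$cell == "u", ]
  expect_equal(u$proportion, 1)
  expect_equal(u$ci_lower, 1)
  expect_equal(u$ci_upper, 1)
  v <- out[out$cell == "v", ]
  expect_lt(abs(v$proportion - 0.3), 0.15)
  out2 <- summarise_proportions(rec, "cell", B = 200, seed = 3)
  expect_identical(out, out2)
})
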