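#' Run configuration
#'
#' Builds a validated configuration for the pipeline entry points. All
#' randomness is controlled by the mandatory `seed`; per-stage seeds are
#' derived deterministically from it.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param seed Integer seed (mandatory).
#' @param n_subjects Experiment-1 recruited subjects (default 72).
#' @param n_per_condition Experiment-2 subjects per condition (default 20).
#' @param coefficients Generative speaker coefficients; defaults to
#'   [exp1_speaker_coefficients()] / [exp2_speaker_coefficients()].
#' @param sigma_u Subject-intercept SD (default 0.8).
#' @param underinform_rate Speaker noise rate (see the agents documentation).
#' @param n_fatigue Injected fatigue subjects (Experiment 1 only, default 0).
#' @param chains,iter MCMC settings forwarded to the model spec.
#' @return A list of class `run_config`.
#' @export
run_config <- function(experiment = c("exp1", "exp2"), seed,
                       n_subjects = 72, n_per_condition = 20,
                       coefficients = NULL, sigma_u = 0.8,
                       underinform_rate = 0.01, n_fatigue = 0,
                       chains = 4, iter = 2000) {
  experiment <- match.arg(experiment)
  if (missing(seed) || is.null(seed)) stop_invalid("seed is mandatory")
  if (is.null(coefficients)) {
    coefficients <- if (experiment == "exp1") exp1_speaker_coefficients()
                    else exp2_speaker_coefficients()
  }
  structure(list(
    experiment = experiment, seed = as.integer(seed),
    n_subjects = n_subjects, n_per_condition = n_per_condition,
    coefficients = coefficients, sigma_u = sigma_u,
    underinform_rate = underinform_rate, n_fatigue = n_fatigue,
    chains = chains, iter = iter
  ), class = "run_config")
}

#' Read a run configuration from a YAML or JSON file
#'
#' Unknown fields raise a validation error naming the field; missing
#' mandatory fields likewise.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_invalid("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$coefficients)) raw$coefficients <- unlist(raw$coefficients)
  do.call(run_config, raw)
}

write_manifest <- function(out_dir, config, extra = list()) {
  manifest <- c(
    list(seed = config$seed, experiment = config$experiment,
         config_hash = config_hash(unclass(config)),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Render the stimulus continua to disk
#'
#' Writes the colour continua (50 steps each) as a CSV manifest with sRGB hex
#' strings, and the two material sound continua (10 steps each) as
#' volume-normalised 16-bit WAV files. Deterministic given the configuration.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the colour manifest and WAV paths.
#' @export
run_stimuli <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ep <- default_colour_endpoints()
  continua <- list(
    blue_green = interpolate_lab(ep$cool$A, ep$cool$B, 50,
                                 ep$cool$label_A, ep$cool$label_B),
    yellow_orange = interpolate_lab(ep$warm$A, ep$warm$B, 50,
                                    ep$warm$label_A, ep$warm$label_B)
  )
  manifest <- write_colour_manifest(continua, file.path(out_dir, "colours.csv"))
  mats <- default_materials()
  pairs <- list(
    wood_glass = interpolate_modal(mats$wood, mats$glass, 10),
    cardboard_metal = interpolate_modal(mats$cardboard, mats$metal, 10)
  )
  wav_paths <- character()
  for (nm in names(pairs)) {
    sc <- pairs[[nm]]
    for (s in seq_len(sc$n_steps)) {
      w <- normalise_volume(synthesize_impact(sc$steps[[s]]))
      p <- file.path(out_dir, sprintf("%s_step%02d.wav", nm, s))
      write_wav(w, p)
      wav_paths <- c(wav_paths, p)
    }
  }
  write_manifest(out_dir, config,
                 list(n_colour_steps = 50, n_sound_steps = 10,
                      files = c("colours.csv", basename(wav_paths))))
  invisible(list(colours = manifest, wavs = wav_paths))
}

#' Simulate a full synthetic experiment and write it to disk
#'
#' Runs the configured experiment simulation, writing the response table, the
#' per-item trial tables, and (for Experiment 1) per-subject staircase logs.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return The `response_dataset`, invisibly.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- if (config$experiment == "exp1") {
    simulate_experiment1(
      n_subjects = config$n_subjects, coefficients = config$coefficients,
      sigma_u = config$sigma_u, underinform_rate = config$underinform_rate,
      n_fatigue = config$n_fatigue, seed = child_seed(config$seed, "simulate")
    )
  } else {
    simulate_experiment2(
      n_per_condition = config$n_per_condition,
      coefficients = config$coefficients, sigma_u = config$sigma_u,
      seed = child_seed(config$seed, "simulate")
    )
  }
  write.csv(ds$responses, file.path(out_dir, "responses.csv"), row.names = FALSE)
  items <- dplyr::bind_rows(purrr::imap(ds$trials, function(session, j) {
    if (is.null(session)) return(NULL)
    tab <- session_table(session)
    tab$subject <- j
    tab
  }))
  write.csv(items, file.path(out_dir, "trial_items.csv"), row.names = FALSE)
  if (config$experiment == "exp1") {
    logs <- dplyr::bind_rows(purrr::imap(ds$calibrations, function(cal, j) {
      dplyr::bind_rows(
        dplyr::mutate(cal$colour$log, subject = j, attribute = "colour"),
        dplyr::mutate(cal$material$log, subject = j, attribute = "material")
      )
    }))
    write.csv(logs, file.path(out_dir, "staircase_log.csv"), row.names = FALSE)
    cal_manifest <- purrr::imap(ds$calibrations, function(cal, j) {
      list(subject = j,
           colour = cal$colour[c("high_disc_A", "high_disc_B",
                                 "low_disc_A", "low_disc_B", "success")],
           material = cal$material[c("high_disc_A", "high_disc_B",
                                     "low_disc_A", "low_disc_B", "success")])
    })
    jsonlite::write_json(cal_manifest, file.path(out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_manifest(out_dir, config,
                 list(n_responses = nrow(ds$responses),
                      n_calibration_failures = length(ds$excluded_calibration)))
  invisible(ds)
}

#' Analyse a response dataset
#'
#' Codes responses, applies the exclusion rules, fits the experiment's
#' Bayesian mixed-effects logistic model on critical trials, and writes the
#' coefficient table and exclusion report.
#'
#' @param dataset A `response_dataset`.
#' @param config A `run_config` (supplies seeds and sampler settings).
#' @param out_dir Optional output directory for the CSV/JSON reports.
#' @return A list: `coded`, `kept`, `report`, `fit` (a `posterior_summary`).
#' @export
run_analysis <- function(dataset, config, out_dir = NULL) {
  coded <- code_responses(dataset)
  excl <- apply_exclusions(coded)
  critical <- excl$records[!excl$records$is_filler, ]
  spec <- if (dataset$experiment == "exp1") {
    exp1_model_spec(chains = config$chains, iter = config$iter)
  } else {
    exp2_model_spec(chains = config$chains, iter = config$iter)
  }
  fit <- fit_bayes_logistic(critical, spec, seed = child_seed(config$seed, "mcmc"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(fit), file.path(out_dir, "coefficients.csv"),
              row.names = FALSE)
    jsonlite::write_json(excl$report, file.path(out_dir, "exclusions.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(coded = coded, kept = excl$records, report = excl$report, fit = fit)
}

#' Parameter-recovery harness
#'
#' Simulates the configured experiment with known generative coefficients,
#' analyses it, and reports each coefficient's posterior mean against its
#' generating value, over one or more seeds.
#'
#' @param config A `run_config`.
#' @param seeds Integer vector of seeds (default: the config seed).
#' @return A tibble with columns `seed`, `effect`, `truth`, `estimate`,
#'   `error` (estimate minus truth), plus interval bounds.
#' @export
run_recovery <- function(config, seeds = config$seed) {
  rows <- purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    ds <- if (cfg$experiment == "exp1") {
      simulate_experiment1(
        n_subjects = cfg$n_subjects, coefficients = cfg$coefficients,
        sigma_u = cfg$sigma_u, underinform_rate = cfg$underinform_rate,
        seed = child_seed(cfg$seed, "simulate")
      )
    } else {
      simulate_experiment2(
        n_per_condition = cfg$n_per_condition, coefficients = cfg$coefficients,
        sigma_u = cfg$sigma_u, seed = child_seed(cfg$seed, "simulate")
      )
    }
    res <- run_analysis(ds, cfg)
    fit <- res$fit
    truth <- unname(cfg$coefficients)
    k <- length(truth)
    tibble::tibble(
      seed = s, effect = fit$effect[seq_len(k)], truth = truth,
      estimate = fit$estimate[seq_len(k)],
      error = fit$estimate[seq_len(k)] - truth,
      ci_lower = fit$ci_lower[seq_len(k)], ci_upper = fit$ci_upper[seq_len(k)]
    )
  })
  dplyr::bind_rows(rows)
}
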