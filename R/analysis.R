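#' Code director-task responses
#'
#' Classifies every response against its trial display. Attribute terms that
#' mislabel a low-discriminability (boundary) stimulus are flagged and set
#' aside: the trial counts as identifiable when the remainder of the
#' expression still demarcates the target (such responses are necessarily
#' overinformative, since the remainder already suffices). Mislabelling is an
#' inevitable aspect of low discriminability and is therefore not treated as
#' an error. All other non-demarcating expressions are coded
#' underinformative.
#'
#' @param dataset A `response_dataset` from [simulate_experiment1()] or
#'   [simulate_experiment2()].
#' @return A tibble of coded records: one row per trial with metadata,
#'   `overinformative`, `identifiable`, `underinformative`,
#'   `mislabelled_low_disc` and `category`.
#' @export
code_responses <- function(dataset) {
  stopifnot(inherits(dataset, "response_dataset"))
  rows <- dataset$responses
  slots <- intersect(c("colour_term", "material_term", "orientation_term"), names(rows))
  out <- vector("list", nrow(rows))
  for (r in seq_len(nrow(rows))) {
    row <- rows[r, ]
    tr <- dataset$trials[[row$subject]][[row$trial]]
    terms <- list()
    for (s in slots) {
      if (!is.na(row[[s]])) terms[[sub("_term$", "", s)]] <- row[[s]]
    }
    noun <- if (!is.na(row$noun)) row$noun else NULL

    # split off terms that mislabel a low-discriminability stimulus
    mislabelled <- character()
    kept <- terms
    for (attr in names(terms)) {
      low_col <- paste0(attr, "_lowdisc")
      if (!low_col %in% names(tr$items)) next
      i <- tr$target
      if (isTRUE(tr$items[[low_col]][i]) && terms[[attr]] != tr$items[[attr]][i]) {
        mislabelled <- c(mislabelled, attr)
        kept[[attr]] <- NULL
      }
    }

    args <- kept
    args$noun <- noun
    cls <- if (length(args) == 0) {
      list(category = "underinformative", identifiable = FALSE)
    } else {
      classify_expression(tr, do.call(ref_expression, args))
    }
    overinf <- cls$category == "overinformative"
    # a retained mislabelled term means the speaker said more than the
    # (already demarcating) remainder: overinformative by definition
    if (length(mislabelled) > 0 && cls$identifiable) overinf <- TRUE
    category <- if (!cls$identifiable) "underinformative"
                else if (overinf) "overinformative" else "minimal"

    meta <- row[setdiff(names(row), c(slots, "noun"))]
    out[[r]] <- tibble::as_tibble(c(meta, list(
      overinformative = overinf,
      identifiable = cls$identifiable,
      underinformative = !cls$identifiable,
      mislabelled_low_disc = length(mislabelled) > 0,
      category = category
    )))
  }
  dplyr::bind_rows(out)
}

#' Apply the exclusion rules
#'
#' Subjects with more than `threshold` underinformative director-task trials
#' (critical and filler alike) are dropped entirely; remaining
#' non-identifiable trials are dropped individually; identifiable trials with
#' mislabelled low-discriminability attributes are retained. Applying the
#' exclusions twice equals applying them once.
#'
#' @param records Coded records from [code_responses()].
#' @param threshold Strict underinformativeness threshold (default 10: a
#'   subject with 11 such trials is excluded, one with 10 is retained).
#' @return A list: `records` (kept rows) and `report` (counts per reason,
#'   excluded subject ids, retained mislabelled-trial count).
#' @export
apply_exclusions <- function(records, threshold = 10) {
  per_subj <- dplyr::summarise(
    dplyr::group_by(records, .data$subject),
    n_underinformative = sum(.data$underinformative), .groups = "drop"
  )
  bad_subjects <- per_subj$subject[per_subj$n_underinformative > threshold]
  kept <- records[!records$subject %in% bad_subjects, ]
  n_trials_dropped <- sum(!kept$identifiable)
  kept <- kept[kept$identifiable, ]
  report <- list(
    excluded_subjects = bad_subjects,
    n_subjects_excluded = length(bad_subjects),
    n_trials_dropped = n_trials_dropped,
    n_mislabelled_retained = sum(kept$mislabelled_low_disc),
    n_kept = nrow(kept),
    threshold = threshold
  )
  list(records = kept, report = report)
}

#' Specification of a Bayesian logistic model
#'
#' @param response Name of the logical/0-1 response column.
#' @param effects Character vector of categorical predictor columns.
#' @param references Named character vector of reference levels (dummy coding).
#' @param contrasts `"dummy"` (treatment) or `"sum"`.
#' @param interaction Include the full interaction between the effects?
#' @param subject_intercepts Include by-subject random intercepts?
#' @param prior_sd SD of the Normal(0, .) prior on coefficients (default 2).
#' @param group_sd_prior_sd Scale of the half-Normal prior on the
#'   subject-intercept SD (default 1).
#' @param chains,iter MCMC chains (4) and iterations per chain (2000, half
#'   of which is warm-up).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(response, effects, references = NULL,
                       contrasts = c("dummy", "sum"), interaction = FALSE,
                       subject_intercepts = TRUE, prior_sd = 2,
                       group_sd_prior_sd = 1, chains = 4, iter = 2000) {
  contrasts <- match.arg(contrasts)
  structure(list(
    response = response, effects = effects, references = references,
    contrasts = contrasts, interaction = interaction,
    subject_intercepts = subject_intercepts, prior_sd = prior_sd,
    group_sd_prior_sd = group_sd_prior_sd, chains = chains, iter = iter
  ), class = "model_spec")
}

#' @rdname model_spec
#' @export
exp1_model_spec <- function(interaction = FALSE, ...) {
  model_spec(
    response = "overinformative",
    effects = c("redundant_attribute", "display_type"),
    references = c(redundant_attribute = "colour", display_type = "s_low_r_high"),
    interaction = interaction, ...
  )
}

#' @rdname model_spec
#' @export
exp2_model_spec <- function(...) {
  model_spec(
    response = "overinformative",
    effects = "condition",
    references = c(condition = "colour_hf"),
    ...
  )
}

# design matrix + response + subject index from coded records and a spec
build_model_data <- function(records, spec) {
  df <- as.data.frame(records)
  y <- as.integer(df[[spec$response]])
  if (length(unique(y)) < 2) stop_invalid("need both response classes present")
  for (e in spec$effects) {
    f <- factor(df[[e]])
    ref <- spec$references[[e]]
    if (!is.null(ref) && !is.na(ref)) {
      if (!ref %in% levels(f)) stop_invalid("reference level '", ref,
                                            "' not present in ", e)
      f <- stats::relevel(f, ref)
    }
    if (spec$contrasts == "sum") stats::contrasts(f) <- stats::contr.sum(nlevels(f))
    # dummy coding is the factor default (treatment contrasts) after relevel
    df[[e]] <- f
  }
  op <- if (spec$interaction) " * " else " + "
  fml <- stats::as.formula(paste("~", paste(spec$effects, collapse = op)))
  X <- model.matrix(fml, df)
  subj <- as.integer(factor(df$subject))
  list(y = y, X = X, subj = subj, J = max(subj))
}

jags_model_re <- "
model {
  eta <- X %*% beta
  for (i in 1:N) { y[i] ~ dbern(ilogit(eta[i] + u[subj[i]])) }
  for (k in 1:K) { beta[k] ~ dnorm(0, beta_prec) }
  for (j in 1:J) { u[j] ~ dnorm(0, tau_u) }
  sigma_u ~ dnorm(0, sigma_prec) T(0,)
  tau_u <- pow(sigma_u, -2)
}"

# hierarchically centered variant for fully between-subject designs (the
# design matrix is constant within subject): the subject effect is centered
# on the subject-level linear predictor, which mixes far better than the
# sum parameterisation when fixed effects are subject-constant
jags_model_centered <- "
model {
  mu <- Xs %*% beta
  for (i in 1:N) { y[i] ~ dbern(ilogit(a[subj[i]])) }
  for (j in 1:J) { a[j] ~ dnorm(mu[j], tau_u) }
  for (k in 1:K) { beta[k] ~ dnorm(0, beta_prec) }
  sigma_u ~ dnorm(0, sigma_prec) T(0,)
  tau_u <- pow(sigma_u, -2)
}"

jags_model_fixed <- "
model {
  eta <- X %*% beta
  for (i in 1:N) { y[i] ~ dbern(ilogit(eta[i])) }
  for (k in 1:K) { beta[k] ~ dnorm(0, beta_prec) }
}"

#' Fit a Bayesian (mixed-effects) logistic regression
#'
#' Posterior sampling by MCMC (JAGS) with Normal(0, `prior_sd`) priors on all
#' coefficients, optional by-subject random intercepts with a half-Normal
#' prior on their SD, and Gelman--Rubin convergence checks. The fit fails
#' loudly if any R-hat exceeds 1.05.
#'
#' @param records Coded (and typically exclusion-filtered, critical-only)
#'   records with a `subject` column.
#' @param spec A [model_spec()].
#' @param seed Integer seed for the MCMC chains.
#' @return A tibble of class `posterior_summary`: per effect the posterior
#'   mean (`estimate`), posterior SD (`se`), central 95% credible interval
#'   (`ci_lower`, `ci_upper`) and `rhat`. The coda samples are attached as
#'   attribute `"samples"`.
#' @export
fit_bayes_logistic <- function(records, spec, seed = 1) {
  md <- build_model_data(records, spec)
  K <- ncol(md$X)
  data <- list(
    y = md$y, X = md$X, N = length(md$y), K = K,
    beta_prec = 1 / spec$prior_sd^2
  )
  monitor <- "beta"
  model_str <- jags_model_fixed
  if (spec$subject_intercepts) {
    data$subj <- md$subj
    data$J <- md$J
    data$sigma_prec <- 1 / spec$group_sd_prior_sd^2
    monitor <- c("beta", "sigma_u")
    first <- match(seq_len(md$J), md$subj)
    between_subject <- all(vapply(seq_len(K), function(k) {
      all(md$X[, k] == md$X[first, k][md$subj])
    }, logical(1)))
    if (between_subject) {
      model_str <- jags_model_centered
      data$Xs <- md$X[first, , drop = FALSE]
      data$X <- NULL
    } else {
      model_str <- jags_model_re
    }
  }
  inits <- lapply(seq_len(spec$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed(seed, paste0("chain", i)))
  })
  warmup <- floor(spec$iter / 2)
  adapt <- min(500L, floor(warmup / 2))
  jm <- rjags::jags.model(textConnection(model_str), data = data,
                          inits = inits, n.chains = spec$chains,
                          n.adapt = adapt, quiet = TRUE)
  stats::update(jm, warmup - adapt, progress.bar = "none")
  samples <- rjags::coda.samples(jm, monitor, n.iter = spec$iter - warmup,
                                 progress.bar = "none")
  st <- summary(samples)
  means <- st$statistics[, "Mean"]
  sds <- st$statistics[, "SD"]
  qs <- st$quantiles
  rhat <- coda::gelman.diag(samples, multivariate = FALSE, autoburnin = FALSE)$psrf[, 1]
  labels <- c(colnames(md$X), if (spec$subject_intercepts) "sigma_u")
  idx <- c(paste0("beta[", seq_len(K), "]"), if (spec$subject_intercepts) "sigma_u")
  if (K == 1) idx[1] <- "beta"
  out <- tibble::tibble(
    effect = labels,
    estimate = unname(means[idx]), se = unname(sds[idx]),
    ci_lower = unname(qs[idx, "2.5%"]), ci_upper = unname(qs[idx, "97.5%"]),
    rhat = unname(rhat[idx])
  )
  bad <- out$rhat > 1.05
  if (any(bad, na.rm = TRUE)) {
    stop_invalid(
      "MCMC did not converge; R-hat > 1.05 for: ",
      paste(sprintf("%s (%.3f)", out$effect[bad], out$rhat[bad]), collapse = ", ")
    )
  }
  structure(out, class = c("posterior_summary", class(out)),
            samples = samples, spec = spec)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Bayesian logistic regression posterior summary\n")
  NextMethod()
  invisible(x)
}

# joint log posterior (and gradient) for the Laplace approximation;
# theta = (beta, u, log sigma_u) when random effects are present
laplace_logpost <- function(md, spec) {
  K <- ncol(md$X)
  re <- spec$subject_intercepts
  J <- if (re) md$J else 0L
  s_beta <- spec$prior_sd
  s_tau <- spec$group_sd_prior_sd
  fn <- function(theta) {
    beta <- theta[seq_len(K)]
    eta <- as.numeric(md$X %*% beta)
    lp <- sum(stats::dnorm(beta, 0, s_beta, log = TRUE))
    if (re) {
      u <- theta[K + seq_len(J)]
      ls <- theta[K + J + 1]
      sig <- exp(ls)
      eta <- eta + u[md$subj]
      lp <- lp + sum(stats::dnorm(u, 0, sig, log = TRUE)) +
        log(2) + stats::dnorm(sig, 0, s_tau, log = TRUE) + ls
    }
    p <- plogis(eta)
    lp + sum(ifelse(md$y == 1, log(p), log1p(-p)))
  }
  gr <- function(theta) {
    beta <- theta[seq_len(K)]
    eta <- as.numeric(md$X %*% beta)
    if (re) {
      u <- theta[K + seq_len(J)]
      ls <- theta[K + J + 1]
      sig <- exp(ls)
      eta <- eta + u[md$subj]
    }
    resid <- md$y - plogis(eta)
    g_beta <- as.numeric(crossprod(md$X, resid)) - beta / s_beta^2
    if (!re) return(g_beta)
    g_u <- tapply(resid, md$subj, sum)[as.character(seq_len(J))]
    g_u[is.na(g_u)] <- 0
    g_u <- as.numeric(g_u) - u / sig^2
    g_ls <- sum(u^2 / sig^2 - 1) - sig^2 / s_tau^2 + 1
    c(g_beta, g_u, g_ls)
  }
  list(fn = fn, gr = gr, d = K + J + re)
}

laplace_logml <- function(records, spec) {
  md <- build_model_data(records, spec)
  lpf <- laplace_logpost(md, spec)
  start_beta <- tryCatch(
    coef(glm(md$y ~ md$X - 1, family = binomial())),
    warning = function(w) suppressWarnings(coef(glm(md$y ~ md$X - 1, family = binomial())))
  )
  start_beta[!is.finite(start_beta)] <- 0
  start <- c(start_beta,
             if (spec$subject_intercepts) c(rep(0, md$J), log(0.5)))
  opt <- optim(start, lpf$fn, lpf$gr, method = "BFGS", hessian = TRUE,
               control = list(fnscale = -1, maxit = 1000))
  if (opt$convergence != 0) stop_invalid("posterior mode finding failed")
  ld <- determinant(-opt$hessian, logarithm = TRUE)
  if (ld$sign <= 0) stop_invalid("Hessian not negative definite at the mode")
  opt$value + lpf$d / 2 * log(2 * pi) - 0.5 * as.numeric(ld$modulus)
}

#' Compare two model specifications by Bayes factor
#'
#' Marginal likelihoods are approximated by a Laplace approximation at the
#' joint posterior mode (coefficients, random intercepts and log group SD).
#' The returned Bayes factor is `p(y | spec2) / p(y | spec1)`; a value below 1
#' means the second model (conventionally the interaction model) is inferior.
#' The approximation is documented as approximate; it is suitable for
#' comparing nested logistic specifications at these sample sizes.
#'
#' @param records Coded records (identical data for both fits).
#' @param spec1,spec2 Two [model_spec()]s.
#' @return A list: `bf`, `log_ml1`, `log_ml2`.
#' @export
compare_models <- function(records, spec1, spec2) {
  ml1 <- laplace_logml(records, spec1)
  ml2 <- laplace_logml(records, spec2)
  list(bf = exp(ml2 - ml1), log_ml1 = ml1, log_ml2 = ml2)
}

#' Fit psychometric functions to categorisation trials
#'
#' Maximum-likelihood logistic fit of the probability of the far-end category
#' label against continuum position, pooled and (when a `subject` column is
#' present) per subject, with percentile-bootstrap confidence intervals for
#' the pooled boundary and for binned response proportions (five trials per
#' bin by default, as appropriate for long colour continua).
#'
#' @param trials A tibble with `position`, logical `toward_B`, and optionally
#'   `subject` (e.g. from [staircase_trials()]).
#' @param bin_trials Trials per display bin (default 5).
#' @param B Bootstrap resamples (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return A list of class `psychometric_fit`: `pooled` (one-row tibble with
#'   `boundary`, `scale`, `degenerate`, `ci_lower`, `ci_upper`),
#'   `by_subject`, and `points` (binned proportions with bootstrap CIs).
#' @export
fit_psychometric <- function(trials, bin_trials = 5, B = 1000, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (length(unique(trials$position)) < 2) {
    stop_invalid("need at least 2 distinct positions")
  }
  fit_one <- function(df) {
    if (all(df$toward_B) || all(!df$toward_B)) {
      edge <- if (all(df$toward_B)) min(df$position) else max(df$position)
      return(tibble::tibble(boundary = edge, scale = NA_real_, degenerate = TRUE))
    }
    cf <- suppressWarnings(coef(glm(toward_B ~ position, binomial(), data = df)))
    tibble::tibble(boundary = -cf[[1]] / cf[[2]], scale = 1 / cf[[2]],
                   degenerate = FALSE)
  }
  pooled <- fit_one(trials)
  boot_b <- replicate(B, {
    fit_one(trials[sample.int(nrow(trials), replace = TRUE), ])$boundary
  })
  pooled$ci_lower <- unname(quantile(boot_b, 0.025, na.rm = TRUE))
  pooled$ci_upper <- unname(quantile(boot_b, 0.975, na.rm = TRUE))

  by_subject <- NULL
  if ("subject" %in% names(trials)) {
    by_subject <- dplyr::group_modify(
      dplyr::group_by(trials, .data$subject),
      function(df, key) fit_one(df)
    )
    by_subject <- dplyr::ungroup(by_subject)
  }

  ord <- trials[order(trials$position), ]
  ord$bin <- ceiling(seq_len(nrow(ord)) / bin_trials)
  points <- dplyr::group_modify(
    dplyr::group_by(ord, .data$bin),
    function(df, key) {
      props <- replicate(B, mean(df$toward_B[sample.int(nrow(df), replace = TRUE)]))
      tibble::tibble(
        position = mean(df$position), n = nrow(df),
        proportion = mean(df$toward_B),
        ci_lower = unname(quantile(props, 0.025)),
        ci_upper = unname(quantile(props, 0.975))
      )
    }
  )
  structure(list(pooled = pooled, by_subject = by_subject,
                 points = dplyr::ungroup(points)),
            class = "psychometric_fit")
}

#' Per-cell proportions with bootstrapped confidence intervals
#'
#' Computes subject-level means within each cell of `grouping`, then the grand
#' mean over subjects and a percentile bootstrap interval obtained by
#' resampling subjects (B = 1000 by default). Empty cells are simply absent
#' from the output.
#'
#' @param records Coded records.
#' @param grouping Character vector of grouping columns (e.g.
#'   `c("display_type", "redundant_attribute")`).
#' @param value Response column to average (default `"overinformative"`).
#' @param B Bootstrap resamples.
#' @param seed Optional seed for reproducible intervals.
#' @return A tibble: grouping columns, `n_subjects`, `proportion`,
#'   `ci_lower`, `ci_upper`.
#' @export
summarise_proportions <- function(records, grouping,
                                  value = "overinformative",
                                  B = 1000, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  subj_means <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(c("subject", grouping)))),
    m = mean(.data[[value]]), .groups = "drop"
  )
  dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(subj_means, dplyr::across(dplyr::all_of(grouping))),
    function(df, key) {
      boots <- replicate(B, mean(df$m[sample.int(nrow(df), replace = TRUE)]))
      tibble::tibble(
        n_subjects = nrow(df), proportion = mean(df$m),
        ci_lower = unname(quantile(boots, 0.025)),
        ci_upper = unname(quantile(boots, 0.975))
      )
    }
  ))
}
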