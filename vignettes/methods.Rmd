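---
title: "Simulating calibrated reference-production experiments: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating calibrated reference-production experiments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(refprodsim)
```

## What this package models

Speakers referring to objects frequently *overinform*: they mention more
attributes than are needed to single out the referent ("the blue cup" when
only one cup is present). One influential account holds that redundancy is
communicatively efficient when it helps the listener's perceptual search for
the referent. Testing that account requires director-task experiments in
which the perceptual discriminability of attributes (colour seen on screen,
material heard as an impact sound) is controlled per participant via
psychophysical calibration, and in which the resulting binary
overinform/minimal choices are analysed with Bayesian mixed-effects logistic
regression.

`refprodsim` implements that entire apparatus as testable code, replacing
human participants with simulated observers and speakers whose generative
structure matches what the analysis assumes. Every stage — stimulus
construction, adaptive calibration, trial generation, response production,
coding, exclusion, model fitting — can therefore be exercised end to end,
and the analysis pipeline can be validated by parameter recovery: simulate
with known coefficients, fit, and check that the posterior concentrates near
the truth.

## Stimulus continua

**Colour.** Continua are linear interpolations in CIELAB space, which is
approximately perceptually uniform, so equally spaced coordinate steps give
an approximately perceptually smooth gradient. The packaged endpoints are a
cool pair (blue (73.03, −19.98, 37.84) to green (87.24, −62.94, 41.00)) and
a warm pair (yellow (88.29, −0.98, 69.51) to orange (68.55, 40.91, 49.37)),
each rendered at 50 steps; a lightness-equalised, perceptually proximate
blue/green pair (L fixed at 73) serves the second experiment. Rendering to
sRGB uses the standard D65 transform with piecewise gamma; out-of-gamut
channels are clipped with a warning rather than an error, because everything
downstream of rendering depends only on step indices.

**Material.** Impact sounds are banks of resonant modes, each mode a triple
(amplitude, centre frequency, decay rate), rendered for 1 s as additive
exponentially damped sinusoids
$x(t) = \sum_i a_i e^{-d_i t} \sin(2\pi f_i t)$.
This is the minimal synthesis model consistent with those named parameters;
richer generative acoustics (nonlinear attack transients, noise floors,
inharmonic coupling) are out of scope. Continua interpolate paired modes
affinely over 10 steps, pairing modes in ascending-frequency order — a
deterministic choice that preserves spectral ordering. The shipped material
parameter sets (wood, glass, cardboard, metal; 10 modes each) are synthetic
placeholders shaped to give plausible bright/damped spectra; every
interpolation and synthesis contract holds for arbitrary parameter values,
so no test depends on them. "Volume normalisation" is implemented as RMS
equalisation (a `method = "peak"` option exists); psychoacoustic loudness
models are deliberately not used.

## Adaptive dual staircases

Each attribute is calibrated with two interleaved staircases starting from
opposite ends of the continuum, strictly alternating trials; when one
terminates, remaining trials go to the other. A response is "correct" when
it matches the staircase's own starting category. Two consecutive correct
identifications trigger a progression; an incorrect identification (a
*reversal*) triggers a regression. The material staircase moves one step in
both directions. The colour staircase uses accelerated schedules indexed by
the running count of incorrect identifications: progressions of 5, 4, 2,
then 1 step, and regressions of 4, 3, 2, then 1, both flooring at 1. The
progression sequence is implemented verbatim (5, 4, 2, 1), preserving the
apparent skip of 3 in its source description rather than "correcting" it.
After five reversals the staircase asks for one more correct identification
(confirming the participant will still categorise the boundary stimulus) and
terminates. If the confirmation response is incorrect, the staircase
regresses and asks again; the reversal counter saturates at five so the
invariant `n_reversals <= 5` holds throughout.

Two operationalisations of "reversal" were possible (any incorrect
identification, or a label switch relative to the previous trial); the first
is implemented, matching the definition under which the schedules are
stated. The *low-discriminability* stimulus is the stimulus of the final
correct identification. A *high-discriminability* stimulus must have been
correctly identified at step ≤ 2 before any reversal; a staircase that never
produces one marks the whole attribute calibration as failed, and failed
participants are dropped before the director task, mirroring the exclusion
structure of a real calibration phase. Both staircases' low-discriminability
estimates are retained separately (the design consumes the one matching the
target's category) rather than averaged, since averaging would discard the
category asymmetry the confirmation rule is designed to respect. A cap of
500 trials per dual run guarantees halting for pathological responders and
is reported as a calibration failure, never an error.

## Trial generation

**Experiment 1 (bat factory).** Three bats fall sequentially (800 ms fall,
1 s impact sound, 1.7 s dwell); the sufficient attribute uniquely demarcates
the target while the redundant attribute is shared by all three items.
Display types set the discriminability levels: Baseline (sufficient high,
redundant high), S-High/R-Low, and S-Low/R-High. Low-discriminability
stimuli are placed on the *target* for sufficient-low displays (the speaker
must label the boundary stimulus to name the target) and shared by all items
for redundant-low displays. The session comprises 48 critical trials plus 12
fillers (target differs in exactly one attribute). The source design states
both "48 critical (24 colour-redundant, 24 material-redundant)" and a
12/12/12 split over display types; the two cannot both hold, and the 48 and
24/24 figures are stated twice (trial counts and exclusion arithmetic), so
the generator honours them with 16 trials per display type (8 per
display-type × redundant-attribute cell).

**Experiment 2 (shape arrays).** Displays of 3, 6, 9 or 16 shapes (circle,
square, pentagon, hexagon) varying in one attribute per condition:
orientation (horizontal/vertical), high-frequency colour terms (green/blue),
or low-frequency terms (teal/jade) over the same proximate colour pair. In
critical trials the target's shape is unique (the noun alone demarcates it)
and exactly `n_distractors` (0–4; 0–1 at set size 3) non-targets share its
attribute value; every combination appears exactly twice (34 critical
trials). Fourteen fillers share the target's shape with a distractor while
its attribute value is unique, forcing adjective + noun. Distractor shapes
may repeat (unavoidable for set sizes above 4 with three non-target shapes).
Expressions lacking a noun are rejected by construction, mirroring the
button-press interface's noun requirement.

**Expression semantics.** An expression denotes the items matching every
mentioned term; it is identifiable iff that set is exactly the target,
overinformative iff some proper subset of its *attribute* terms (the noun,
being grammatically obligatory, is always retained) still identifies, and
minimal otherwise. The test suite checks this classifier against a
brute-force subset enumeration on a thousand generated displays. Feedback
follows the task's rules: thumbs-down for non-demarcating expressions,
thumbs-up otherwise, and a shrug for overinforming on filler trials.

## Simulated agents

**Observers** categorise with a lapse-logistic psychometric function:
$P(\text{far label}) = \gamma/2 + (1-\gamma)\,\mathrm{logit}^{-1}((x-b)/\sigma)$.
Defaults: boundary $b$ drawn uniformly from the middle third of the
continuum (a participant whose boundary sits at an extreme would not be
calibratable, matching the task's exclusion logic), lapse $\gamma = 0.02$,
scale $\sigma = 2.5$ steps (colour, of 50) and $0.8$ steps (material, of
10), chosen once so that aggregate categorisation curves show a smooth
sigmoidal transition over a plausible fraction of the continuum.

**Speakers** first produce a non-demarcating response with a small
probability (default 0.01; a bare noun in Experiment 1, a mislabelled noun
at rate 0.015 in Experiment 2 — placeholder rates whose only role is to
exercise the exclusion machinery), otherwise produce the minimal sufficient
expression and upgrade it to the overinformative one with probability
$\mathrm{logit}^{-1}(x'\beta + u_j)$, where $x$ is the trial's dummy coding
and $u_j \sim N(0, \sigma_u)$ a by-subject intercept. The default
$\sigma_u = 0.8$ yields between-subject heterogeneity comparable to the
spread of subject means in published director-task data without producing
degenerate cells. Default coefficients are, for Experiment 1 (reference:
colour-redundant, S-Low/R-High): intercept −2.50, material-redundant −1.43,
baseline −0.94, S-High/R-Low −1.09; for Experiment 2 (reference:
high-frequency colour): intercept 0.97, low-frequency colour −0.20,
orientation −0.97. Attribute terms that refer to a low-discriminability
(boundary) stimulus are mislabelled with the probability the attached
observer assigns to the wrong category at that stimulus position — deriving
speech errors from the same psychometric model that drove calibration,
rather than from a free parameter. Nouns are never mislabelled by this
mechanism. Optional "fatigue" subjects (off by default) answer with a bare
noun from a random early trial onward, to exercise the
underinformativeness exclusion.

## Coding, exclusion and analysis

Coding recomputes everything from the expressions; nothing is carried over
from the generator's internal decisions. A mislabelled low-discriminability
attribute term is flagged and set aside: the trial counts as identifiable
when the remainder of the expression still demarcates the target (in which
case the response is necessarily overinformative), and is otherwise dropped
as non-identifiable. Subjects with more than 10 underinformative trials
(critical and filler alike — the threshold counts director-task trials, not
only critical ones) are excluded entirely; remaining non-identifiable
trials are dropped individually; flagged mislabelled trials are retained.
Exclusion is idempotent by construction.

The model is a Bayesian logistic regression on critical, identifiable
trials with Normal(0, 2) priors on all coefficients, by-subject random
intercepts with a half-Normal(0, 1) prior on their SD (the group-level
prior is not pinned down by the analysis being emulated; half-Normal(0, 1)
is weakly informative on the log-odds scale), dummy-coded contrasts with
the reference levels above, and MCMC via JAGS (4 chains × 2000 iterations,
half warm-up). Convergence is enforced, not assumed: the fit errors if any
Gelman–Rubin R-hat exceeds 1.05. For fully between-subject designs
(Experiment 2's condition factor) the sampler uses a hierarchically
centered parameterisation — subject effects centred on the subject-level
linear predictor — which leaves the posterior unchanged but mixes far
better than the sum parameterisation when fixed effects are
subject-constant. Where the printed reference levels and the body text of
the emulated analysis disagree (the body text names Material-Redundant as a
reference while the coefficient table names Colour-Redundant and lists a
Material-Redundant *effect*), the coefficient table's own footnote is
followed: the reference is Colour-Redundant, which is the only reading
consistent with the listed effect names.

Model comparison uses a Bayes factor from Laplace-approximated marginal
likelihoods at the joint posterior mode (over coefficients, random
intercepts and log group SD, with an analytic gradient for the
optimisation). This is an approximation, documented as such, and kept out
of the recovery targets; for the nested logistic comparisons used here it
reliably orders models generated with and without an interaction.

Psychometric curves are fitted by maximum-likelihood logistic regression of
label on continuum position (pooled and per subject), with percentile
bootstrap intervals; displayed points are binned five trials per bin.
Degenerate (constant-response) data are flagged and the boundary reported
at the edge of the observed positions. Proportion summaries bootstrap
subject means with B = 1000 percentile resamples.

## Numerical and design choices

* Step indices are 1-based and endpoints count toward the step total ("10
  steps" = endpoints + 8 interior).
* Staircase positions clamp to `[1, n_steps]`; a clamped regression still
  counts its reversal.
* Waveforms are peak-limited by rescaling only when the raw peak exceeds 1,
  and RMS normalisation follows synthesis, so limiting almost never
  engages in practice.
* Seeds: every simulation entry point takes an explicit seed; per-stage
  seeds are derived deterministically from it and kept below 2^31. MCMC
  chains receive derived per-chain RNG seeds, so fits are exactly
  reproducible.
* The "SE" column reported alongside posterior means is the posterior SD.

## Scale of the packaged validation runs

The recovery checks simulate the full study sizes (72 subjects for
Experiment 1; 20 per condition for Experiment 2) and assert each posterior
mean lands within ±0.35 of its generating value in a single seeded run —
the tolerance implied by the posterior spread at those sample sizes.
Credible-interval calibration is checked on 100 reduced-scale null
simulations (16 subjects × 36 trials, 2 chains × 3000 iterations, β = 0
truth), pooling coverage over all three coefficients (about 300 intervals)
so that the binomial noise of the check (± about 1 percentage point) is
small against the 93–97% acceptance band. The scale was chosen so the check
measures the procedure rather than small-sample artefacts: with only 8
trials per condition per subject, log-odds contrasts are intrinsically
anticonservative by 1–2 points and short chains add Monte-Carlo noise to
the interval endpoints, neither of which is a property of the fitting code. Staircase boundary recovery is checked over 200
seeded dual runs per attribute. Each staircase's low-discriminability
stimulus (the final correct identification) sits systematically on its own
side of the boundary — the confirmation follows a regression, so the
estimate is offset toward the staircase's own start by roughly the terminal
regression step plus the two-down/one-up convergence offset (about
$0.88\sigma$). The two staircases bracket the boundary symmetrically, and
the dual procedure's boundary estimate is the midpoint of the two extracted
indices; its median absolute error is required to be within 1 step of the
observer's boundary for material (10 steps) and within 4 steps for colour
(50 steps), and lands well inside both (about 0.35 and 0.8 steps at the
default observer slopes).

## What passing tests do and do not show

The simulated agents have, by construction, exactly the statistical
structure the analysis assumes: logistic psychometric observers, a
logit-linear speaker with additive subject intercepts, independent trials.
Passing recovery therefore validates the *pipeline* — calibration, design,
coding, exclusion and inference are mutually consistent and unbiased — but
says nothing about whether human speakers satisfy those assumptions: real
data bring strategy shifts over time, trial-order effects, non-logistic
psychometric shapes, correlated lapses, and audience design, none of which
the generator emulates. Empirical coefficient values from human data are
likewise outside what this package can or does reproduce.

## Known limitations

* The modal synthesis is a simplification; it does not reproduce any
  specific recorded material, and the shipped parameter sets are synthetic.
* The Bayes factor is Laplace-approximated, not bridge-sampled; treat it as
  an ordering, not a calibrated evidence ratio.
* Experiment 2's emulated analysis is ambiguous between sum and dummy
  contrasts in its source description; dummy coding (matching the reported
  coefficient table) is the default, with sum contrasts available via
  `model_spec(contrasts = "sum")`. Whether that analysis included
  by-subject intercepts is equally unstated; they are included here, which
  widens posterior uncertainty relative to a fixed-effects reading but
  leaves posterior means recoverable.
* Browser delivery, animation rendering, audio playback timing and
  free-text response parsing are out of scope; expressions are structured
  objects throughout.
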