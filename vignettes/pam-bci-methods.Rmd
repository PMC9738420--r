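---
title: "Simulating performance accommodation in a motor-imagery BCI game, and analysing its ordinal ratings"
author: "pamgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating performance accommodation in a motor-imagery BCI game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamgame)
```

## The problem this package addresses

Motor-imagery (MI) brain–computer interfaces are used in stroke
rehabilitation, but many users control them poorly, and poor control breeds
frustration and disengagement. One remedy is to wrap the BCI in a game whose
*performance accommodation mechanisms* (PAMs) quietly lower the challenge:
**augmented success** (AS) amplifies a genuine success, **mitigated failure**
(MF) converts a failure into a neutral outcome, and **input override** (IO)
converts a failure into a success. `pamgame` provides a desk-scale simulator
of such a system — synthetic EEG, an online decoder, a fishing-game state
machine, and the urn-model trial scheduler that doses the help — together
with a from-scratch ordinal mixed-model toolkit for analysing the 7-point
perceived-control and frustration ratings such experiments produce. A
transcribed per-participant study table (18 participants × 4 conditions,
one missing cell) ships with the package, and the analysis pipeline
reproduces its published model comparisons.

## The ordinal model at the core

Ratings are ordinal, so the package models them with a cumulative link
(proportional odds) mixed model. For subject $i$, observation $j$, rating
$Y_{ij} \in \{1,\dots,J\}$:

$$\Pr(Y_{ij} \le k \mid b_i) \;=\;
  \mathrm{logit}^{-1}\!\left(\theta_k - x_{ij}^\top \beta - b_i\right),
  \qquad b_i \sim N(0, \sigma^2),$$

with strictly increasing thresholds $\theta_1 < \dots < \theta_{J-1}$
("flexible" threshold structure), fixed effects $\beta$, and a subject
random intercept absorbing between-subject baseline differences in how the
scale is used. The marginal likelihood integrates $b_i$ out per subject;
`clmm()` approximates each one-dimensional integral by the Laplace method:
an inner Newton iteration (tolerance $10^{-10}$, concave objective) locates
the conditional mode, and a second-order expansion there yields the
per-subject contribution. The outer optimization runs over
$(\theta_1, \log\Delta\theta_2, \dots, \beta, \log\sigma)$ — the increasing
reparameterization enforces threshold ordering, the log keeps $\sigma$
positive — using `nlminb` followed by BFGS from three deterministic starts
around the fixed-effects solution, then a Newton polish on the observed
information until the gradient norm is below $10^{-8}$. Standard errors
come from the inverse observed information at the optimum.

Model size is $k = (J-1) + p + 1$ and $\mathrm{AIC} = 2k - 2\ell$. The
variance parameter counts toward $k$ even when $\hat\sigma$ sits on the
zero boundary (`fix_sigma = 0` gives the fixed-effects likelihood with the
bookkeeping unchanged), which is what makes the package's AICs directly
comparable with the published tables. Likelihood-ratio tests (`lr_test()`,
`anova()`) use $2\Delta\ell$ against a $\chi^2$ with $\Delta k$ degrees of
freedom, and `forward_stepwise()` implements AIC-guided forward selection
in which a candidate is admitted only when its LR test against the current
model has $p < 0.05$; AIC ties break by larger LR, then term name.

Analysis conventions: ratings printed on the normalized 0–1 grid are
recoded back to integer levels with `recode_rating()`
($\mathrm{round}(1 + 6v)$) and analysed at those levels — AIC and the
likelihood are invariant to strictly monotone relabelling (a property the
tests check), so nothing hinges on the labels. The condition factor uses
the no-help condition as reference level. The row with the single missing
cell is dropped listwise (71 of 72 rows), and one participant excluded at
source never enters the table.

### Why Laplace, and how accurate it is here

The Laplace approximation is the standard fast route for a scalar random
effect, and it is what the published analysis used, so reproducing the
printed AICs requires reproducing its bias as well as its likelihood. The
test suite pins the implementation down from two independent directions:
an oracle that recomputes the Laplace likelihood per subject with
`optimize()` and finite differences agrees to ~$10^{-6}$, and a 50-node
Gauss–Hermite quadrature oracle measures the *intrinsic* approximation
error: up to ~0.15 log-likelihood units with only 4 observations per
subject (exactly zero whenever $\hat\sigma$ collapses), shrinking within
0.05 by a dozen observations per subject. On the packaged 71-row table the
fits match the published AICs to better than 0.05 units, which also shows
the whole-percent rounding of the printed covariates is benign.

## The simulator

**Synthetic EEG.** `synthetic_mi_epochs()` emulates a calibration session:
4-s epochs at 250 Hz over F3, F4, C3, Cz, C4, P3, P4, built from broadband
noise (default SD 1 µV) plus band-limited mu (8–12 Hz, SD 2 µV) and beta
(13–30 Hz, SD 1 µV) rhythms with mild log-normal epoch-to-epoch amplitude
variability. During MI the rhythm power on C3/Cz is scaled by
$1-\texttt{erd\_depth}$, mimicking event-related desynchronization;
`erd_depth = 0` makes the classes exactly exchangeable, which the null
tests exploit. The generator emulates stationary rhythms and spatially
independent channels; it does not model volume conduction, eye or muscle
artifacts, 1/f background structure, or non-stationarity, so passing tests
certify the pipeline's logic, not its robustness to real recordings.

**Decoder.** `calibrate_decoder()` runs the standard pipeline — 5th-order
Butterworth band-pass 8–30 Hz (zero-phase), common spatial patterns (6
components, 3 per end of the eigenvalue spectrum, covariances
trace-normalized with $10^{-6}$ diagonal loading), log-variance features,
linear discriminant — with stratified 5-fold cross-validation refitting
the whole pipeline per fold. Online, `stream_decode()` emits one score per
1/16 s from a sliding 1-s analysis buffer, mapped to $(0,1)$ by the
logistic of the signed discriminant distance; near the start of a signal
the buffer truncates to what is available, and trial simulations pass 1 s
of lead-in so the 2-s input window yields its full 32 decisions.
`detect_mi()` declares MI at the first run of 8 consecutive decisions (0.5
s at 16 Hz) at or above the threshold, latency being the last decision of
that run. The probability threshold (default 0.5) and dwell are separate,
configurable quantities. `tune_threshold()` models the short online test
run before play: by default it picks the lowest grid threshold whose
false-activation rate on idle windows stays at or below 0.2 — keeping
false positives rare while leaving the BCI as easy as possible to activate
— because the Youden-style alternative (also provided) leaves the
operating point arbitrary precisely when the decoder carries no
information. With these defaults a strong simulated user (ERD depth 0.8)
succeeds in >80% of trials and a no-information user lands around 10–25%,
spanning the low-to-high control range real users exhibit.

**Game.** The fishing game is a small deterministic state machine
(`game_config()`, `spawn_fish()`, `apply_feedback()`): fish appear in a
uniformly random lane needing 1–3 reels, escape at 3 unreels; positive
feedback reels one step, extra-positive two (overshoot caps at the catch,
with no carry-over), neutral holds position. Hook steering is abstracted
away — the simulated player always hooks the fish, as no hooking failures
were reported. A fish still hooked when the condition's 20 trials run out
counts as lost, applied uniformly.

**Urn scheduler.** Each helped condition plans
$\mathrm{round}(0.30 \times 20) = 6$ special trials shuffled uniformly
among 20 (`plan_condition()`; rounding is half-up for other configs).
`resolve_attempt()` maps (behavior, PAM, genuine attempt) to delivered
feedback and an outcome-change label: IO and MF specials disregard the
user's input in experiment mode (deployment mode, selectable, fires them
only on failure), while AS requires a genuine success — a failed AS trial
resolves as a normal failure and `replan_after_failure()` re-inserts the
owed special uniformly among the remaining normal slots, dropping and
logging it when none remain. An extra-positive trial counts as *one*
positive-feedback trial (the variable is a count of trials) even though it
advances the reel by two.

The 70% control cap was genuinely open to interpretation. A strict
worst-case look-ahead (convert upcoming normal slots to forced rejections
whenever banked positives plus all future positive-capable slots exceed
$\lfloor 0.7 n\rfloor + 1$) plants rejections from trial one for *every*
player, including those who never approach the cap. The package's default
trigger therefore follows the reported behaviour — rejections are inserted
when the player is succeeding *above the target*: conversion starts once
delivered positives exceed $0.7 \times$ trials-played by at least one full
trial, after which the worst-case projection is enforced. Under this rule
a player with ~10% success never sees a rejection (the cap is
unreachable), while a perfect player is capped at $0.75 = 0.7 + 1/20$
exactly; both strategies (`"above_target"`, `"eager"`) and the converted
slot choice (random or earliest) are exposed on `enforce_control_cap()`.
One known edge remains: a player who hovers just below the trigger while
all six IO specials sit in the final slots can finish marginally above the
cap (at most 0.80); the configurations the tests exercise, and perfect
players in particular, respect the bound.

**Cohorts.** `simulate_cohort()` replays the full pipeline — scheduler,
game, summary — for a vector of per-participant success rates (defaults to
the packaged reference-condition MI conversion rates, mean 0.575), with a
Bernoulli attempt model or full decoder-based users. Ratings are left
missing: the package deliberately has no generative model of human
ratings, so simulated cohorts exercise the explanatory variables only.

## Packaged study table

`load_study_table()` reads the transcribed per-participant session table
and validates its structural invariants: ratings on the 1/6 grid of a
7-point scale, percentages in multiples of 5 (consistent with 20 trials),
the reference condition's positive feedback identical to its MI conversion
rate, 18 participants × 4 conditions with exactly one missing cell.
Off-grid cells fail hard with a list of offenders. One participant's
all-zero fish counts are printed that way at source; the loader reports
them with a message and keeps them, since the published grand means
include them. Per-participant mean rows are not stored — tests recompute
them and compare against the printed header values.

## Problem sizes and numerical choices

The test suite uses calibration sets of 20–60 epochs, conditions of 20
trials, cohorts of up to 18 simulated users, and 50 parameter-recovery
replicates at 100 subjects × 4 observations (mean absolute error of the
recovered fixed effect below 0.1). Cell probabilities are computed in the
better logistic tail and floored at $10^{-300}$; CSP refuses numerically
singular pooled covariances; zero-variance calibration features signal a
calibration failure rather than propagating degenerate models.

## Known limitations

* The simulator's EEG is stationary and artifact-free; decoder accuracies
  here are optimistic relative to real recordings.
* Simulated cohorts cannot reproduce rating-side results (no human model);
  they validate the scheduler's delivered-feedback statistics only.
* The Laplace likelihood inherits its intrinsic small-sample bias; for
  designs with very few observations per subject and a need for exact
  likelihoods, a quadrature-based fit (not provided) would be preferable.
* The best published model for perceived control adds the per-condition
  help rate as a covariate; that covariate is not printed per cell in the
  source table, so it can only be studied here on simulated cohorts.
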