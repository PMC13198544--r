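---
title: "A generative mixture model for multifeature whole-report recall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A generative mixture model for multifeature whole-report recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wholereport)
library(dplyr)
```

## The problem

In continuous-report tests of visual short-term memory, observers memorise a
small set of objects — here three dots, each defined by a colour (a hue angle
on a colour wheel) and a location (an angle on an invisible circle around
fixation) — and later reproduce those features on continuous response scales.
Recall errors are classically decomposed into noisy reports centred on the
target, *misbinding* (reporting a feature that belongs to a different
memorised object), and guesses drawn uniformly from the response space.

Single-feature cued recall cannot tell whether a misbinding error is a
*symmetric swap* — two objects genuinely exchanging a feature — or an
*asymmetric misattribution*, where one object receives another object's
feature while the displaced feature is simply lost and guessed.  Multifeature
whole report can: the observer reproduces **both** features of **all three**
objects, in a freely chosen order, so the fate of every feature is on the
table.  This package implements a generative mixture model of that task, the
machinery to fit it hierarchically across subjects, and the decompositions
that turn fitted parameters into interpretable error rates.

## The generative model

One trial produces a 6-dimensional response vector (three colour reports and
three location reports; on cued trials the cue dimension is a forced choice
among the three displayed features).  The forward model draws, in order:

1. **Report order.**  A categorical draw over the six permutations of the
   three objects (`order_weights`, one parameter on the 6-simplex).  Observers
   are free to report objects in any order, so the model must marginalise over
   this mapping; otherwise a mere change of report order would masquerade as
   a memory failure.
2. **Binding error.**  A categorical draw: with probability `p_swap` two
   objects exchange a feature on one dimension (the pair uniform over the
   three possibilities), with probability `p_cyclic_swap` all three features
   rotate (two possible directions, uniform), otherwise no binding error.
   Because a pairwise colour-swap and the mirror-image location-swap produce
   identical colour–location pairings for two-feature objects, swaps are
   represented canonically on the colour dimension (the report dimension on
   cued trials); this avoids a non-identifiable latent label.
3. **Guesses.**  Per object, a Bernoulli *object guess* (both features
   forgotten) or independent per-feature *feature guesses*.  The rates depend
   on the error context: `g_feature`/`g_object` on no-error trials,
   `g_feat_swap_swp`/`g_obj_swap_swp` for the two objects inside a swap,
   `g_feat_swap_non`/`g_obj_swap_non` for the bystander object, and
   `g_feat_cyclic`/`g_obj_cyclic` on cyclic trials.  An object guess takes
   precedence over the feature draws for that object.
4. **Emission.**  Each non-guessed feature is drawn from a von Mises
   distribution centred on its assigned source feature, with concentration
   `kappa_colour` or `kappa_location` (precision shared across the three
   objects); guessed features are uniform on the circle.

That is 12 scalar parameters plus the report-order weights — 13 free
parameters per parameter group.  Parameters may differ between cued trials
and the two uncued conditions (colour-first `uncued_CL`, location-first
`uncued_LC`); both cued probes share one group.

A swap accompanied by guessing *within* the swap is exactly an asymmetric
misattribution: information flowed one way, and the reciprocal feature was
lost.  A swap with no guessing on the swapped dimension is a symmetric
misbinding.  The model therefore separates the two without ever observing
them directly.

## Likelihood

The marginal likelihood of a trial sums over every latent state: report
orders (6, uncued trials only) x binding-error configurations (no error, 3
swap pairs, 2 cyclic directions) x per-object guess states.  The full
enumeration (4500 states for an uncued trial, 162 for a cued trial) is
exposed by `enumerate_latents()`/`state_loglik()` for transparency and
testing.  The production path (`trial_loglik()`, `loglik_trials()`) uses the
same sum with the per-object guess layer collapsed in closed form — per
object the guess mixture factorises, so each (order, error) cell costs three
object marginals — implemented in C++ and equal to the explicit enumeration
to floating-point accuracy (this identity is asserted against an
independently coded brute-force oracle in the test suite).

On cued trials the observed cue selection fixes the slot-to-object mapping:
the cue dimension is copied exactly (density contribution 1), order weights
drop out of the likelihood, and binding errors and guesses act on the report
dimension only.

Numerical conventions: angles are degrees in `[0, 360)` at every interface
and radians inside density code; densities are per radian; an exactly
antipodal circular distance resolves to +180 for determinism; mixture sums
are accumulated in probability space per trial (the state space is small and
the factorised form keeps terms well-scaled), with `-Inf` returned only when
the trial is genuinely impossible under the parameters.

## Hierarchical estimation

Subject-level parameters live on transformed scales — log for the two
concentrations, logit for the ten probabilities, an anchored 5-dimensional
softmax for the order weights — and are constrained by a population Normal
per parameter: `t_sp ~ N(mu_p, sd_p)`.  Hyperpriors are weakly informative:
`mu_p ~ N(0, 1.5)` and `sd_p ~ half-N(1)` on the transformed scale; order
weights carry a flat Dirichlet(1) at the subject level.  These hyperpriors
are exposed in `population_prior()` and can be varied for prior-sensitivity
checks.

Sampling is Metropolis-within-Gibbs: per-subject adaptive Gaussian random
walks on each transformed scalar (target acceptance 0.44, Robbins-Monro
adaptation during warm-up only), a joint 5-dimensional random walk for each
subject's order weights (target 0.25), a conjugate Gibbs draw for each
population mean, and a log-scale random walk for each population SD.  The
discrete latent states never enter the sampler — they are summed out of the
likelihood exactly — which keeps the chain on a fixed-dimension continuous
space.  The constraint `p_swap + p_cyclic_swap <= 1` is enforced by
rejection.  Chains are initialised at the prior means (concentrations at 5)
and are reproducible given the seed.

The reference configuration is 5000 adaptation iterations, 10,000 retained
iterations and 4 chains (40,000 retained draws, `mcmc_config()`); per-subject
estimates are posterior means over the retained draws.  Simulation studies
and the test suite use the scaled-down `mcmc_config_quick()` (500/1000/2,
2000 draws), which this package's compiled likelihood completes in about two
minutes on one core for 12 subjects x 120 trials; the vignette and tests
state the problem sizes they use and were chosen as the smallest designs at
which the checks are statistically meaningful.

### Model variants

`build_variant()` defines the comparison set: `full`; `null` (no swapping,
no guessing — concentrations and order weights only); `no_asymmetric` (swaps
allowed but all within-swap and cyclic guess parameters frozen at zero, so
asymmetric misattribution cannot arise); `collapse_cue_uncued` (one shared
parameter set); and `collapse_order` (the two uncued conditions share a
set).  Variants are compared by WAIC on the pointwise posterior
log-likelihood matrix (`pointwise_loglik()`, `waic()`), with the variance
form of the effective-parameter penalty and ΔWAIC relative to the best
model.

## Decompositions

Conditional on a swap of objects *i* and *j*, the closed-form composition
follows from the within-swap guess rates (`swap_composition()`):
symmetric = `((1-g_obj)(1-g_feat))^2` (neither swapped object object-guessed
nor feature-guessed on the swapped dimension), asymmetric-by-object-guess =
`1-(1-g_obj)^2` (at least one swapped object wholly guessed; an object guess
dominates the label), and asymmetric-by-feature-guess the remainder.
Guesses on the bystander object, or on the unswapped dimension, do not
change the label — the reciprocal exchange on the swapped dimension is still
intact.  `classify_trials()` produces the same taxonomy per trial as a
posterior over six classes (correct, symmetric swap, asymmetric by feature,
asymmetric by object, cyclic, pure guess), evaluated at per-subject
posterior means; on large simulated datasets the mean class masses over
ground-truth swap trials recover the generating composition, which the test
suite checks to within 0.05.

`absolute_error()` reports the raw slotwise unsigned circular error without
any latent reassignment (the quantity that motivates the model: it confounds
report order with memory failure).  `report_order_bias()` measures the
topmost-first/leftmost-first reporting tendency; because the uncued data do
not label which object a report was aimed at, the first reported object is
attributed as the one whose true location is circularly nearest to the first
reported location, with screen-up at 90 degrees (configurable — the
coordinate frame is a convention).

## Inferential layer

`bf_ttest()` implements the JZS Bayes factor: a zero-centred Cauchy prior
(default scale 0.707) on the standardised effect size, integrated by
adaptive quadrature through the Zellner–Siow inverse-gamma representation of
the g-prior (substituting `g = r^2 h` keeps the integrand well-scaled at any
prior scale).  `bf_correlation()` places a stretched-beta prior (default
width 1, i.e. uniform) on the population correlation and uses the exact
sampling density of Pearson's r (Gauss hypergeometric series).
`interpret_bf()` applies the conventional evidence bands (>100 extreme,
30–100 very strong, 10–30 strong, 3–10 moderate, 1/3–3 anecdotal, with
reciprocal bands below 1/3 and extreme support for the null below 0.01).
`within_subject_sem()` implements the Loftus–Masson normalisation: subtract
each subject's mean across conditions, add back the grand mean, then take
per-condition SEMs — between-subject offsets cancel exactly.

Quadrature rather than Monte Carlo is used for every Bayes factor so results
are deterministic; both constructions are verified against independent
numerical-integration oracles in the tests.

## What the synthetic generator does and does not emulate

`make_design()`/`simulate_dataset()` reproduce the task's stimulus
statistics: three dots on a 6.5 degree-of-visual-angle circle, dot centres at
least 1.4 dva apart (enforced as the equivalent central angle,
`2*asin(1.4/13)` ≈ 12.36 degrees), hues uniform with at least 5 degrees of
pairwise separation, rejection-sampled with an attempt cap.  The generator
retains the ground-truth latent state of every trial, which is what makes
parameter-recovery and classification-calibration studies possible.

It deliberately does **not** emulate several features of real behaviour:
output interference (error growing over the report sequence — marginalised
over, as in the model), sequential-presentation primacy/recency structure,
response-time structure, perceptual similarity effects between nearby hues,
or strategic, confidence-dependent guessing.  Passing recovery tests
therefore shows that the estimation machinery is correct and well calibrated
*under the model's own assumptions*; it does not certify those assumptions
for real data.

## Design choices that were genuinely open

* **Swap dimension canonicalisation** — pairwise colour- and location-swaps
  are observationally equivalent, so a single canonical representation (the
  colour/report dimension) is used; the alternative (a latent dimension
  label) would be unidentifiable and double-count states.
* **Cued-trial semantics** — the cue dimension is treated as data: exact
  copies, never guessed, order weights unused.  Re-inferring the cue mapping
  would add latent states with no likelihood support.
* **Uniform swap-pair and rotation choices** — the minimal assumption in the
  absence of stated structure.
* **Object-guess precedence** — "object guess" is one Bernoulli blanking
  both features, drawn before (and overriding) the per-feature draws; a
  guessed feature may land anywhere, including near its true value, so
  duplicated correct reports are attributed to guessing.
* **Sampler choice** — Metropolis-within-Gibbs with exact discrete
  marginalisation, rather than data augmentation of latent states or an
  external PPL: the state space is small enough to sum exactly, which makes
  the likelihood testable against brute force and keeps the sampler simple.
  The likelihood seam (`loglik_trials()`) would admit an HMC backend.

## Known limitations

* The population model is a diagonal Normal on transformed scales; parameter
  correlations across subjects are not modelled.
* Order weights have no population-level pooling (flat Dirichlet per
  subject).
* Slow-mixing tail parameters (e.g. within-swap guess rates at low swap
  counts) can show high split-Rhat under the quick configuration; `glance()`
  reports diagnostics so this is visible, and the reference configuration
  mixes substantially better.
* WAIC is the only model-comparison tool provided (no LOO-CV), matching the
  intended use.

## A small worked run

```{r recovery, eval = FALSE}
cfg <- default_config()           # 12 subjects x 120 uncued trials
res <- run_recovery(cfg, seed = 1, quick = TRUE)
res$coverage                      # population means vs 95% intervals
res$comparison                    # full vs null by WAIC
plot_composition(res$fit)
```

The same pipeline is scriptable from a shell via the launcher in
`inst/cli/` (`simulate`, `fit`, `compare`, `classify`, `summarize`, `bf`,
`recover` subcommands), and `scripts/acceptance.R` runs the whole chain —
simulation, three variant fits, decomposition, model comparison and the
normalisation check — writing its numbers to JSON.
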