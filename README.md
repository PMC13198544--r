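# wholereport

Hierarchical Bayesian mixture modelling of **multifeature whole-report**
visual short-term memory.

## The problem

In continuous-report memory tasks, observers memorise three coloured dots —
each defined by a hue angle on a colour wheel and a location angle on a
circle around fixation — and reproduce those features after a delay.
Recall errors mix noisy target reports, *misbinding* (reporting a feature
that belongs to a different object), and uniform guesses.  Standard cued
recall cannot tell whether a misbinding is a **symmetric swap** (two objects
genuinely exchange a feature) or an **asymmetric misattribution** (one
object receives another's feature while the displaced feature is lost and
guessed).  Whole report of *both* features of *all three* objects, in a
freely chosen order, can — given a generative model that marginalises over
the unknown report order.

This package provides that model for experimenters working with
continuous-report data: a forward simulator of the task, the exact marginal
likelihood, hierarchical MCMC fitting, WAIC model comparison, and the
decomposition of swap errors into symmetric and asymmetric components.

## The model

Per trial the model generates a 6-dimensional response vector
(3 colour + 3 location reports) through four latent stages:

1. report order `π` ~ Categorical over the 6 permutations (*order weights*);
2. binding error ~ Categorical: symmetric swap (`P_swap`, pair uniform),
   cyclic three-way swap (`P_cyclic_swap`, direction uniform), or none;
3. per-object Bernoulli guesses — whole-object (`G_object`-family) or
   per-feature (`G_feature`-family) — with separate rates for objects inside
   a swap (`G_*_swap_swp`), beside a swap (`G_*_swap_non`), and on cyclic
   trials (`G_*_cyclic`);
4. emission: von Mises around the assigned source feature with concentration
   `κ_colour` / `κ_location`; uniform for guessed features.

That is 13 free parameters per condition group (12 scalars + the
order-weight simplex), estimated per subject under population-level Normal
constraints on transformed scales.  The per-trial likelihood sums over the
full latent support (report orders × swap/cyclic configurations × guess
states) exactly; a swap with within-swap guessing *is* an asymmetric
misattribution, so the fitted guess rates decompose swaps in closed form.

Model variants (`null`, `no_asymmetric`, `collapse_cue_uncued`,
`collapse_order`) are compared by WAIC; the inferential layer provides JZS
Bayes-factor t-tests (Cauchy prior, default scale 0.707), a default-prior
correlation Bayes factor, and Loftus–Masson within-subject SEMs.

## Worked example

Simulate 12 subjects × 120 uncued (colour-first) trials from known
parameters, fit the full model with the scaled-down MCMC configuration, and
inspect recovery:

```r
library(wholereport)
library(dplyr)

truep <- model_params(kappa_colour = 10, kappa_location = 15, p_swap = 0.06,
                      p_cyclic_swap = 0.01, g_feature = 0.12, g_object = 0.05,
                      g_feat_swap_non = 0.1, g_feat_swap_swp = 0.2,
                      g_obj_swap_non = 0.05, g_obj_swap_swp = 0.15,
                      g_feat_cyclic = 0.1, g_obj_cyclic = 0.05)
swap_composition(truep)
#> # A tibble: 1 × 5
#>   p_swap_overall frac_symmetric frac_asym_feature frac_asym_object p_cyclic
#>            <dbl>          <dbl>             <dbl>            <dbl>    <dbl>
#> 1           0.06          0.462             0.260            0.278     0.01

design <- make_design(12, 120, conditions = "uncued_CL", seed = 21)
data   <- simulate_dataset(design, truep, seed = 22)
fit    <- fit_hierarchical(data, build_variant("full"),
                           mcmc = mcmc_config_quick(seed = 5))  # ~2 min

tidy(fit) |>
  filter(term %in% c("kappa_colour", "kappa_location", "p_swap",
                     "g_feature", "g_object")) |>
  select(term, estimate, conf.low, conf.high)
#> # A tibble: 5 × 4
#>   term           estimate conf.low conf.high
#>   <chr>             <dbl>    <dbl>     <dbl>
#> 1 kappa_colour    10.6      9.96     11.3
#> 2 kappa_location  14.8     14.0      15.6
#> 3 p_swap           0.0672   0.0340    0.103
#> 4 g_feature        0.123    0.110     0.139
#> 5 g_object         0.0385   0.0260    0.0531

glance(fit) |> select(variant, n_draws, max_rhat, accept_rate)
#> # A tibble: 1 × 4
#>   variant n_draws max_rhat accept_rate
#>   <chr>     <int>    <dbl>       <dbl>
#> 1 full       2000     1.84       0.438
```

Every generating value sits inside its 95% posterior interval: the swap rate
(6%), both guessing rates, and both concentrations are recovered.
`swap_composition()` says that with these within-swap guess rates only ~46%
of swap trials are true symmetric misbindings — the rest are asymmetric
misattributions, which is precisely the distinction the model exists to
make.  (With 2000 quick-configuration draws some weakly identified
parameters still show elevated split-R̂; the reference configuration,
`mcmc_config()`, runs 4 chains × 10,000 retained draws.)

Downstream: `classify_trials()` gives per-trial posteriors over the six
error classes, `compare_models()` ranks variants by ΔWAIC,
`plot_composition()` draws the decomposition with within-subject error bars,
and `bf_ttest()` / `bf_correlation()` quantify condition differences.  The
same pipeline is available from a shell via the launcher in `inst/cli/`
(subcommands `simulate`, `fit`, `compare`, `classify`, `summarize`, `bf`,
`recover`).

See `vignettes/whole-report-model.Rmd` for the full model description,
assumptions, and design choices.

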