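# matemarket

Evolutionary agent-based models of human mating markets under competing
mate-preference-integration algorithms, with a Euclidean mate-value metric
layer and an out-of-sample procedure for scoring each simulated market
against cross-cultural survey-style data.

## The problem

People hold ideal-partner preferences on many dimensions at once, but choose
one whole person. Whatever psychology turns a multi-dimensional preference
vector plus a candidate's traits into a single evaluation is the *preference
integration algorithm*, and different hypotheses about it imply different
mating-market dynamics. `matemarket` implements eight market models — six
integration rules (Euclidean distance over ideal points, cosine similarity,
aspiration ranges, linear, sinusoidal, and cubic-polynomial preference
functions) plus two null models (random pairing; random pairing followed by
updating one's ideals 90% toward the chosen partner) — and the analysis
pipeline used to decide which model best explains survey data.

All models share one scale. For vectors $a, b$ on a 1–7 instrument with $n$
dimensions,

$$s(a,b) \;=\; 10\left(1 - \frac{\lVert a-b\rVert}{6\sqrt{n}}\right)\in[0,10],$$

and the four measures are: **preference fulfillment** $s(\text{own ideal},
\text{partner's traits})$; **mate value** $s(\text{own traits},
\bar p_{\text{opposite sex}})$; **ideal-partner mate value** ("choosiness")
$s(\text{own ideal}, \bar p_{\text{same sex}})$; and the **partner's mate
value** — where $\bar p$ is the group's mean preference vector (a model run
or a country). The *power of choice* pattern is the trio of positive
within-group correlations of mate value with fulfillment, choosiness, and
the partner's mate value (assortative mating).

Markets evolve by: attraction matrices from the integration rule →
elementwise mutual-attraction combination → greedy pairing of the most
mutually attracted couples → roulette-wheel reproduction weighted by couple
energy (inverse deviation of traits from a per-run optimal vector) →
non-overlapping generations. A synthetic cross-cultural cohort generator
(`generate_cohort()`) emulates the survey side with controlled effect sizes,
and `compare_models()` trains per-run multilevel regressions
(`outcome ~ mate_value * outcome_type + (1 | individual)`) and scores them
sight-unseen on the cohort by RMSE and predicted–observed correlation.

## Worked example

```r
library(matemarket)

# five replicate euclidean markets: 200 agents, 20 traits, 200 generations
base <- sim_config("euclidean", mutation_sd = 0.15, selection_strength = 0.15,
                   seed = 1)
sweep <- run_sweep(base, mutation_sds = 0.15, selection_strengths = 0.15,
                   runs = 5)
records <- do.call(rbind, lapply(names(sweep), function(tag) {
  r <- mate_value_suite(sweep[[tag]]); r$group <- tag; r
}))
power_of_choice_stats(records)$summary
#>          statistic mean    sd n_groups ci_lo ci_hi
#> 1 mean_fulfillment 4.86 1.562        5  2.92  6.80
#> 2 r_mv_fulfillment 0.86 0.044        5  0.81  0.91
#> 3       r_mv_ideal 0.17 0.429        5 -0.36  0.70
#> 4     r_mv_partner 0.88 0.044        5  0.82  0.93
```

Mean scaled fulfillment sits near 4.9/10 after 200 generations under the
default (capped-advantage) selection regime, with strong mate-value
gradients: higher mate-value agents fulfill their preferences better
(r ≈ 0.86) and pair assortatively (r ≈ 0.88); the choosiness gradient is
positive on average but unstable across runs at this horizon. The methods
vignette (`vignettes/mating-market-models.Rmd`) discusses why preference
convergence is the slow mode of these dynamics and what the alternative
`selection = "proportional"` regime changes.

The survey side, with known structure wired in:

```r
cohort <- generate_cohort(cohort_spec(seed = 1))   # 45 countries, ~14.5k rows
power_of_choice_stats(mate_value_suite(cohort))$summary
#>          statistic mean    sd n_groups ci_lo ci_hi
#> 1 mean_fulfillment 8.11 0.172       45  8.06  8.16
#> 2 r_mv_fulfillment 0.16 0.090       45  0.13  0.19
#> 3       r_mv_ideal 0.28 0.077       45  0.26  0.30
#> 4     r_mv_partner 0.29 0.109       45  0.26  0.32
```

The generator wires latent gradients of 0.26/0.38/0.35; the 7-point
instrument and partner-report noise attenuate the recovered values, exactly
as they would in real ratings. `compare_models(runs_by_model, cohort_records)`
then produces the leaderboard of how well each market's trained regression
predicts the cohort, with a cohort-trained in-sample baseline on top, and
`plot_fit_report()` draws it.

A full experiment (simulate → metrics → compare, with an on-disk manifest
and resumable runs) is driven by `cmd_simulate()` / `cmd_metrics()` /
`cmd_compare()` / `cmd_synth()`, or from a shell via the thin wrapper
`inst/cli/matemarket.R`.

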