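# affectcue

How do observers combine what a person's face and body show with what
the surrounding scene suggests when judging how that person feels?
`affectcue` is an R package for analyzing continuous valence–arousal
ratings (bounded on [−1, 1]) collected under cue-isolating conditions —
`context_only` (character obscured), `character_only` (scene obscured)
and `ground_truth` (both visible) — and for deciding *which combination
rule* best explains the ground-truth ratings. It is aimed at
computational cognitive scientists running emotion-tracking or
cue-combination studies, and at anyone who wants a fully testable,
seeded pipeline for reliability-weighted cue integration.

## The models

At each trial or timepoint, the context and character cues are
summarized by rating distributions with means μ_c, μ_f and
across-observer spreads σ_c, σ_f (spread = momentary cue ambiguity).
Seven candidate strategies map these to a predicted rating:

| strategy | rule |
|---|---|
| `bayes` | precision-weighted product of cue distributions: μ* = (μ_c/σ_c² + μ_f/σ_f²)/(1/σ_c² + 1/σ_f²), variance 1/(1/σ_c² + 1/σ_f²) |
| `heuristic` | unweighted average (μ_c + μ_f)/2; variance = (σ_c² + σ_f²)/2 |
| `context75` / `character75` | stable weights 0.75/0.25 (and the reverse) |
| `all_in` | follow the lower-variance cue at each timepoint |
| `random_switch` | follow one cue per timepoint, fair coin |
| `correlated_switch` | Markov switching between cues, 10% switch rate |

The Bayesian posterior is computed on a discretized affect grid in log
space, normalized by a max-stabilized log-sum-exp (exact under the flat
prior), so multiplying near-underflowing densities is safe. Models are
scored against ground truth with Pearson r, RMSE and the
Gaussian-residual AIC = n·ln(SSE/n) + 2k, with bootstrap percentile CIs,
chi-squared sign tests on per-observer AIC differences, paired
t/Wilcoxon tests, and protected exceedance probabilities (PXP).

A seeded synthetic-data generator produces whole rating cohorts — smooth
latent affect trajectories, two cue channels with time-varying
ambiguity, observer noise, and a ground-truth channel produced by a
*known* strategy — so model recovery can be verified end to end. See the
methods vignette (`vignettes/affective-cue-integration.Rmd`) for the
model, the generator, and every numerical design choice.

## Worked example

Simulate a Bayes-generated cohort at a moderate scale, then ask both
analyses which strategy explains the ratings:

```r
library(affectcue)

cfg <- synthetic_config(n_videos = 4, duration_s = 60, n_observers = 30,
                        generating_strategy = "bayes", seed = 42)
cohort <- generate_dataset(cfg)

group <- run_group_level(cohort, n_boot = 1000, seed = 1)
print(group)
#> <comparison_report> group level, 7 model(s)
#>              model pearson_r    rmse    aic
#>              bayes    0.9979 0.02220 -18305
#>          heuristic    0.9703 0.08490 -11867
#>          context75    0.9610 0.09666 -11275
#>        character75    0.9540 0.10432 -10866
#>             all_in    0.9902 0.04963 -14443
#>      random_switch    0.9236 0.13596  -9600
#>  correlated_switch    0.9275 0.13323  -9702
#> AIC winner: bayes

indiv <- run_individual_level(cohort,
                              models = c("bayes", "heuristic", "all_in"),
                              n_boot = 1000, seed = 1)
print(indiv)
#> <comparison_report> individual level, 3 model(s)
#>      model pearson_r   rmse    aic
#>      bayes    0.9628 0.1027 -10940
#>  heuristic    0.8497 0.2118  -7463
#>     all_in    0.9363 0.1362  -9584
#> AIC winner: bayes
#> per-observer winners: bayes=30
#> PXP: bayes=1.000, heuristic=0.000, all_in=0.000
```

Reading the output: the generator was the reliability-weighted rule, and
both analyses recover it — the Bayes row has the highest correlation
with the ground-truth trajectory (r = 0.998 at the consensus level), the
smallest RMSE, and the lowest (best) AIC; every one of the 30 simulated
observers is individually classified as a Bayes integrator, and the PXP
places all posterior mass on that strategy. The same pipeline applied to
a `heuristic`-generated cohort flips the ranking. Bootstrap CIs for any
metric are in `indiv$ci`; per-observer metrics in `indiv$per_observer`.

Real data enter through `read_ratings()` (tidy CSV, one row per
observer/video/condition/timepoint) and `resample_to_grid()`; a thin
command-line front end lives at `inst/cli/affectcue.R` with `simulate`,
`fit`, `compare` and `recover` subcommands.

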