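# tracermix

Quantitative diet estimation for predators from two complementary biotracers:
**fatty-acid (FA) profiles** and **stable-isotope (SI) ratios**. The package is
aimed at trophic ecologists who want to run the same Bayesian mixing analysis
on both tracer families — as has been done for sympatric pack-ice seal
populations — with the tracer-specific preprocessing, source screening and
convergence checking that workflow requires, and at methodologists who want a
fully synthetic, reproducible testbed for that workflow.

## The model

A consumer's tracer values are modelled as a proportion-weighted mixture of
its prey ("sources"). For consumer *i* and tracer *j*,

```
x_ij ~ Normal( mu_j(p), omega_j^2(p, xi) )

mu_j(p)      = sum_k p_k (mu_kj + Delta_j)
omega_j^2(p) = xi_j * sum_k p_k^2 (sigma_kj^2 + sigma_Dj^2)
```

where `p = (p_1..p_K)` are the diet proportions on the simplex with a
Dirichlet(alpha) prior (alpha = 1: uninformative), `mu_kj`/`sigma_kj` are the
source means/SDs, `Delta_j ± sigma_Dj` is the additive trophic discrimination
factor (TDF), and `xi_j > 0` is a per-tracer multiplicative process-error
factor with a standard log-normal prior (the `process_only` error model fixes
`xi = 1`). Optional concentration dependence replaces `p_k` per tracer by
`p_k c_kj / sum_l p_l c_lj`.

The two tracer families enter the same likelihood differently:

* **SI** (δ13C, δ15N in ‰): discrimination is additive, e.g. 2.2 ± 0.7‰ and
  3.5 ± 0.6‰; it stays in the likelihood so its uncertainty propagates.
* **FA** (proportions of total FA): trophic modification is multiplicative.
  Prey profiles are multiplied by per-FA **calibration coefficients** (CC) and
  renormalized — moved into "predator space" — before fitting, and the
  additive discrimination is then zero. FAs with CC > 3 are excluded as
  metabolism-dominated (`select_fa_tracers()`).

Before fitting, sources are screened for statistical distinguishability with
distance-based PERMANOVA (Bray–Curtis for FA, Euclidean for SI) plus pairwise
comparisons with Bonferroni adjustment, and NMDS for visual inspection.
Sources that cannot be told apart are pooled by transitive closure of the
non-difference graph (`build_aggregation_plan()`, `combine_sources()`),
producing combined groups with concatenated labels (e.g. `Pa_Ea`).

Posterior sampling is adaptive random-walk Metropolis on the
multinomial-logit transform of the simplex, 3+ chains from over-dispersed
starts, with Gelman–Rubin and Geweke convergence diagnostics.

## Worked example

Generate a synthetic three-predator study (groups of n = 21, 18, 13
consumers; FA and SI variants; a CC table with one coefficient above the
exclusion threshold; one deliberately confounded SI source pair) and run the
FA pipeline on the first group:

```r
library(tracermix)

dir <- file.path(tempdir(), "study")
make_study_bundle(dir, seed = 1)

cfg <- run_config(n_iter = 20000, n_burn = 10000, thin = 10, seed = 99,
                  n_permutations = 499)
res <- run_fa_pipeline(
  consumer_file  = file.path(dir, "groupA_fa_consumers.csv"),
  source_file    = file.path(dir, "groupA_fa_sources.csv"),
  cc_file        = file.path(dir, "groupA_fa_cc.csv"),
  replicate_file = file.path(dir, "groupA_fa_source_replicates.csv"),
  config = cfg)
res
#> <pipeline_result>
#> <screen_result>
#>   global pseudo-F(3) = 48.81, p = 0.002
#>   4 sources -> 4 groups after aggregation
#> <diet_fit> FA model, 4 sources, 21 consumers
#>   3 chains x 1000 kept draws; convergence ok (max rhat 1.008)
#>   source1            0.840 (0.816-0.862)
#>   source2            0.049 (0.010-0.085)
#>   source3            0.090 (0.062-0.117)
#>   source4            0.020 (0.004-0.049)

dplyr::filter(res$selection, !keep)
#> # A tibble: 1 × 4
#>   tracer     cc keep  reason
#>   <chr>   <dbl> <lgl> <chr>
#> 1 22:5n-3   3.5 FALSE cc_above_threshold
```

Reading the output: the prey species are all distinguishable (global
PERMANOVA pseudo-F = 48.8, permutation p = 0.002), so no sources were pooled;
one fatty acid (22:5n-3, CC = 3.5) was dropped before fitting; and the
posterior median diet attributes 84.0% (95% CI 81.6–86.2%) to the dominant
source — the simulation truth for this group is 0.84. `tidy()`, `glance()`,
`autoplot()`, `plot_posterior_density()` and `plot_traces()` give tibble and
ggplot views of the fit; `write_posterior_report()` exports the summary and
raw draws as seed-stamped CSV.

The SI counterpart (`run_si_pipeline()`) additionally merges the confounded
source pair found by screening before fitting, exactly as indistinguishable
prey are pooled in field studies.

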