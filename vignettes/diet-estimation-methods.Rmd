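---
title: "Dual-biotracer diet estimation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-biotracer diet estimation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracermix)
```

This vignette is the package's own account of the science it implements: the
mixing model and its assumptions, the preprocessing that differs between
fatty-acid (FA) and stable-isotope (SI) tracers, the source-screening step,
the sampler and its numerical choices, and what the synthetic-data generator
does and does not emulate.

## The mixing model

A consumer's tracer vector is modelled as a noisy proportion-weighted
combination of source (prey) signatures. For consumer $i$ and tracer $j$:

$$x_{ij} \sim \mathrm{Normal}\!\left(\mu_j(p),\ \omega_j^2(p,\xi)\right),
\qquad
\mu_j(p) = \sum_k p_k (\mu_{kj} + \Delta_j),
\qquad
\omega_j^2 = \xi_j \sum_k p_k^2 (\sigma_{kj}^2 + \sigma_{\Delta j}^2).$$

* $p$ lives on the $K$-simplex with a $\mathrm{Dirichlet}(\alpha)$ prior;
  the default $\alpha = (1,\dots,1)$ is uninformative.
* $\mu_{kj}, \sigma_{kj}$ are source summaries (means and SDs), not raw prey
  data: the model consumes literature-style per-species tables.
* $\Delta_j \pm \sigma_{\Delta j}$ is the additive trophic discrimination
  factor. It stays inside the likelihood — mean shift plus variance term —
  rather than being pre-added to source means, so TDF uncertainty propagates
  into the posterior.
* $\xi_j > 0$ is the per-tracer multiplicative process-error factor
  (`error_model = "process_x_residual"`), with independent standard
  log-normal priors ($\log \xi_j \sim N(0,1)$ — weakly informative, chosen
  because the error structure names no prior). `"process_only"` fixes
  $\xi \equiv 1$.
* Concentration dependence (off by default) replaces $p_k$ per tracer with
  $p_k c_{kj} / \sum_l p_l c_{lj}$, so proportions refer to assimilated
  tracer mass. It is off by default because per-source concentration data
  are rarely available for wild-prey compilations.

Assumptions worth stating plainly: consumers are exchangeable draws from one
population diet (no individual random effects, no covariates); tracers are
conditionally independent given $p$ and $\xi$; each retained FA proportion is
treated as an unconstrained Gaussian tracer, ignoring the simplex constraint
— the convention of Gaussian-likelihood mixing tools applied to FA data.
Compositional likelihoods (e.g. ilr-transformed) are out of scope.

## Tracer-specific preprocessing

**Stable isotopes.** Raw instrument ratios convert to delta notation via
$\delta = (R_{sample}/R_{standard} - 1) \times 1000$ (‰; V-PDB for carbon,
atmospheric N$_2$ for nitrogen). Whiskers analysed in 2 mm sections are
averaged per individual (`mean_consumer_isotope()`, unweighted) because diet
estimation uses one value per consumer. Defaults ship nothing for the TDF;
the worked examples use 2.2 ± 0.7‰ ($\delta^{13}$C) and 3.5 ± 0.6‰
($\delta^{15}$N), sea-otter-derived values commonly applied to pinnipeds.

**Fatty acids.** All FA math happens on proportions of total FA
(`normalize_fa_profile()`; percent input accepted with a `%` header flag).
Trophic modification of FAs is multiplicative, quantified by per-FA
calibration coefficients (CC) from captive feeding studies. Because the
likelihood treats trophic modification additively, prey profiles are moved
into predator space *before* fitting:

$$\mu'_{kj} = \frac{\mu_{kj}\,CC_j}{\sum_l \mu_{kl}\,CC_l},$$

after which $\Delta \equiv 0$. Candidate FAs (the dietary + extended-dietary
list, shipped as an editable vector, `default_fa_names()`) with CC above the
threshold (default 3, exclusion strictly `>`) are dropped first: a large CC
means predator metabolism, not diet, dominates that FA's signal.

Two open choices were settled as follows:

* **SD transfer under CC.** Only means are stated to be multiplied in the
  workflow this package systematizes. We scale each $\sigma_{kj}$ by the same
  per-source linear factor $CC_j / \sum_l \mu_{kl} CC_l$ (first-order
  treatment holding the renormalization denominator at its mean), which keeps
  per-tracer coefficients of variation stable. `scale_sd = FALSE` leaves SDs
  untouched; both behaviours are tested.
* **12-FA membership.** The retained FA set depends on the CC table and
  threshold, so it is configuration, not code: `select_fa_tracers()` records
  a per-tracer reason (`kept`, `cc_above_threshold`, `user_excluded`).

## Source screening and aggregation

Mixing models need statistically distinguishable sources. Screening requires
replicate-level prey data (summaries alone cannot support permutation tests;
the pipelines skip screening with a warning when only summaries exist):

1. Distance matrix: Bray–Curtis for FA compositions, Euclidean for SI pairs
   (both selectable). Computed by vegan.
2. Global and pairwise PERMANOVA, implemented in-package: the Huygens
   decomposition $SS_{total} = \sum_{i<j} d_{ij}^2 / N$, pseudo-F
   $= (SS_{among}/(g-1)) / (SS_{within}/(N-g))$, and the permutation p-value
   $(1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})$ with the observed
   statistic counted among the permutations (999 by default, seeded).
   On Euclidean distances of univariate data the pseudo-F is algebraically
   the one-way ANOVA F, which the tests verify to 1e-9, alongside a
   cross-check against `vegan::adonis2` and a full-enumeration oracle.
3. Pairwise p-values are Bonferroni-adjusted by default (Holm or any
   `p.adjust` method available), capped at 1.
4. `build_aggregation_plan()` merges sources by **transitive closure** of
   "adjusted p ≥ α" links. Closure reproduces the pooling of mutually
   indistinguishable sets and resolves intransitive triples
   deterministically (if A~B and B~C but A≁C, all three merge). Combined
   labels concatenate abbreviated member names ("Pa_Ea" style).
5. `combine_sources()` pools member moments: n-weighted mean, and the pooled
   SD of the reconstructed member samples with denominator $N-1$,
   $s^2 = [\sum_k (n_k{-}1) s_k^2 + n_k (m_k - \bar m)^2] / (N-1)$. With
   equal member SDs this shrinks the SD by $\sqrt{(N-g)/(N-1)}$ — the exact
   consequence of the $N-1$ convention, asserted in the tests.

NMDS (Kruskal stress-1, best of 20 random starts via `vegan::metaMDS`) is
provided for visual inspection; it never gates the pipeline.

A note on permutation p-values in degenerate corners: when within-group
distances are exactly zero the pseudo-F is infinite, and any permutation that
recreates the same partition ties with it, so the attainable minimum p equals
the tie mass (e.g. 2/20 for two groups of three), not
$1/(1+n_{perm})$. With any within-group scatter the observed F is the unique
maximum and p reaches its floor.

## Sampling and numerical choices

* **Parameterization.** $p$ is sampled on the multinomial-logit transform
  $z \in \mathbb{R}^{K-1}$, $p = \mathrm{softmax}(z, 0)$, whose Jacobian
  $\prod_k p_k$ folds the Dirichlet prior into $\sum_k \alpha_k \log p_k$;
  $\xi$ is sampled as $\theta = \log \xi$.
* **Kernel.** Block random-walk Metropolis, one block for $z$ and one for
  $\theta$, with Robbins–Monro scale adaptation in 50-iteration batches
  toward 23% acceptance, active during burn-in only (frozen afterwards, so
  the post-burn-in kernel is valid Metropolis).
* **Chains.** Default 3 chains from over-dispersed starts
  ($z \sim N(0, 1.5^2)$); per-chain seeds derive deterministically from the
  run seed, so a fixed seed reproduces draws bitwise.
* **Run length.** Defaults are deliberately long (100k iterations, 50k
  burn-in, thin 50). The test suite and the acceptance script use shorter,
  stated runs (typically 8k–30k iterations, thin 4–10, and 20 replicate
  datasets per recovery scenario) — sizes chosen so the whole suite re-runs
  in a few minutes while keeping Monte-Carlo error far below the tolerances
  being asserted.
* **Likelihood internals.** The Gaussian likelihood is evaluated from
  per-tracer sufficient statistics (n, mean, centred SS), making each
  evaluation O(KJ). The generator and the likelihood share one
  implementation of $\mu_j(p)$ and $\omega_j^2(p)$, so the two cannot drift
  apart.
* **Variance floor.** A constant (default $10^{-12}$) is added to every
  $\omega_j^2$ to keep the density proper in zero-variance corners; tests
  confirm it does not bias recovery. The zero-variance "analytic limit" test
  raises the floor to $10^{-4}$ (σ = 0.01‰): with exactly zero variance the
  posterior is a Dirac mass no sampler can traverse, while the tiny floor
  yields a posterior whose width (~0.002 in $p$) is far inside the ±0.02
  band being checked.
* **Degenerate inputs.** Zero variance with data off the mixture mean gives
  log-posterior $-\infty$ (not an exception); an exact match gives $+\infty$
  and is accepted. All-zero FA rows are rejected at validation.

## Convergence diagnostics

Gelman–Rubin PSRF $\hat R = \sqrt{((n{-}1)/n \cdot W + B/n)/W}$ per
parameter across chains, and Geweke $z$ per parameter per chain (first 10%
vs last 50%, standard errors from the AR-fit spectral density at frequency
zero). Thresholds: $\hat R < 1.05$, $|z| < 2$. Both are reported
per-parameter; coda's implementations serve as independent cross-checks in
the tests.

The omnibus `pass` flag applies $\hat R < 1.05$ strictly, but is
multiplicity-aware for Geweke: with $K + J$ parameters over 3 chains there
are dozens of $z$ scores, and $|z| \ge 2$ occurs ~5% of the time on
perfectly stationary chains, so requiring *all* scores below 2 would fail
most converged fits by chance. The flag therefore tolerates up to the upper
99% binomial bound of threshold crossings at rate 0.05 and hard-fails any
$|z| \ge 4$. A failed flag always warns, and the pipelines refuse to write
report files without `force = TRUE`.

## The synthetic-data generator

`make_study_bundle()` emulates a three-predator pinniped study: consumer
groups of n = 21, 18 and 13; FA variants with 12 tracers and 4–5 sources; SI
variants with 2 tracers and 3–5 sources; dominant-source truths of
0.84/0.91, 0.657/0.72 and 0.663/0.632 (krill- and fish-dominated diets at
the scale reported for pack-ice seals); a CC table containing one
coefficient above 3 to exercise exclusion; and one deliberately confounded
SI source pair to exercise aggregation.

What it emulates:

* Gaussian source scatter around distinct means; SI source means span a
  realistic Antarctic envelope (δ13C −26.5 to −21.5‰, δ15N 3.5 to 11.5‰)
  with the δ15N levels shuffled across sources so the source polygon has
  area — collinear source means would collapse the 2-tracer mixing space to
  one dimension and make diets unidentifiable by construction.
* FA source profiles drawn from a Dirichlet, replicates by logistic-normal
  jitter (perturb log proportions, renormalize), so replicates stay on the
  simplex.
* Consumers drawn from *exactly* the fitted likelihood via the shared
  mean/variance code; FA consumers are renormalized onto the simplex after
  the Gaussian draw (negative cells truncated at zero first, count
  recorded). This renormalization is the one deliberate mismatch with the
  fitted likelihood — it is tiny at realistic noise levels (row sums deviate
  from 1 by ~3% before renormalization) and mirrors how real percent tables
  arise.

What it does not emulate — and hence what passing tests do not show about
real data: whisker growth and temporal integration of diet; blubber-layer
stratification and turnover; non-Gaussian or skewed prey distributions;
inter-individual diet heterogeneity (the model's exchangeability assumption
is true in the generator, unknowable in the field); errors in the CC or TDF
values themselves (the generator uses the same modifier the model is given,
whereas field TDFs are borrowed across species).

## Known limitations

* **SI under-determination.** With 2 isotopes, diets of more than 3 sources
  are under-determined ($K-1 > J$): the posterior concentrates on a solution
  manifold and shrinks toward the prior. The synthetic K=5 SI scenarios show
  dominant-source errors of 0.2–0.35 — the honest behaviour of the method,
  matching the near-uniform minor-source estimates such models produce in
  the field. FA models ($J = 11$–12 after exclusion) do not share this
  limit; their recovery errors in the acceptance runs are 0.001–0.05.
* **Posterior medians of a simplex-valued posterior** are marginal and need
  not sum to 1 (documented in `summarize_posterior()`).
* The report writes both the 95% equal-tailed credible interval and the
  min–max of draws, because "median (and range)" summaries are ambiguous
  between the two; the credible interval is the headline.
* No hierarchical structure (individual effects, covariates, time-varying
  diet) and no informative priors — single-population snapshots only.

## Reduced problem sizes used by the automated checks

Recovery: 3 scenarios × 20 replicate datasets, fits at 10k iterations / 3
chains. Grid-integration oracle: 3 sources × 2 tracers, step 0.01 (4,950
simplex points) against 18k kept draws. Null calibration of PERMANOVA: 200
simulated null datasets at 199 permutations. These sizes keep each
assertion's Monte-Carlo error well below the tolerance it checks.
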