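test_that("mixture mean and variance match hand arithmetic", {
  src <- toy_si_sources(sd = 2)
  mod <- zero_modifier()
  # pure-source corner
  expect_equal(unname(mixture_mean(c(1, 0, 0), src, mod)), c(-25, 5))
  # weighted combination, hand computed
  expect_equal(unname(mixture_mean(c(0.5, 0.3, 0.2), src, mod)), c(-21.9, 9.7))
  # discrimination shifts the mean additively
  mod2 <- seal_modifier()
  expect_equal(unname(mixture_mean(c(1, 0, 0), src, mod2)), c(-22.8, 8.5))

  # variance: p=(1,0,...), sigma=2, sigma_delta=0.7 -> 4.49
  mod3 <- trophic_modifier(si_suite(), delta_mean = c(0, 0), delta_sd = c(0.7, 0.7))
  expect_equal(unname(mixture_variance(c(1, 0, 0), src, mod3))[1], 4.49)
  # zero-variance limit
  src0 <- toy_si_sources(sd = 0)
  expect_equal(unname(mixture_variance(c(0.5, 0.3, 0.2), src0, mod)), c(0, 0))
  # p^2 convexity: an even split of symmetric sources beats a pure source
  expect_lt(mixture_variance(c(0.5, 0.5, 0), src, mod)[1],
            mixture_variance(c(1, 0, 0), src, mod)[1])

  expect_error(mixture_mean(c(0.5, 0.5), src, mod), "length")
  expect_error(mixture_mean(c(0.7, 0.7, -0.4), src, mod), "sum to 1|nonnegative")
})

test_that("concentration dependence reweights by tracer mass", {
  si <- si_suite()
  src <- source_table(tibble::tibble(
    source = rep(c("A", "B"), each = 2),
    tracer = rep(c("d13C", "d15N"), 2),
    mean = c(-25, 5, -18, 12), sd = 0.5, n = 5,
    conc = c(0.4, 0.1, 0.4, 0.1)
  ), si)
  mod <- zero_modifier()
  # equal concentrations across sources leave the mean unchanged
  expect_equal(mixture_mean(c(0.3, 0.7), src, mod, concentration_dependence = TRUE),
               mixture_mean(c(0.3, 0.7), src, mod))
  # unequal concentrations pull the mean toward the concentrated source
  src2 <- source_table(tibble::tibble(
    source = rep(c("A", "B"), each = 2),
    tracer = rep(c("d13C", "d15N"), 2),
    mean = c(-25, 5, -18, 12), sd = 0.5, n = 5,
    conc = c(0.9, 0.9, 0.1, 0.1)
  ), si)
  mu_cd <- mixture_mean(c(0.5, 0.5), src2, mod, concentration_dependence = TRUE)
  expect_equal(unname(mu_cd), c(0.9 * -25 + 0.1 * -18, 0.9 * 5 + 0.1 * 12))
})

test_that("log posterior has the right shape", {
  src <- toy_si_sources(sd = 1)
  mod <- zero_modifier()
  cfg <- run_config(error_model = "process_only")
  # prior-only (no data): uniform over the simplex under alpha = 1
  lp1 <- log_posterior(c(0.5, 0.3, 0.2), NULL, NULL, src, mod, cfg)
  lp2 <- log_posterior(c(0.1, 0.1, 0.8), NULL, NULL, src, mod, cfg)
  expect_equal(lp1, lp2)
  # a consumer at the mixture mean beats a displaced one
  p <- c(0.5, 0.3, 0.2)
  cons_at <- exact_consumers(p, src, mod, n = 1)
  mu <- mixture_mean(p, src, mod)
  df <- tibble::tibble(d13C = mu[1] + 3, d15N = mu[2] - 3)
  cons_off <- consumer_table(df, si_suite())
  expect_gt(log_posterior(p, NULL, cons_at, src, mod, cfg),
            log_posterior(p, NULL, cons_off, src, mod, cfg))
  # zero variance with mismatched data: -Inf, not an exception
  src0 <- toy_si_sources(sd = 0)
  expect_identical(log_posterior(p, NULL, cons_off, src0, mod, cfg,
                                 variance_floor = 0), -Inf)
})

test_that("the sampler recovers an exactly determined mixture", {
  src0 <- toy_si_sources(sd = 0)
  mod <- zero_modifier()
  truth <- c(0.5, 0.3, 0.2)
  cons <- exact_consumers(truth, src0, mod, n = 5)
  cfg <- run_config(n_iter = 20000, n_burn = 10000, thin = 5, seed = 9,
                    error_model = "process_only")
  fit <- suppressWarnings(fit_mixing_model(cons, src0, mod, cfg,
                                           variance_floor = 1e-4))
  smry <- summarize_posterior(fit)
  expect_equal(smry$median, truth, tolerance = 0.02)
})

test_that("identical sources leave the posterior at the prior", {
  si <- si_suite()
  src <- source_table(tibble::tibble(
    source = rep(c("A", "B", "C"), each = 2),
    tracer = rep(c("d13C", "d15N"), 3),
    mean = rep(c(-22, 9), 3), sd = 1, n = 5
  ), si)
  mod <- zero_modifier()
  cons <- exact_consumers(c(1, 0, 0), src, mod, n = 8)
  fit <- suppressWarnings(
    fit_mixing_model(cons, src, mod, test_config(seed = 2,
                                                 error_model = "process_only"))
  )
  smry <- summarize_posterior(fit)
  # non-identifiable symmetry: medians near 1/K, wide intervals
  expect_equal(smry$median, rep(1 / 3, 3), tolerance = 0.08)
  expect_true(all(smry$ci_upper - smry$ci_lower > 0.5))
})

test_that("with no data the posterior reproduces the Dirichlet prior", {
  src <- toy_si_sources(sd = 1)
  mod <- zero_modifier()
  cfg <- test_config(seed = 3, error_model = "process_only")
  fit <- suppressWarnings(fit_mixing_model(NULL, src, mod, cfg))
  means <- apply(fit$p_draws, 3, mean)
  expect_equal(unname(means), rep(1 / 3, 3), tolerance = 0.03)
  # asymmetric prior: marginal means alpha_k / sum(alpha)
  cfg2 <- test_config(seed = 4, error_model = "process_only",
                      prior_alpha = c(2, 1, 1))
  fit2 <- suppressWarnings(fit_mixing_model(NULL, src, mod, cfg2))
  means2 <- apply(fit2$p_draws, 3, mean)
  expect_equal(unname(means2), c(0.5, 0.25, 0.25), tolerance = 0.03)
})

test_that("MCMC matches deterministic grid integration on a toy posterior", {
  src <- toy_si_sources(sd = 1)
  mod <- zero_modifier()
  scn <- scenario("grid", "SI", k = 3, true_p = c(0.5, 0.3, 0.2),
                  n_consumers = 8, seed = 5, source_sd = 1)
  cons <- generate_consumers(scn, src, mod)
  cfg <- run_config(n_iter = 30000, n_burn = 6000, thin = 4, seed = 42,
                    error_model = "process_only")
  fit <- suppressWarnings(fit_mixing_model(cons, src, mod, cfg))
  mcmc_mean <- apply(fit$p_draws, 3, mean)
  oracle <- grid_posterior_mean(cons, src, mod, cfg, h = 0.01)
  expect_equal(unname(mcmc_mean), unname(oracle), tolerance = 0.01)
})

test_that("source relabeling permutes posterior summaries identically", {
  src <- toy_si_sources(sd = 1)
  mod <- zero_modifier()
  scn <- scenario("perm", "SI", k = 3, true_p = c(0.6, 0.25, 0.15),
                  n_consumers = 10, seed = 8, source_sd = 1)
  cons <- generate_consumers(scn, src, mod)
  cfg <- test_config(seed = 21, error_model = "process_only")
  fit1 <- suppressWarnings(fit_mixing_model(cons, src, mod, cfg))
  # reorder sources C, A, B
  perm <- c("C", "A", "B")
  src_perm <- source_table(
    dplyr::arrange(tibble::as_tibble(src), match(.data$source, perm)),
    si_suite()
  )
  fit2 <- suppressWarnings(fit_mixing_model(cons, src_perm, mod, cfg))
  s1 <- summarize_posterior(fit1)
  s2 <- summarize_posterior(fit2)
  expect_equal(s2$source, perm)
  expect_equal(s2$median[match(s1$source, s2$source)], s1$median,
               tolerance = 0.03)
})

test_that("fits are deterministic under a fixed seed", {
  src <- toy_si_sources(sd = 1)
  mod <- zero_modifier()
  scn <- scenario("det", "SI", k = 3, true_p = c(0.5, 0.3, 0.2),
                  n_consumers = 6, seed = 3, source_sd = 1)
  cons <- generate_consumers(scn, src, mod)
  cfg <- run_config(n_iter = 2000, n_burn = 1000, thin = 2, seed = 77)
  f1 <- suppressWarnings(fit_mixing_model(cons, src, mod, cfg))
  f2 <- suppressWarnings(fit_mixing_model(cons, src, mod, cfg))
  expect_identical(f1$p_draws, f2$p_draws)
  expect_identical(f1$xi_draws, f2$xi_draws)
})

test_that("tidy and glance expose broom-style views of a fit", {
  src <- toy_si_sources(sd = 1)
  mod <- zero_modifier()
  scn <- scenario("tidy", "SI", k = 3, true_p = c(0.5, 0.3, 0.2),
                  n_consumers = 6, seed = 3, source_sd = 1)
  cons <- generate_consumers(scn, src, mod)
  fit <- suppressWarnings(fit_mixing_model(cons, src, mod, test_config(seed = 5)))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high", "rhat") %in% names(td)))
  expect_equal(sum(startsWith(td$term, "p[")), 3)
  expect_equal(sum(startsWith(td$term, "xi[")), 2)
  gl <- glance(fit)
  expect_equal(gl$n_sources, 3)
  expect_equal(gl$n_consumers, 6)
  expect_equal(gl$seed, 5L)
})
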