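# shared fixtures: tiny deterministic objects built in code

si_suite <- function() tracer_suite("SI", c("d13C", "d15N"))

# 3-source SI toy with configurable SDs; means from a well-separated triangle
toy_si_sources <- function(sd = 1, n = 10) {
  source_table(tibble::tibble(
    source = rep(c("A", "B", "C"), each = 2),
    tracer = rep(c("d13C", "d15N"), 3),
    mean = c(-25, 5, -18, 12, -20, 18),
    sd = rep(sd, 6),
    n = n
  ), si_suite())
}

zero_modifier <- function(suite = si_suite()) {
  trophic_modifier(suite, delta_mean = rep(0, length(suite$tracers)),
                   delta_sd = rep(0, length(suite$tracers)))
}

seal_modifier <- function() {
  trophic_modifier(si_suite(), delta_mean = c(2.2, 3.5), delta_sd = c(0.7, 0.6))
}

# consumers placed exactly at the mixture mean of `p`
exact_consumers <- function(p, src, modifier, n = 5) {
  mu <- mixture_mean(p, src, modifier)
  df <- tibble::as_tibble(as.data.frame(matrix(rep(mu, each = n), nrow = n)))
  names(df) <- attr(src, "suite")$tracers
  consumer_table(df, attr(src, "suite"))
}

# fast MCMC settings for tests
test_config <- function(seed = 1L, ...) {
  run_config(n_iter = 8000L, n_burn = 4000L, thin = 4L, seed = seed, ...)
}

# independent simplex-grid integration of the unnormalized posterior
# (process_only error model, so the only unknowns are the K=3 proportions)
grid_posterior_mean <- function(cons, src, modifier, config, h = 0.01) {
  g <- seq(h / 2, 1 - h / 2, by = h)
  pts <- list(); lps <- numeric(0)
  for (p1 in g) for (p2 in g) {
    if (p1 + p2 < 1) {
      p <- c(p1, p2, 1 - p1 - p2)
      pts[[length(pts) + 1]] <- p
      lps[length(lps) + 1] <- log_posterior(p, NULL, cons, src, modifier, config)
    }
  }
  P <- do.call(rbind, pts)
  w <- exp(lps - max(lps))
  colSums(w * P) / sum(w)
}

# classical one-way ANOVA F, the analytic twin of Euclidean PERMANOVA
anova_f <- function(x, groups) {
  fit <- stats::aov(x ~ groups)
  summary(fit)[[1]][["F value"]][1]
}
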