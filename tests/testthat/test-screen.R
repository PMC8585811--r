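test_that("distance matrices match hand-computed values", {
  # identical samples sit at distance zero
  d0 <- tracer_distance(tibble::tibble(source = c("A", "A"), x = c(1, 1), y = c(2, 2)),
                        metric = "euclidean")
  expect_equal(as.vector(d0), 0)
  # Bray-Curtis of opposite simplex corners is 1
  fa <- tracer_suite("FA", c("x", "y"))
  db <- tracer_distance(tibble::tibble(source = c("A", "B"), x = c(1, 0), y = c(0, 1)),
                        suite = fa)
  expect_equal(attr(db, "metric"), "bray_curtis")
  expect_equal(as.vector(db), 1)
  # Euclidean 3-4-5 triangle on SI pairs
  de <- tracer_distance(tibble::tibble(source = c("A", "B"),
                                       d13C = c(-20, -23), d15N = c(8, 12)),
                        suite = si_suite())
  expect_equal(as.vector(de), 5)
  expect_error(tracer_distance(tibble::tibble(source = "A", x = NA_real_)), "NaN|non-numeric|missing")
})

test_that("euclidean PERMANOVA pseudo-F equals classical one-way ANOVA F", {
  withr::with_seed(31, {
    for (rep in 1:4) {
      x <- rnorm(18, mean = rep(c(0, 1, 3), each = 6))
      g <- factor(rep(c("a", "b", "c"), each = 6))
      d <- stats::dist(x)
      res <- permanova(d, g, n_permutations = 0)
      expect_equal(res$pseudo_f, anova_f(x, g), tolerance = 1e-9)
    }
  })
})

test_that("PERMANOVA agrees with an independent implementation and is invariant", {
  withr::with_seed(5, {
    X <- matrix(rnorm(30), 15, 2) + rep(c(0, 2, 4), each = 5)
    g <- factor(rep(c("a", "b", "c"), each = 5))
  })
  d <- stats::dist(X)
  res <- permanova(d, g, n_permutations = 999, seed = 8)
  ado <- vegan::adonis2(d ~ g, permutations = 999)
  expect_equal(res$pseudo_f, ado$F[1], tolerance = 1e-9)
  expect_equal(res$df_among, ado$Df[1])

  # invariance to group relabeling and global distance scaling
  relab <- factor(c(a = "z", b = "x", c = "y")[as.character(g)])
  res2 <- permanova(d, relab, n_permutations = 499, seed = 8)
  expect_equal(res2$pseudo_f, res$pseudo_f, tolerance = 1e-12)
  res3 <- permanova(d * 7.3, g, n_permutations = 499, seed = 8)
  res1b <- permanova(d, g, n_permutations = 499, seed = 8)
  expect_equal(res3$pseudo_f, res1b$pseudo_f, tolerance = 1e-9)
  expect_equal(res3$p_value, res1b$p_value)

  # determinism under a fixed seed
  expect_equal(permanova(d, g, 199, seed = 4), permanova(d, g, 199, seed = 4))
})

test_that("perfect separation attains the minimum permutation p-value", {
  # two far-apart clusters with tiny internal scatter: the observed F is the
  # unique maximum over relabelings, so p hits its floor 1/(1+n_permutations)
  withr::with_seed(61, {
    reps <- tibble::tibble(
      source = rep(c("A", "B"), each = 8),
      x = rep(c(0, 100), each = 8) + rnorm(16, 0, 0.01),
      y = rep(c(0, 100), each = 8) + rnorm(16, 0, 0.01)
    )
  })
  d <- tracer_distance(reps, metric = "euclidean")
  res <- permanova(d, n_permutations = 999, seed = 1)
  expect_equal(res$p_value, 1 / 1000)
  expect_gt(res$pseudo_f, 1e6)

  # fully degenerate groups (zero within-distance): permutations recreating
  # the same partition tie at infinite F, so p equals the tie mass, not 1/1000
  reps0 <- tibble::tibble(source = rep(c("A", "B"), each = 3),
                          x = rep(c(0, 10), each = 3),
                          y = rep(c(0, 10), each = 3))
  d0 <- tracer_distance(reps0, metric = "euclidean")
  res0 <- permanova(d0, n_permutations = 999, seed = 1)
  expect_true(is.infinite(res0$pseudo_f))
  expect_lt(res0$p_value, 0.2)  # tie mass is 2/20 of relabelings
})

test_that("permutation p matches full enumeration on N=6 two-group data", {
  withr::with_seed(13, {
    x <- matrix(rnorm(12), 6, 2) + rep(c(0, 1.2), each = 3)
  })
  g <- factor(rep(c("A", "B"), each = 3))
  d <- stats::dist(x)
  # brute-force oracle: all 20 ways to assign 3 of 6 samples to group A
  dmat <- as.matrix(d)
  fstat <- function(lab) permanova(stats::as.dist(dmat), lab, n_permutations = 0)$pseudo_f
  f_obs <- fstat(g)
  combos <- utils::combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    lab <- factor(ifelse(seq_len(6) %in% idx, "A", "B"))
    fstat(lab)
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- permanova(d, g, n_permutations = 999, seed = 2)
  # Monte-Carlo error of a proportion at 999 draws
  expect_lt(abs(res$p_value - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 999) + 2e-3)
})

test_that("pairwise comparisons adjust p-values and cap at 1", {
  withr::with_seed(17, {
    X <- matrix(rnorm(64), 32, 2)
    X[1:8, ] <- X[1:8, ] + 8            # one clearly separated group
  })
  g <- factor(rep(c("a", "b", "c", "d"), each = 8))
  d <- stats::dist(X)
  pw <- pairwise_permanova(d, g, n_permutations = 199, seed = 3)
  expect_equal(nrow(pw), 6)            # 4 groups -> 6 pairs
  expect_true(all(pw$p_adjusted >= pw$p_value))
  expect_true(all(pw$p_adjusted <= 1))
  # Bonferroni: adjusted = min(1, 6 * raw)
  expect_equal(pw$p_adjusted, pmin(1, pw$p_value * 6))
  # the separated group's pairs are significant
  sep <- pw$group_a == "a" | pw$group_b == "a"
  expect_true(all(pw$p_adjusted[sep] <= 6 * min(pw$p_value)))
})

test_that("NMDS recovers planar configurations and orders stress by dimension", {
  # a planar configuration embeds with near-zero stress
  pts <- cbind(c(0, 3, 0, 3, 1.5), c(0, 0, 2, 2, 4))
  d <- stats::dist(pts)
  attr(d, "groups") <- factor(rep("g", 5))
  fit <- suppressWarnings(nmds_screen(d, k = 2, n_starts = 10, seed = 2))
  expect_lt(fit$stress, 0.01)
  # coordinates come back centered
  expect_equal(unname(colMeans(as.matrix(fit$coordinates[c("axis1", "axis2")]))),
               c(0, 0), tolerance = 1e-8)

  # stress is non-increasing in embedding dimension
  withr::with_seed(3, { X <- matrix(rnorm(8 * 5), 8, 5) })
  d8 <- stats::dist(X)
  s2 <- suppressWarnings(nmds_screen(d8, k = 2, n_starts = 8, seed = 5))$stress
  s3 <- suppressWarnings(nmds_screen(d8, k = 3, n_starts = 8, seed = 5))$stress
  expect_lte(s3, s2 + 1e-6)

  expect_error(nmds_screen(stats::as.dist(matrix(0, 5, 5))), "all-zero")
})

test_that("aggregation plans merge by transitive closure of non-difference", {
  pw <- tibble::tibble(
    group_a = c("P. antarcticum", "P. antarcticum", "E. antarctica"),
    group_b = c("E. antarctica", "E. superba", "E. superba"),
    pseudo_f = c(1.01, 50, 60),
    p_value = c(0.9, 0.001, 0.001),
    p_adjusted = c(1.00, 0.003, 0.003)
  )
  plan <- build_aggregation_plan(pw, alpha = 0.05)
  expect_equal(plan$group[plan$source == "P. antarcticum"], "Pa_Ea")
  expect_equal(plan$group[plan$source == "E. antarctica"], "Pa_Ea")
  expect_equal(plan$group[plan$source == "E. superba"], "E. superba")

  # three mutually non-distinct species collapse into one group
  pw3 <- tibble::tibble(
    group_a = c("P. antarcticum", "P. antarcticum", "E. antarctica"),
    group_b = c("E. antarctica", "Pareledone sp", "Pareledone sp"),
    pseudo_f = c(1.01, 4.95, 1.27),
    p_value = c(1, 0.04, 1),
    p_adjusted = c(1.00, 0.20, 1.00)
  )
  plan3 <- build_aggregation_plan(pw3, alpha = 0.05)
  expect_equal(length(unique(plan3$group)), 1)
  expect_equal(unique(plan3$group), "Pa_Ea_Ps")

  # all pairs significant: identity partition
  pw0 <- pw; pw0$p_adjusted <- c(0.01, 0.01, 0.01)
  plan0 <- build_aggregation_plan(pw0)
  expect_equal(plan0$group, plan0$source)

  # output is always a partition
  expect_setequal(plan$source, unique(c(pw$group_a, pw$group_b)))
  expect_false(anyDuplicated(plan$source) > 0)
})

test_that("combining sources pools moments correctly", {
  si <- si_suite()
  src <- source_table(tibble::tibble(
    source = rep(c("A", "B"), each = 2),
    tracer = rep(c("d13C", "d15N"), 2),
    mean = c(10, 1, 20, 1), sd = c(0, 0.5, 0, 0.5), n = 5
  ), si)
  plan <- tibble::tibble(source = c("A", "B"), group = c("AB", "AB"))
  merged <- combine_sources(src, plan)
  m <- source_matrices(merged)
  # two point masses of 5 at 10 and 20: pooled mean 15, pooled SD over the
  # 10 reconstructed values sqrt(10*25/9) = 5.2705
  expect_equal(unname(m$mean[1, "d13C"]), 15)
  expect_equal(unname(m$sd[1, "d13C"]), sqrt(250 / 9), tolerance = 1e-9)
  expect_equal(unname(m$n), 10)
  # tracer with equal member means keeps the mean; the pooled SD carries the
  # exact N-1 reconstruction factor sqrt(sum (n_k-1) s_k^2 / (N-1))
  expect_equal(unname(m$mean[1, "d15N"]), 1)
  expect_equal(unname(m$sd[1, "d15N"]), 0.5 * sqrt(8 / 9), tolerance = 1e-9)

  # merging a source with itself leaves it unchanged
  plan_id <- tibble::tibble(source = c("A", "B"), group = c("A", "B"))
  same <- combine_sources(src, plan_id)
  expect_equal(source_matrices(same)$mean, source_matrices(src)$mean)
  expect_equal(source_matrices(same)$sd, source_matrices(src)$sd)

  expect_error(combine_sources(src, tibble::tibble(source = "Z", group = "Z")),
               "unknown|partition")
})
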