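test_that("delta notation follows the ratio equation", {
  # sample equal to standard sits at 0 permil
  expect_equal(delta_from_ratio(0.0112372, 0.0112372), 0)
  # hand arithmetic on the printed equation
  expect_equal(delta_from_ratio(1.1 * 0.0112372, 0.0112372), 100)
  expect_equal(delta_from_ratio(0.9 * 0.0112372, 0.0112372), -100)
  expect_error(delta_from_ratio(-1, 0.01), "positive")
  expect_error(delta_from_ratio(0.01, 0), "positive")
  # strictly increasing in the sample ratio
  r <- seq(0.9, 1.1, by = 0.01)
  expect_true(all(diff(delta_from_ratio(r, 1)) > 0))
})

test_that("whole-whisker means average sections per individual", {
  one <- tibble::tibble(id = "s1", d13C = -22, d15N = 10)
  expect_equal(mean_consumer_isotope(one)$d13C, -22)
  two <- tibble::tibble(id = "s1", d13C = c(-20, -24), d15N = c(8, 12))
  out <- mean_consumer_isotope(two)
  expect_equal(c(out$d13C, out$d15N), c(-22, 10))
  many <- tibble::tibble(id = "s1", d13C = rep(-21.3, 30), d15N = rep(9.9, 30))
  expect_equal(mean_consumer_isotope(many)$d15N, 9.9)
  expect_error(mean_consumer_isotope(two[0, ]), "no whisker sections")
})

test_that("FA normalization is proportional, closed and idempotent", {
  expect_equal(normalize_fa_profile(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  p <- c(0.1, 0.2, 0.7)
  expect_equal(normalize_fa_profile(p), p)
  expect_equal(normalize_fa_profile(normalize_fa_profile(c(7, 1, 3))),
               normalize_fa_profile(c(7, 1, 3)))
  expect_equal(normalize_fa_profile(c(1, 0, 0)), c(1, 0, 0))
  expect_error(normalize_fa_profile(c(0, 0)), "all-zero")
  m <- matrix(c(2, 3, 5, 1, 1, 2), 2, 3, byrow = TRUE)
  expect_equal(rowSums(normalize_fa_profile(m)), c(1, 1))
})

test_that("tracer selection drops high-CC fatty acids with reasons", {
  cand <- paste0("fa", 1:14)
  cc <- stats::setNames(c(rep(1, 12), 3.5, 4.2), cand)
  sel <- select_fa_tracers(cand, cc, threshold = 3)
  expect_equal(sum(sel$keep), 12)
  expect_equal(sel$reason[sel$cc > 3], rep("cc_above_threshold", 2))
  # a CC exactly at the threshold is kept (exclusion is strictly >)
  cc2 <- stats::setNames(c(3, 1, 1), c("x", "y", "z"))
  expect_true(all(select_fa_tracers(c("x", "y", "z"), cc2)$keep))
  # user exclusions and the <2-survivors guard
  sel3 <- select_fa_tracers(c("x", "y", "z"), cc2, exclude = "x")
  expect_equal(sel3$reason[1], "user_excluded")
  expect_error(select_fa_tracers(c("x", "y"), stats::setNames(c(9, 9), c("x", "y"))),
               "fewer than 2")
})

test_that("calibration-coefficient transfer renormalizes and round-trips", {
  fa <- tracer_suite("FA", c("a", "b", "c"))
  src <- source_table(tibble::tibble(
    source = rep(c("S1", "S2"), each = 3),
    tracer = rep(c("a", "b", "c"), 2),
    mean = c(0.5, 0.3, 0.2, 0.1, 0.6, 0.3),
    sd = c(0.05, 0.03, 0.02, 0.01, 0.06, 0.03),
    n = 8
  ), fa)

  # identity coefficients are a no-op
  id <- apply_calibration_coefficients(src, c(a = 1, b = 1, c = 1))
  expect_equal(source_matrices(id$source)$mean, source_matrices(src)$mean,
               tolerance = 1e-12)
  expect_equal(source_matrices(id$source)$sd, source_matrices(src)$sd,
               tolerance = 1e-12)

  # hand arithmetic: multiply then renormalize
  out <- apply_calibration_coefficients(src, c(a = 2, b = 1, c = 1))
  expect_equal(unname(source_matrices(out$source)$mean[1, ]),
               c(1.0, 0.3, 0.2) / 1.5, tolerance = 1e-9)
  # closure: rows re-sum to 1
  expect_equal(unname(rowSums(source_matrices(out$source)$mean)), c(1, 1),
               tolerance = 1e-9)
  # the returned modifier carries zero additive discrimination
  expect_equal(unname(out$modifier$delta_mean), c(0, 0, 0))
  expect_equal(unname(out$modifier$delta_sd), c(0, 0, 0))

  # reciprocal CC recovers the original means (brute-force round trip)
  withr::with_seed(21, {
    for (rep in 1:5) {
      cc <- stats::setNames(exp(rnorm(3, 0, 0.5)), c("a", "b", "c"))
      fwd <- apply_calibration_coefficients(src, cc)
      bak <- apply_calibration_coefficients(fwd$source, 1 / cc)
      expect_equal(source_matrices(bak$source)$mean, source_matrices(src)$mean,
                   tolerance = 1e-9)
    }
  })

  expect_error(apply_calibration_coefficients(src, c(a = -1, b = 1, c = 1)),
               "positive")
  # SD scaling keeps the per-tracer coefficient of variation stable
  cv_in <- source_matrices(src)$sd / source_matrices(src)$mean
  cv_out <- source_matrices(out$source)$sd / source_matrices(out$source)$mean
  expect_equal(cv_out, cv_in, tolerance = 1e-9)
  # scale_sd = FALSE leaves SDs untouched
  raw <- apply_calibration_coefficients(src, c(a = 2, b = 1, c = 1), scale_sd = FALSE)
  expect_equal(source_matrices(raw$source)$sd, source_matrices(src)$sd)
})

test_that("discrimination attaches to SI sources and shifts the model mean", {
  src <- toy_si_sources(sd = 0.5)
  att <- attach_discrimination(src, delta_mean = c(2.2, 3.5), delta_sd = c(0.7, 0.6))
  # a pure-source consumer has model mean mu_k + Delta
  mu <- mixture_mean(c(1, 0, 0), att$source, att$modifier)
  expect_equal(unname(mu), c(-25 + 2.2, 5 + 3.5))
  # zero discrimination leaves the mean at the source mean
  z <- attach_discrimination(src, delta_mean = c(0, 0), delta_sd = c(0, 0))
  expect_equal(unname(mixture_mean(c(1, 0, 0), z$source, z$modifier)), c(-25, 5))
  expect_error(attach_discrimination(src, delta_mean = c(2.2, 3.5),
                                     delta_sd = c(-0.1, 0.6)), "nonnegative")
  expect_error(attach_discrimination(src, delta_mean = 2.2, delta_sd = 0.7),
               "match")
})
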