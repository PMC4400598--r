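# Kolmogorov-Smirnov machinery: statistic, asymptotic series, exact p,
# two-sample mode, and the uniform-null wrapper.

test_that("angle normalisation maps [0, 90] onto [0, 1]", {
  expect_equal(normalize_angles(angle_dataset("g", c(0, 45, 90))), c(0, 0.5, 1))
  expect_equal(normalize_angles(c(11.1)), 11.1 / 90)
  expect_error(angle_dataset("g", numeric(0)), class = "gcorient_validation_error")
  expect_error(angle_dataset("g", c(10, 95)), class = "gcorient_validation_error")
})

test_that("uniform KS statistic matches hand values and the brute-force sup", {
  expect_equal(ks_statistic_uniform(0.5), 0.5)
  expect_equal(ks_statistic_uniform(c(0.1, 0.2, 0.3)), 0.7)
  n <- 100
  # evenly spaced sample i/(n+1): both one-sided gaps peak at exactly 1/(n+1)
  expect_equal(ks_statistic_uniform(seq_len(n) / (n + 1)), 1 / (n + 1), tolerance = 1e-12)
  withr::with_seed(42, {
    for (rep in 1:5) {
      u <- runif(sample(3:60, 1))
      expect_equal(ks_statistic_uniform(u), brute_force_uniform_D(u), tolerance = 1e-9)
    }
  })
  expect_error(ks_statistic_uniform(c(0.2, 1.4)), class = "gcorient_validation_error")
})

test_that("asymptotic Kolmogorov p reproduces closed forms and is monotone", {
  expect_equal(kolmogorov_p_asymptotic(0, 10), 1)
  # direct series at one hand-checkable point
  lam <- sqrt(41) * 0.5582
  expect_equal(kolmogorov_p_asymptotic(0.5582, 41),
               2 * sum((-1)^(0:19) * exp(-2 * (1:20)^2 * lam^2)), tolerance = 1e-12)
  # monotone non-increasing in D (fixed n) and in n (fixed D)
  ds <- seq(0.01, 0.9, by = 0.01)
  ps <- vapply(ds, kolmogorov_p_asymptotic, numeric(1), n = 31)
  expect_true(all(diff(ps) <= 1e-12))
  ns <- c(5, 10, 20, 50, 100, 400)
  pn <- vapply(ns, function(n) kolmogorov_p_asymptotic(0.15, n), numeric(1))
  expect_true(all(diff(pn) <= 1e-12))
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("exact Kolmogorov p matches closed forms at n = 1 and the reference routine", {
  # D_1 = max(U, 1-U) >= 0.5 always; P(D_1 >= 0.9) = P(U <= .1) + P(U >= .9)
  expect_equal(kolmogorov_p_exact(0.5, 1), 1)
  expect_equal(kolmogorov_p_exact(0.9, 1), 0.2, tolerance = 1e-12)
  expect_error(kolmogorov_p_exact(0.1, 2000), class = "gcorient_validation_error")
  # cross-check against stats::ks.test exact small-sample p on real samples
  withr::with_seed(99, {
    for (n in c(5, 17, 31, 80)) {
      u <- runif(n)
      ref <- stats::ks.test(u, "punif", exact = TRUE)
      expect_equal(ks_statistic_uniform(u), unname(ref$statistic), tolerance = 1e-12)
      expect_equal(kolmogorov_p_exact(ks_statistic_uniform(u), n), ref$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("exact p converges to the asymptotic value as n grows", {
  # the asymptotic approximation error is O(1/sqrt(n)): about 0.017 at n = 100
  # and D = 0.1, shrinking below 0.005 by n = 1000
  for (n in c(100, 250, 500)) {
    for (D in c(0.05, 0.1, 0.2)) {
      expect_lt(abs(kolmogorov_p_exact(D, n) - kolmogorov_p_asymptotic(D, n)), 0.02)
    }
  }
  gap <- function(n, D) abs(kolmogorov_p_exact(D, n) - kolmogorov_p_asymptotic(D, n))
  expect_lt(gap(1000, 0.05), 0.005)
  expect_lt(gap(1000, 0.05), gap(100, 0.05))
})

test_that("two-sample KS handles degenerate and disjoint samples", {
  x <- c(0.2, 0.5, 0.8)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(c(0.1, 0.2), c(0.8, 0.9))$D, 1)
  withr::with_seed(7, {
    u <- runif(31); v <- runif(25)
    ref <- suppressWarnings(stats::ks.test(u, v))
    expect_equal(ks_two_sample(u, v)$D, unname(ref$statistic), tolerance = 1e-12)
  })
  expect_error(ks_two_sample(numeric(0), x), class = "gcorient_validation_error")
})

test_that("test_against_random covers degenerate, null and single-point datasets", {
  conc <- test_against_random(angle_dataset("conc", rep(0, 41)))
  expect_equal(conc$D, 1)
  expect_lt(conc$p, 1e-12)
  big <- withr::with_seed(5, runif(1e4, 0, 90))
  null_res <- test_against_random(angle_dataset("null", big), method = "asymptotic")
  expect_gt(null_res$p, 0.01)
  one <- test_against_random(angle_dataset("one", 40))
  expect_true(one$D >= 0.5 && one$p >= 0 && one$p <= 1)
  # two-sample mode is seeded and reproducible
  a <- test_against_random(angle_dataset("g", big[1:31]), mode = "two_sample", seed = 11)
  b <- test_against_random(angle_dataset("g", big[1:31]), mode = "two_sample", seed = 11)
  expect_identical(a$D, b$D)
  expect_identical(a$p, b$p)
  expect_equal(a$mode, "two_sample")
  expect_equal(a$seed, 11)
})
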