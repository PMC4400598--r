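# Mann-Whitney / Hodges-Lehmann machinery and Fisher's exact test.

test_that("U statistic and exact p match hand-enumerated cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)                 # no (x, y) pair with y < x
  expect_equal(r$p, 2 / 20)            # two-sided: 2 * one-sided 1/20
  expect_equal(r$method, "exact")
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$hl_shift, 0)
  expect_equal(same$p, 1)
  hl <- mann_whitney(c(0, 0, 10), c(5, 5, 15))
  expect_equal(hl$hl_shift, 5)         # median of the 9 pairwise differences
  expect_error(mann_whitney(numeric(0), c(1, 2)), class = "gcorient_validation_error")
})

test_that("exact p equals full enumeration for every size pair up to 6x6", {
  withr::with_seed(123, {
    for (n1 in 2:6) {
      for (n2 in 2:6) {
        x <- rnorm(n1); y <- rnorm(n2)
        r <- mann_whitney(x, y)
        expect_equal(r$method, "exact")
        expect_equal(r$p, enumerate_mw_p(x, y), tolerance = 1e-12,
                     info = sprintf("n1=%d n2=%d", n1, n2))
      }
    }
  })
})

test_that("statistic and p agree with the reference implementation", {
  withr::with_seed(21, {
    # exact branch, no ties
    x <- rnorm(8); y <- rnorm(10)
    r <- mann_whitney(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE, conf.int = TRUE)
    expect_equal(r$U, unname(ref$statistic))
    expect_equal(r$p, ref$p.value, tolerance = 1e-12)
    expect_equal(r$hl_shift, -unname(ref$estimate), tolerance = 1e-9)
    # normal approximation with ties and continuity correction
    xt <- round(runif(25, 0, 90) / 5) * 5
    yt <- round(runif(30, 0, 90) / 5) * 5
    rt <- mann_whitney(xt, yt)
    reft <- suppressWarnings(stats::wilcox.test(xt, yt, exact = FALSE, correct = TRUE))
    expect_equal(rt$method, "normal_approximation")
    expect_equal(rt$U, unname(reft$statistic))
    expect_equal(rt$p, reft$p.value, tolerance = 1e-12)
  })
})

test_that("Hodges-Lehmann shift is translation-equivariant and inside its CI", {
  withr::with_seed(8, {
    x <- runif(15, 0, 90)
    y <- runif(12, 0, 90)
    r0 <- mann_whitney(x, y)
    for (c_shift in c(-12.5, 3, 40)) {
      rc <- mann_whitney(x, y + c_shift)
      expect_equal(rc$hl_shift, r0$hl_shift + c_shift, tolerance = 1e-12)
    }
    expect_lte(r0$ci_low, r0$hl_shift)
    expect_gte(r0$ci_high, r0$hl_shift)
  })
})

test_that("Hodges-Lehmann CI covers a planted shift at roughly the stated rate", {
  hits <- withr::with_seed(31, {
    vapply(1:200, function(i) {
      x <- rnorm(20); y <- rnorm(20) + 1
      r <- mann_whitney(x, y)
      r$ci_low <= 1 && 1 <= r$ci_high
    }, logical(1))
  })
  expect_gt(mean(hits), 0.88)  # nominal 0.95, distribution-free interval
})

test_that("Fisher's exact test matches enumeration and the reference", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(3, 3, 3, 3), 2, byrow = TRUE)), 1)
  expect_equal(fisher_exact_2x2(matrix(0, 2, 2)), 1)  # degenerate, documented
  expect_error(fisher_exact_2x2(c(1, -2, 3, 4)), class = "gcorient_validation_error")
  expect_error(fisher_exact_2x2(c(1, 2.5, 3, 4)), class = "gcorient_validation_error")
  withr::with_seed(4, {
    for (i in 1:10) {
      tab <- matrix(rpois(4, 6), 2, 2)
      expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                   tolerance = 1e-9)
    }
  })
})

test_that("fertility summaries report group means, SDs and Welch p-values", {
  rec <- data.frame(
    group = rep(c("ctrl", "mut"), each = 5),
    pair_id = paste0("p", 1:10),
    litters = c(6, 5, 6, 5, 6, 5, 5, 5, 5, 5),
    litter_size = c(7.2, 6.9, 7.0, 7.1, 6.8, 4.4, 4.7, 4.6, 4.5, 4.8)
  )
  s <- summarize_fertility(rec, control = "ctrl")
  expect_equal(s$mean_litter_size[s$group == "mut"], 4.6)
  expect_true(is.na(s$p_size_vs_control[s$group == "ctrl"]))
  ref <- t.test(rec$litter_size[6:10], rec$litter_size[1:5], var.equal = FALSE)
  expect_equal(s$p_size_vs_control[s$group == "mut"], ref$p.value)
  # identical groups: p = 1 within numerical tolerance
  rec2 <- rec; rec2$litters <- rep(c(5, 6, 5, 6, 5), 2); rec2$litter_size <- rep(c(7, 6, 7, 6, 7), 2)
  s2 <- summarize_fertility(rec2, control = "ctrl")
  expect_equal(s2$p_litters_vs_control[s2$group == "mut"], 1, tolerance = 1e-9)
  # planted separation at the scale of the fertility assay rejects
  expect_lt(s$p_size_vs_control[s$group == "mut"], 0.05)
  # single pair in a group: SD undefined
  expect_error(summarize_fertility(rec[c(1:5, 6), ], control = "ctrl"),
               class = "gcorient_validation_error")
})
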