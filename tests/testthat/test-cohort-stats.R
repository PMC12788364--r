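test_that("rmANOVA matches the aov error-strata reference", {
  set.seed(301)
  for (i in 1:5) {
    d <- random_rm_dataset(n = 8, effects = runif(1, 0, 2))
    mine <- rm_anova_3way(d, "y")
    ref <- aov_reference(d)
    expect_equal(mine$F, ref$F, tolerance = 1e-10)
    expect_equal(mine$p_uncorrected, ref$p, tolerance = 1e-10)
  }
})

test_that("two-level factor F equals the squared paired t statistic", {
  set.seed(302)
  d <- random_rm_dataset(n = 10)
  a <- rm_anova_3way(d, "y")
  m <- tapply(d$y, list(d$subject, d$surface), mean)
  tt <- t.test(m[, 1], m[, 2], paired = TRUE)
  row <- a[a$effect == "surface", ]
  expect_equal(row$F, unname(tt$statistic)^2)
  expect_equal(row$p_uncorrected, tt$p.value)
  expect_equal(row$gg_epsilon, 1)   # two levels are always spherical
  expect_equal(row$mauchly_p, 1)
})

test_that("the sum-of-squares partition is exhaustive", {
  set.seed(303)
  d <- random_rm_dataset(n = 6, effects = 1)
  a <- rm_anova_3way(d, "y")
  part <- attr(a, "ss_partition")
  ss_total <- sum((d$y - mean(d$y))^2)
  expect_equal(sum(part$ss), ss_total, tolerance = 1e-10)
})

test_that("rmANOVA rejects degenerate designs naming the offenders", {
  d <- random_rm_dataset(n = 5)
  expect_error(rm_anova_3way(d[-3, ], "y"), "S03")
  expect_error(rm_anova_3way(d[d$subject %in% c("S01", "S02"), ], "y"),
               "insufficient subjects")
  expect_error(rm_anova_3way(d, "nope"), "missing columns")
})

test_that("Greenhouse-Geisser epsilon has its closed-form limits", {
  expect_equal(greenhouse_geisser_epsilon(diag(3)), 1)
  # compound symmetry is spherical for any k
  S <- matrix(0.6, 4, 4); diag(S) <- 1
  expect_equal(greenhouse_geisser_epsilon(S), 1)
  # rank-1 covariance hits the lower bound 1/(k-1)
  v <- c(2, -1, 0.5)
  expect_equal(greenhouse_geisser_epsilon(outer(v, v)), 0.5)
  expect_error(greenhouse_geisser_epsilon(diag(1)), "2 levels")
})

test_that("Mauchly test agrees with the canonical implementations", {
  # frozen cross-validation fixture: values confirmed against
  # stats::mauchly.test and an independent Python implementation
  set.seed(123)
  n <- 12; k <- 4
  Sigma <- matrix(c(1, .6, .3, .1, .6, 1, .5, .2,
                    .3, .5, 1, .4, .1, .2, .4, 1), 4)
  D <- matrix(rnorm(n * k), n, k) %*% chol(Sigma)
  D <- sweep(D, 2, c(0, .3, .5, .2), "+")
  ms <- mauchly_sphericity(D)
  expect_equal(ms$W, 0.5584187191686166, tolerance = 1e-12)
  expect_equal(ms$p, 0.3423873151316588, tolerance = 1e-10)
  expect_equal(ms$gg_epsilon, 0.7349610613728202, tolerance = 1e-12)
  ref <- stats::mauchly.test(lm(D ~ 1), X = ~1)
  expect_equal(ms$W, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ms$p, ref$p.value, tolerance = 1e-10)
  # two-level degeneracy
  d2 <- mauchly_sphericity(D[, 1:2])
  expect_equal(d2$W, 1)
  expect_equal(d2$p, 1)
})

test_that("Mauchly test rejects strongly non-spherical data", {
  set.seed(304)
  rej <- mean(replicate(100, {
    base <- rnorm(10, sd = 3)
    D <- cbind(base + rnorm(10, sd = 0.1), base + rnorm(10, sd = 0.1),
               rnorm(10, sd = 3))
    mauchly_sphericity(D)$p < 0.05
  }))
  expect_gt(rej, 0.8)
})

test_that("Shapiro-Wilk wrapper handles regular and degenerate input", {
  set.seed(305)
  r <- shapiro_wilk(rnorm(50))
  expect_true(r$W > 0 && r$W <= 1)
  expect_error(shapiro_wilk(rep(3, 10)), "identical")
  rej <- mean(replicate(200, shapiro_wilk(rexp(50))$p < 0.05))
  expect_gt(rej, 0.9)
})

test_that("Bonferroni adjustment scales, caps and preserves order", {
  expect_equal(bonferroni_adjust(0.01, 6), 0.06)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  p <- c(0.001, 0.02, 0.2)
  expect_equal(bonferroni_adjust(p, 1), p)
  expect_true(all(diff(bonferroni_adjust(p, 4)) >= 0))
  expect_true(all(bonferroni_adjust(p, 4) >= p))
})

test_that("paired Cohen's d follows the d_z convention with Cohen bands", {
  x <- c(1, 2, 3, 4)
  expect_equal(cohens_d_paired(x, x), list(d = 0, d_av = 0,
                                           rating = "negligible"))
  r <- cohens_d_paired(c(2, 4, 6), c(1, 2, 3))  # diffs 1, 2, 3
  expect_equal(r$d, 2)
  expect_equal(r$rating, "large")
  expect_error(cohens_d_paired(x + 1, x), "zero-variance")
  expect_error(cohens_d_paired(1:3, 1:4), "paired")
})

test_that("effect-size rating bands sit exactly at Cohen's boundaries", {
  # pairs whose differences have sample mean d and SD exactly 1 give d_z = d
  set.seed(306)
  base <- as.numeric(scale(rnorm(50)))
  expect_equal(cohens_d_paired(base + 0.79, rep(0, 50))$d, 0.79)
  expect_equal(cohens_d_paired(base + 0.79, rep(0, 50))$rating, "medium")
  expect_equal(cohens_d_paired(base + 0.80, rep(0, 50))$rating, "large")
  # partial eta squared bands
  expect_equal(partial_eta_squared(0, 5), list(value = 0, rating = "negligible"))
  expect_equal(partial_eta_squared(5, 0), list(value = 1, rating = "large"))
  expect_equal(partial_eta_squared(3, 7), list(value = 0.3, rating = "large"))
  expect_equal(partial_eta_squared(0.05, 0.95)$rating, "small")
  expect_equal(partial_eta_squared(0.13, 0.87)$rating, "medium")
  expect_error(partial_eta_squared(-1, 2), "non-negative")
})

test_that("condition slopes reproduce the reporting convention", {
  expect_equal(round(condition_slopes(c(160, 166, 172), c(9.4, 12.7, 14.9)), 1),
               2.2)
  expect_equal(condition_slopes(c(5, 5, 5), 1:3), 0)
  expect_equal(condition_slopes(c(0, 5), c(0, 1)), 5)
  expect_error(condition_slopes(5, 1), "2 \\(covariate")
  expect_error(condition_slopes(c(1, 2), c(3, 3)), "constant")
})

test_that("post hoc comparisons are Bonferroni-corrected per family", {
  set.seed(307)
  d <- random_rm_dataset(n = 9, effects = 2)
  ph <- posthoc_pairwise(d, "y", "speed_level")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_bonferroni, pmin(1, 3 * ph$p_raw))
  expect_true(all(ph$ci_lower <= ph$mean_diff & ph$mean_diff <= ph$ci_upper))
  # conditioning on another factor multiplies families, not comparisons
  ph_by <- posthoc_pairwise(d, "y", "speed_level", by = "surface")
  expect_equal(nrow(ph_by), 6)
  expect_equal(sort(unique(ph_by$family)), c("ROAD", "TRAIL"))
})

test_that("null post hoc family-wise error stays at or below nominal", {
  set.seed(308)
  fwer <- mean(replicate(300, {
    d <- random_rm_dataset(n = 8)
    any(posthoc_pairwise(d, "y", "speed_level")$p_bonferroni < 0.05)
  }))
  expect_lt(fwer, 0.05 + 2 * sqrt(0.05 * 0.95 / 300))
})
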