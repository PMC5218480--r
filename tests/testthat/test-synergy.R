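test_that("combination index follows the Dx arithmetic at single points", {
  f1 <- fit_from_truth(1, 1)
  f2 <- fit_from_truth(1, 2)
  # fa = 0.5: Dx = (1, 2), so (0.5, 1.0) is exactly additive
  res <- combination_index_at_point(f1, f2, 0.5, 1.0, 0.5)
  expect_equal(res$ci, 1.0)
  expect_equal(c(res$dx_1, res$dx_2), c(1, 2))
  # fa = 2/3: Dx = (2, 4), same doses give CI = 0.5
  res <- combination_index_at_point(f1, f2, 0.5, 1.0, 2 / 3)
  expect_equal(res$ci, 0.5)
  # monotherapy limit: dose_2 = 0 reduces to d1 / Dx1
  res <- combination_index_at_point(f1, f2, 0.5, 0, 0.5)
  expect_equal(res$ci, 0.5)
  expect_error(combination_index_at_point(f1, f2, 0, 0, 0.5),
               "not both zero")
  expect_error(combination_index_at_point(f1, f2, 1, 1, 1), "strictly inside")
})

test_that("a flagged monotherapy fit makes the point unevaluable", {
  f1 <- fit_from_truth(1, 1)
  bad <- fit_from_truth(-0.5, 1)
  bad$flags <- "non_monotone"
  res <- combination_index_at_point(f1, bad, 0.5, 1.0, 0.5)
  expect_false(res$evaluable)
  expect_true(is.na(res$ci))
  # the flagged drug at zero dose is irrelevant
  res <- combination_index_at_point(f1, bad, 0.5, 0, 0.5)
  expect_true(res$evaluable)
})

test_that("Loewe-additive constructions yield CI = c for any budget c", {
  set.seed(11)
  for (i in 1:20) {
    m1 <- runif(1, 0.5, 3); Dm1 <- 10^runif(1, -1, 1)
    m2 <- runif(1, 0.5, 3); Dm2 <- 10^runif(1, -1, 1)
    ci_true <- runif(1, 0.2, 2.5)
    fa <- runif(1, 0.05, 0.95)
    share <- runif(1, 0.05, 0.95)
    pt <- loewe_point(m1, Dm1, m2, Dm2, fa, ci_true, share)
    res <- combination_index_at_point(fit_from_truth(m1, Dm1),
                                      fit_from_truth(m2, Dm2),
                                      pt$dose_1, pt$dose_2, fa)
    expect_equal(res$ci, ci_true, tolerance = 1e-9)
  }
})

test_that("CI is scale-invariant, symmetric, and decreasing in observed effect", {
  f1 <- fit_from_truth(1.4, 0.9)
  f2 <- fit_from_truth(2.1, 1.7)
  base <- combination_index_at_point(f1, f2, 0.6, 1.1, 0.55)
  # rescale all of drug 1's doses (data and fit) by k
  k <- 7.3
  f1k <- fit_from_truth(1.4, 0.9 * k)
  scaled <- combination_index_at_point(f1k, f2, 0.6 * k, 1.1, 0.55)
  expect_equal(scaled$ci, base$ci, tolerance = 1e-12)
  # swap drug labels
  swapped <- combination_index_at_point(f2, f1, 1.1, 0.6, 0.55)
  expect_equal(swapped$ci, base$ci, tolerance = 1e-12)
  # stronger observed effect at fixed doses lowers CI
  fa_grid <- seq(0.2, 0.9, by = 0.1)
  cis <- vapply(fa_grid, function(f) {
    combination_index_at_point(f1, f2, 0.6, 1.1, f)$ci
  }, numeric(1))
  expect_true(all(diff(cis) < 0))
})

test_that("constant-ratio profile is additive for an additivity-built series", {
  cb <- simulate_combination(1.3, 1.8, 1.7, 0.9, true_ci = 1,
                             design = "constant_ratio", cv = 0, seed = 1)
  one <- cb[cb$replicate == 1, ]
  pr <- constant_ratio_ci_profile(fit_from_truth(1.3, 1.8),
                                  fit_from_truth(1.7, 0.9),
                                  one$dose_1, one$dose_2, one$fa_true)
  expect_equal(pr$per_point$ci, rep(1, nrow(one)), tolerance = 1e-6)
  # interpolated ED50/75/90 CIs are near 1 (exact only when m1 = m2)
  expect_equal(pr$at_levels$ci, rep(1, 3), tolerance = 0.05)
  # with identical drug shapes the whole profile is exact
  cb2 <- simulate_combination(1.5, 2, 1.5, 0.5, true_ci = 1,
                              design = "constant_ratio", cv = 0, seed = 1)
  one2 <- cb2[cb2$replicate == 1, ]
  pr2 <- constant_ratio_ci_profile(fit_from_truth(1.5, 2),
                                   fit_from_truth(1.5, 0.5),
                                   one2$dose_1, one2$dose_2, one2$fa_true)
  expect_equal(pr2$at_levels$ci, rep(1, 3), tolerance = 1e-6)
  expect_equal(pr2$summary_ci, 1, tolerance = 1e-6)
})

test_that("a self-combination (dose_2 = 0 throughout) has CI profile 1", {
  f1 <- fit_from_truth(1.5, 2)
  doses <- 2 * 2^seq(-2, 2)
  fa <- predict_effect(f1, doses)
  pr <- constant_ratio_ci_profile(f1, f1, doses, rep(0, 5), fa)
  expect_equal(pr$per_point$ci, rep(1, 5), tolerance = 1e-9)
  expect_equal(pr$at_levels$ci, rep(1, 3), tolerance = 1e-9)
})

test_that("mixed dose ratios are rejected as a design error", {
  f1 <- fit_from_truth(1, 1); f2 <- fit_from_truth(1, 1)
  expect_error(
    constant_ratio_ci_profile(f1, f2, c(1, 2, 3), c(1, 2, 2),
                              c(0.4, 0.5, 0.6)),
    "design error")
})

test_that("constant-ratio true CI is recovered within 0.02 under noise", {
  est <- numeric(100)
  for (s in 1:100) {
    cb <- simulate_combination(1.3, 1.8, 1.7, 0.9, true_ci = 0.5,
                               design = "constant_ratio", cv = 0.05,
                               n_replicates = 4, seed = s)
    # average replicates per pair, as the pipeline does
    key <- paste(cb$dose_1, cb$dose_2)
    agg <- do.call(rbind, lapply(split(cb, key), function(g) {
      data.frame(dose_1 = g$dose_1[1], dose_2 = g$dose_2[1],
                 fa = min(max(1 - mean(g$response), 0.005), 0.995))
    }))
    pr <- constant_ratio_ci_profile(fit_from_truth(1.3, 1.8),
                                    fit_from_truth(1.7, 0.9),
                                    agg$dose_1, agg$dose_2, agg$fa)
    est[s] <- mean(pr$per_point$ci)
  }
  expect_lt(abs(mean(est) - 0.5), 0.02)
})

test_that("checkerboard summary takes the median over evaluable points", {
  f1 <- fit_from_truth(1, 1); f2 <- fit_from_truth(1, 2)
  # eight points engineered to CIs 0.2 .. 0.9
  cis <- seq(0.2, 0.9, by = 0.1)
  pts <- do.call(rbind, lapply(cis, function(ci) {
    p <- loewe_point(1, 1, 1, 2, 0.5, ci)
    data.frame(dose_1 = p$dose_1, dose_2 = p$dose_2, fa = 0.5)
  }))
  s <- checkerboard_ci(f1, f2, pts, "s1")
  expect_equal(s$median_ci, 0.55, tolerance = 1e-9)
  expect_equal(s$n_valid, 8L)
  # all-additive board
  pts1 <- do.call(rbind, lapply(seq(0.2, 0.8, 0.1), function(fa) {
    p <- loewe_point(1, 1, 1, 2, fa, 1)
    data.frame(dose_1 = p$dose_1, dose_2 = p$dose_2, fa = fa)
  }))
  expect_equal(checkerboard_ci(f1, f2, pts1)$median_ci, 1, tolerance = 1e-9)
  # unevaluable points (fa at NA) are dropped from the median
  pts$fa[4:8] <- NA
  pts$fa[1:3] <- 0.5
  s2 <- suppressWarnings(checkerboard_ci(f1, f2, pts))
  expect_equal(s2$n_valid, 3L)
  expect_equal(s2$median_ci, median(cis[1:3] / 1), tolerance = 1e-9)
})

test_that("cohort synergy fraction uses a strict CI < 1 rule", {
  expect_equal(cohort_synergy_fraction(c(rep(0.8, 22), rep(1.2, 8)))$fraction,
               22 / 30)
  expect_equal(cohort_synergy_fraction(rep(1, 5))$fraction, 0)
  expect_equal(cohort_synergy_fraction(c(0.2, 0.9))$fraction, 1)
  expect_error(cohort_synergy_fraction(c(NA, NA)), "no evaluable")
})
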