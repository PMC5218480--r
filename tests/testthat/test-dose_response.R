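test_that("fraction-affected normalisation clips and flags boundary cases", {
  # vehicle-equal signal (zero effect) clips up to epsilon
  r <- suppressMessages(normalize_to_fraction_affected(100, 100, 0.001))
  expect_equal(r$fa, 0.001)
  expect_true(r$clipped)
  # half-signal is fa = 0.5, untouched
  r <- normalize_to_fraction_affected(50, 100, 0.001)
  expect_equal(r$fa, 0.5)
  expect_false(r$clipped)
  expect_equal(r$fa + r$fu, 1)
  # growth stimulation clips to epsilon with the flag set
  r <- suppressMessages(normalize_to_fraction_affected(120, 100, 0.005))
  expect_equal(r$fa, 0.005)
  expect_true(r$clipped)
  # full kill clips below 1
  r <- suppressMessages(normalize_to_fraction_affected(0, 100, 0.005))
  expect_equal(r$fa, 0.995)
  expect_error(normalize_to_fraction_affected(1, 0), "invalid control")
  expect_error(normalize_to_fraction_affected(1, 1, 0.2), "epsilon")
})

test_that("median-effect fit recovers exact log-linear data", {
  cases <- list(c(m = 2, Dm = 1), c(m = 1, Dm = 2), c(m = 0.5, Dm = 0.05),
                c(m = 4, Dm = 80))
  for (p in cases) {
    doses <- p[["Dm"]] * 2^seq(-2, 2)
    fa <- 1 / (1 + (p[["Dm"]] / doses)^p[["m"]])
    fit <- fit_median_effect(doses, fa)
    expect_equal(fit$m, p[["m"]], tolerance = 1e-9)
    expect_equal(fit$Dm, p[["Dm"]], tolerance = 1e-9)
    expect_equal(fit$r, 1, tolerance = 1e-9)
  }
})

test_that("median-effect fit validates input and flags non-monotone data", {
  expect_error(fit_median_effect(c(1, 1, 1), c(0.2, 0.4, 0.6)),
               "degenerate")
  expect_error(fit_median_effect(c(1, 2), c(0, 0.5)), "strictly inside")
  w <- capture_warnings(fit <- fit_median_effect(c(1, 2, 4), c(0.8, 0.5, 0.2)))
  expect_match(w, "non-monotone", all = FALSE)
  expect_true("non_monotone" %in% fit$flags)
})

test_that("replicates are averaged per dose by default", {
  doses <- c(1, 1, 2, 2, 4, 4)
  fa <- c(0.45, 0.55, 0.62, 0.70, 0.78, 0.82)
  fit_avg <- fit_median_effect(doses, fa)
  fa_mean <- tapply(fa, doses, mean)
  fit_ref <- fit_median_effect(as.numeric(names(fa_mean)), as.numeric(fa_mean))
  expect_equal(fit_avg$m, fit_ref$m)
  expect_equal(fit_avg$n_points, 3L)
  fit_all <- fit_median_effect(doses, fa, average_replicates = FALSE)
  expect_equal(fit_all$n_points, 6L)
})

test_that("dose_for_effect and predict_effect are exact mutual inverses", {
  fit <- fit_from_truth(1, 2)
  expect_equal(dose_for_effect(fit, 0.5), 2)
  expect_equal(dose_for_effect(fit, 0.9), 18)
  expect_equal(predict_effect(fit, 18), 0.9)
  expect_equal(predict_effect(fit_from_truth(3.3, 1), 1), 0.5)
  expect_equal(dose_for_effect(fit_from_truth(2, 1), 0.8), 2)
  # round trip over a grid, for several parameterisations
  set.seed(4)
  for (i in 1:10) {
    fit <- fit_from_truth(runif(1, 0.5, 4), 10^runif(1, -2, 2))
    fa <- seq(0.02, 0.98, by = 0.04)
    expect_equal(predict_effect(fit, dose_for_effect(fit, fa)), fa,
                 tolerance = 1e-12)
    d <- fit$Dm * 2^seq(-4, 4, by = 0.5)
    expect_equal(dose_for_effect(fit, predict_effect(fit, d)), d,
                 tolerance = 1e-9)
    expect_true(all(diff(predict_effect(fit, d)) > 0))
  }
  expect_error(dose_for_effect(fit, 1), "strictly inside")
  expect_error(predict_effect(fit, -1), "strictly positive")
})

test_that("median-effect parameters are recovered within 5% under 5% CV noise", {
  m_true <- 1.5; Dm_true <- 0.8
  doses <- Dm_true * 2^seq(-3, 3)
  m_hat <- Dm_hat <- numeric(100)
  for (s in 1:100) {
    tab <- simulate_dose_response(m_true, Dm_true, doses, n_replicates = 1,
                                  cv = 0.05, seed = s)
    fa <- suppressMessages(
      normalize_to_fraction_affected(tab$response, 1, 0.005)$fa)
    fit <- fit_median_effect(tab$dose_uM, fa)
    m_hat[s] <- fit$m; Dm_hat[s] <- fit$Dm
  }
  expect_lt(abs(mean(m_hat) / m_true - 1), 0.05)
  expect_lt(abs(mean(Dm_hat) / Dm_true - 1), 0.05)
})

test_that("4PL fit recovers exact logistic data and matches Dm when shapes agree", {
  doses <- 10^seq(-1.5, 1.5, length.out = 9)
  resp <- 0 + (1 - 0) / (1 + (doses / 1.5)^1)
  fit <- fit_logistic_ic50(doses, resp)
  expect_equal(fit$ic50, 1.5, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  # with top = 1, bottom = 0 and hill = m, the 4PL ic50 equals the
  # median-effect Dm
  m <- 2.2; Dm <- 0.7
  resp2 <- 1 - 1 / (1 + (Dm / doses)^m)
  fit2 <- fit_logistic_ic50(doses, resp2)
  me <- fit_median_effect(doses, 1 - resp2)
  expect_equal(fit2$ic50, me$Dm, tolerance = 1e-6)
  expect_error(fit_logistic_ic50(doses, rep(0.5, 9)), "fit failure")
  expect_error(fit_logistic_ic50(1:3, c(1, 0.5, 0)), ">= 4 points")
})

test_that("4PL ic50 is recovered within 10% (median over noisy simulations)", {
  doses <- 10^seq(-1, 1.5, length.out = 9)
  ic <- numeric(100)
  for (s in 1:100) {
    set.seed(1000 + s)
    resp <- 1 / (1 + (doses / 1.5)^1.2) * (1 + rnorm(9, 0, 0.05))
    ic[s] <- fit_logistic_ic50(doses, resp)$ic50
  }
  expect_lt(abs(median(ic) / 1.5 - 1), 0.1)
})

test_that("fit_dose_response_table fits every sample x drug series", {
  tab <- rbind(
    data.frame(sample_id = "s1", drug = "aza",
               dose_uM = 2 * 2^seq(-2, 2), replicate = 1,
               response = 1 - 1 / (1 + (2 / (2 * 2^seq(-2, 2)))^1.4)),
    data.frame(sample_id = "s1", drug = "hdaci",
               dose_uM = 2^seq(-2, 2), replicate = 1,
               response = 1 - 1 / (1 + (1 / 2^seq(-2, 2))^2))
  )
  res <- fit_dose_response_table(tab)
  expect_equal(nrow(res), 2L)
  expect_equal(res$Dm[res$drug == "aza"], 2, tolerance = 1e-6)
  expect_equal(res$m[res$drug == "hdaci"], 2, tolerance = 1e-6)
  expect_error(fit_dose_response_table(tab[, -2]), "missing columns")
})
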