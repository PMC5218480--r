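#' Combination index at a single dose pair
#'
#' Chou-Talalay combination index under Loewe additivity:
#' `CI = d1/Dx1 + d2/Dx2`, where `Dx_j` is the dose of drug j alone that
#' produces the observed effect level. `CI < 1` indicates synergism,
#' `CI = 1` additivity and `CI > 1` antagonism. A zero dose for one drug
#' reduces CI to the monotherapy ratio for the other.
#'
#' @param fit_1,fit_2 monotherapy [fit_median_effect()] results for the two
#'   drugs.
#' @param dose_1,dose_2 doses of the two drugs in the combination (uM,
#'   non-negative, not both zero).
#' @param fa_observed fraction affected observed at the dose pair, in (0, 1).
#' @return list of class `ci_result` with `ci`, `fa_at`, `dose_1`, `dose_2`,
#'   `dx_1`, `dx_2`, and logical `evaluable` (FALSE, with `ci = NA`, when a
#'   needed monotherapy fit is flagged non-monotone).
#' @export
combination_index_at_point <- function(fit_1, fit_2, dose_1, dose_2,
                                       fa_observed) {
  stopifnot(is_median_effect_fit(fit_1), is_median_effect_fit(fit_2))
  if (dose_1 < 0 || dose_2 < 0 || (dose_1 == 0 && dose_2 == 0)) {
    stop("doses must be non-negative and not both zero", call. = FALSE)
  }
  if (!is.finite(fa_observed) || fa_observed <= 0 || fa_observed >= 1) {
    stop("`fa_observed` must lie strictly inside (0, 1)", call. = FALSE)
  }
  need_1 <- dose_1 > 0
  need_2 <- dose_2 > 0
  bad <- (need_1 && "non_monotone" %in% fit_1$flags) ||
    (need_2 && "non_monotone" %in% fit_2$flags)
  dx_1 <- if (need_1) dose_for_effect(fit_1, fa_observed) else NA_real_
  dx_2 <- if (need_2) dose_for_effect(fit_2, fa_observed) else NA_real_
  ci <- if (bad) {
    NA_real_
  } else {
    (if (need_1) dose_1 / dx_1 else 0) + (if (need_2) dose_2 / dx_2 else 0)
  }
  structure(
    list(ci = ci, fa_at = fa_observed, dose_1 = dose_1, dose_2 = dose_2,
         dx_1 = dx_1, dx_2 = dx_2, evaluable = !bad),
    class = "ci_result"
  )
}

#' CI profile for a constant-ratio combination design
#'
#' For a combination series dosed at a fixed drug-1 : drug-2 ratio
#' (typically around IC50:IC50), fits the median-effect model to the
#' combination itself (total dose vs fraction affected), then reports the CI
#' two ways: per combination point at its observed effect, and at requested
#' effect levels (default ED50/75/90) using the combination fit to find the
#' total dose achieving each level. The summary CI is the mean over the
#' requested levels.
#'
#' @inheritParams combination_index_at_point
#' @param dose_1,dose_2 numeric vectors of the combination doses; all pairs
#'   must share `dose_1/dose_2` to within `ratio_tol` (relative).
#' @param fa_observed observed fraction affected for each pair, in (0, 1).
#' @param fa_levels effect levels for the profile; default `c(0.5, 0.75, 0.9)`.
#' @param ratio_tol relative tolerance on the dose ratio. Default 0.01.
#' @return list with `per_point` (data.frame of per-point CIs), `at_levels`
#'   (data.frame of CIs at `fa_levels`), `summary_ci` (mean over levels),
#'   `combo_fit` (the combination median-effect fit) and `ratio`.
#' @export
constant_ratio_ci_profile <- function(fit_1, fit_2, dose_1, dose_2,
                                      fa_observed,
                                      fa_levels = c(0.5, 0.75, 0.9),
                                      ratio_tol = 0.01) {
  stopifnot(length(dose_1) == length(dose_2),
            length(dose_1) == length(fa_observed))
  if (all(dose_2 == 0)) {
    ratio <- Inf
  } else if (all(dose_1 == 0)) {
    ratio <- 0
  } else {
    rr <- dose_1 / dose_2
    ratio <- stats::median(rr)
    if (any(abs(rr / ratio - 1) > ratio_tol)) {
      stop("design error: combination points do not share a constant ",
           "dose ratio (tolerance ", ratio_tol, ")", call. = FALSE)
    }
  }
  total <- dose_1 + dose_2
  combo_fit <- fit_median_effect(total, fa_observed)

  per_point <- do.call(rbind, lapply(seq_along(total), function(i) {
    res <- combination_index_at_point(fit_1, fit_2, dose_1[i], dose_2[i],
                                      fa_observed[i])
    data.frame(dose_1 = dose_1[i], dose_2 = dose_2[i],
               fa = fa_observed[i], ci = res$ci, evaluable = res$evaluable)
  }))

  # split each iso-effective total dose back into the two agents by ratio
  w1 <- if (is.infinite(ratio)) 1 else ratio / (1 + ratio)
  w2 <- 1 - w1
  at_levels <- do.call(rbind, lapply(fa_levels, function(f) {
    d_tot <- dose_for_effect(combo_fit, f)
    res <- combination_index_at_point(fit_1, fit_2, d_tot * w1, d_tot * w2, f)
    data.frame(fa_level = f, total_dose = d_tot,
               dose_1 = d_tot * w1, dose_2 = d_tot * w2,
               ci = res$ci, evaluable = res$evaluable)
  }))

  list(per_point = per_point, at_levels = at_levels,
       summary_ci = mean(at_levels$ci[at_levels$evaluable]),
       combo_fit = combo_fit, ratio = ratio)
}

#' Checkerboard (fixed dose-pair) synergy summary for one sample
#'
#' Computes a per-point CI at each dose pair's observed effect and summarises
#' the sample by the median CI over the evaluable points, the statistic used
#' for patient-sample combination matrices.
#'
#' @inheritParams combination_index_at_point
#' @param points data.frame with columns `dose_1`, `dose_2`, `fa`.
#' @param sample_id label for the sample.
#' @return list of class `sample_synergy_summary` with `sample_id`,
#'   `ci_table` (per-point results), `median_ci` (NA and `evaluable = FALSE`
#'   when no point yields a valid CI), `n_valid`.
#' @export
checkerboard_ci <- function(fit_1, fit_2, points, sample_id = NA_character_) {
  stopifnot(all(c("dose_1", "dose_2", "fa") %in% names(points)),
            nrow(points) >= 1L)
  ci_table <- do.call(rbind, lapply(seq_len(nrow(points)), function(i) {
    res <- tryCatch(
      combination_index_at_point(fit_1, fit_2, points$dose_1[i],
                                 points$dose_2[i], points$fa[i]),
      error = function(e) list(ci = NA_real_, evaluable = FALSE)
    )
    data.frame(dose_1 = points$dose_1[i], dose_2 = points$dose_2[i],
               fa = points$fa[i], ci = res$ci,
               evaluable = isTRUE(res$evaluable) && is.finite(res$ci))
  }))
  valid <- ci_table$ci[ci_table$evaluable]
  structure(
    list(sample_id = sample_id, ci_table = ci_table,
         median_ci = if (length(valid)) stats::median(valid) else NA_real_,
         n_valid = length(valid), evaluable = length(valid) > 0L),
    class = "sample_synergy_summary"
  )
}

#' @export
print.sample_synergy_summary <- function(x, ...) {
  cat("Sample", x$sample_id, ": median CI =", signif(x$median_ci, 4),
      "over", x$n_valid, "valid points\n")
  invisible(x)
}

#' Cohort fraction of synergistic samples
#'
#' Counts samples whose median combination index is strictly below 1
#' (synergism) and reports the fraction of the evaluable cohort.
#'
#' @param median_cis numeric vector of per-sample median CIs, or a list of
#'   [checkerboard_ci()] summaries. NA entries (unevaluable samples) are
#'   dropped.
#' @return list with `n` (evaluable samples), `n_synergistic`, `fraction`.
#' @export
cohort_synergy_fraction <- function(median_cis) {
  if (is.list(median_cis) && !is.data.frame(median_cis)) {
    median_cis <- vapply(median_cis, function(s) s$median_ci, numeric(1))
  }
  median_cis <- median_cis[is.finite(median_cis)]
  if (!length(median_cis)) {
    stop("no evaluable samples", call. = FALSE)
  }
  n_syn <- sum(median_cis < 1)
  list(n = length(median_cis), n_synergistic = n_syn,
       fraction = n_syn / length(median_cis))
}
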