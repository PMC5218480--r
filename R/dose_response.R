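#' Convert raw viability signal to fraction affected
#'
#' Normalises a raw viability readout (luminescence or live-cell count) to the
#' fraction of cells affected by treatment, `fa = 1 - raw / vehicle_mean`.
#' Because the median-effect plot works on `log(fa / (1 - fa))`, values at or
#' beyond the \{0, 1\} boundaries are clipped into `[epsilon, 1 - epsilon]`
#' and flagged; growth stimulation (raw signal above the vehicle mean) clips
#' to `epsilon`.
#'
#' @param raw_signal numeric vector of raw viability signals (same units as
#'   `vehicle_mean`).
#' @param vehicle_mean positive scalar, mean signal of the vehicle control.
#' @param epsilon clipping bound, in `(0, 0.05]`. Default 0.005.
#' @return data.frame with columns `fa`, `fu` (`= 1 - fa`) and logical
#'   `clipped`.
#' @examples
#' normalize_to_fraction_affected(c(100, 50, 10), vehicle_mean = 100)
#' @export
normalize_to_fraction_affected <- function(raw_signal, vehicle_mean,
                                           epsilon = 0.005) {
  if (!is.numeric(vehicle_mean) || length(vehicle_mean) != 1L ||
      !is.finite(vehicle_mean) || vehicle_mean <= 0) {
    stop("invalid control: `vehicle_mean` must be a positive finite scalar",
         call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon > 0.05) {
    stop("`epsilon` must be in (0, 0.05]", call. = FALSE)
  }
  fa_raw <- 1 - raw_signal / vehicle_mean
  fa <- pmin(pmax(fa_raw, epsilon), 1 - epsilon)
  clipped <- fa != fa_raw
  if (any(clipped)) {
    message(sum(clipped), " fraction-affected value(s) clipped to [",
            epsilon, ", ", 1 - epsilon, "]")
  }
  data.frame(fa = fa, fu = 1 - fa, clipped = clipped)
}

#' Fit the median-effect (Chou-Talalay) model
#'
#' Fits `log10(fa/fu) = m * log10(D) - m * log10(Dm)` by ordinary least
#' squares on the median-effect plot. `m` is the sigmoidicity (slope) and
#' `Dm` the median-effect dose, i.e. the dose producing `fa = 0.5`.
#'
#' @param dose numeric vector of doses (uM), strictly positive.
#' @param fa fraction affected at each dose, strictly inside (0, 1).
#' @param average_replicates if `TRUE` (default), observations sharing a dose
#'   are averaged (on the fa scale) before the regression; set `FALSE` to fit
#'   all points individually.
#' @return object of class `median_effect_fit`: list with `m`, `Dm`, `r`
#'   (linear correlation of the median-effect plot), `n_points`, and a
#'   character vector `flags` (contains `"non_monotone"` when the fitted
#'   slope is not positive).
#' @examples
#' d <- c(0.25, 0.5, 1, 2, 4)
#' fa <- 1 / (1 + (1 / d)^2)   # m = 2, Dm = 1
#' fit_median_effect(d, fa)
#' @export
fit_median_effect <- function(dose, fa, average_replicates = TRUE) {
  stopifnot(length(dose) == length(fa))
  ok <- is.finite(dose) & is.finite(fa)
  dose <- dose[ok]; fa <- fa[ok]
  if (any(dose <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (any(fa <= 0 | fa >= 1)) {
    stop("fraction affected must lie strictly inside (0, 1); ",
         "clip with normalize_to_fraction_affected() first", call. = FALSE)
  }
  if (average_replicates && anyDuplicated(dose)) {
    fa <- as.numeric(tapply(fa, dose, mean))
    dose <- sort(unique(dose))
  }
  if (length(unique(dose)) < 2L) {
    stop("degenerate design: need >= 2 distinct doses", call. = FALSE)
  }
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  fit <- stats::lm.fit(cbind(1, x), y)
  m <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  r <- if (stats::sd(y) == 0) {
    # flat response: correlation undefined, report 0
    0
  } else {
    stats::cor(x, y)
  }
  flags <- character()
  if (m <= 0) {
    flags <- "non_monotone"
    warning("fitted median-effect slope m <= 0; fit flagged non-monotone",
            call. = FALSE)
  }
  Dm <- 10^(-intercept / m)
  structure(
    list(m = m, Dm = Dm, r = r, n_points = length(dose), flags = flags),
    class = "median_effect_fit"
  )
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat("Median-effect fit: m =", signif(x$m, 4),
      " Dm =", signif(x$Dm, 4), "uM  r =", signif(x$r, 4),
      " (n =", x$n_points, ")\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

is_median_effect_fit <- function(x) inherits(x, "median_effect_fit")

#' Dose producing a given effect level
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa / (1 - fa))^(1/m)`,
#' the dose of the single agent that alone produces fraction affected `fa`.
#' `dose_for_effect(fit, 0.5)` equals `Dm` exactly.
#'
#' @param fit a [fit_median_effect()] result (or any list with `m`, `Dm`).
#' @param fa effect level(s), strictly inside (0, 1).
#' @return dose(s) in the same units as `Dm`.
#' @export
dose_for_effect <- function(fit, fa) {
  if (any(!is.finite(fa) | fa <= 0 | fa >= 1)) {
    stop("`fa` must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit$Dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Effect produced by a given dose
#'
#' Median-effect equation: `fa = 1 / (1 + (Dm / D)^m)`. Exact inverse of
#' [dose_for_effect()]; `predict_effect(fit, Dm)` is 0.5.
#'
#' @inheritParams dose_for_effect
#' @param dose dose(s), strictly positive.
#' @return fraction affected in (0, 1).
#' @export
predict_effect <- function(fit, dose) {
  if (any(!is.finite(dose) | dose <= 0)) {
    stop("`dose` must be strictly positive", call. = FALSE)
  }
  1 / (1 + (fit$Dm / dose)^fit$m)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Nonlinear least squares of
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)`,
#' the Prism-style 4PL used for monotherapy IC50s. For viability data
#' response falls with dose, so `hill > 0` in this parameterisation.
#'
#' @param dose doses (uM), strictly positive; at least 4 points.
#' @param response observed response fraction relative to vehicle.
#' @return object of class `logistic_fit`: list with `ic50`, `hill`, `top`,
#'   `bottom`, and `rss`.
#' @export
fit_logistic_ic50 <- function(dose, response) {
  stopifnot(length(dose) == length(response))
  if (length(dose) < 4L) stop("need >= 4 points for a 4PL fit", call. = FALSE)
  if (any(dose <= 0)) stop("doses must be strictly positive", call. = FALSE)
  if (stats::sd(response) == 0) {
    stop("fit failure: constant response, 4PL parameters unidentifiable",
         call. = FALSE)
  }
  top0 <- max(response); bot0 <- min(response)
  mid <- (top0 + bot0) / 2
  # starting ic50: dose whose response is closest to the midpoint
  ic0 <- dose[which.min(abs(response - mid))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ bottom + (top - bottom) / (1 + (dose / ic50)^hill),
      start = list(top = top0, bottom = bot0, ic50 = ic0, hill = 1),
      lower = c(top = -Inf, bottom = -Inf, ic50 = 1e-12, hill = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) {
      stop("fit failure: 4PL did not converge (", conditionMessage(e), ")",
           call. = FALSE)
    }
  )
  cf <- stats::coef(fit)
  structure(
    list(ic50 = unname(cf["ic50"]), hill = unname(cf["hill"]),
         top = unname(cf["top"]), bottom = unname(cf["bottom"]),
         rss = sum(stats::resid(fit)^2)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("4PL fit: ic50 =", signif(x$ic50, 4), "uM  hill =", signif(x$hill, 4),
      " top =", signif(x$top, 4), " bottom =", signif(x$bottom, 4), "\n")
  invisible(x)
}

#' Fit every sample x drug monotherapy series in a long table
#'
#' Convenience wrapper over [fit_median_effect()] and [fit_logistic_ic50()]
#' for the long CSV layout (`sample_id, drug, dose_uM, response, replicate`).
#' Responses are converted to fraction affected as `fa = 1 - response`
#' (response already normalised to the vehicle mean) and clipped.
#'
#' @param data data.frame with columns `sample_id`, `drug`, `dose_uM`,
#'   `response` and optionally `replicate`.
#' @param epsilon clipping bound passed to [normalize_to_fraction_affected()].
#' @return data.frame with one row per sample x drug: `m`, `Dm`, `r`,
#'   `ic50_4pl` (NA when the 4PL fails), `n_points`, `flags`.
#' @export
fit_dose_response_table <- function(data, epsilon = 0.005) {
  req <- c("sample_id", "drug", "dose_uM", "response")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(data[, c("sample_id", "drug")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- data[data$sample_id == keys$sample_id[i] &
                  data$drug == keys$drug[i], ]
    fa <- suppressMessages(
      normalize_to_fraction_affected(sub$response, 1, epsilon)$fa
    )
    fit <- suppressWarnings(fit_median_effect(sub$dose_uM, fa))
    ic50 <- tryCatch(fit_logistic_ic50(sub$dose_uM, sub$response)$ic50,
                     error = function(e) NA_real_)
    data.frame(sample_id = keys$sample_id[i], drug = keys$drug[i],
               m = fit$m, Dm = fit$Dm, r = fit$r, ic50_4pl = ic50,
               n_points = fit$n_points,
               flags = paste(fit$flags, collapse = ";"))
  })
  do.call(rbind, out)
}
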