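#' Time to endpoint from a tumor-volume trajectory
#'
#' Derives the study day on which an animal's tumor reached the volume
#' endpoint. When an observation exceeds the endpoint, log10(volume) is
#' regressed on day over the window consisting of the first exceeding
#' observation and up to the three observations immediately preceding it,
#' and the crossing day is `(log10(endpoint) - intercept) / slope`. If that
#' estimate falls outside the bracket formed by the day before attainment
#' and the day of attainment (or the window regression is degenerate /
#' non-increasing), the crossing is instead linearly interpolated in
#' log10(volume) between the bracketing observations. Fate overrides:
#' treatment-related deaths are events at the death day, non-treatment
#' deaths are excluded, and animals that never reach the endpoint are
#' censored at the last study day.
#'
#' "Exceeded" is strict (> endpoint); a measurement exactly at the endpoint
#' still counts as attainment, with the window anchored on the first strict
#' exceedance when one exists, else on the equality point.
#'
#' @param day numeric vector of study days, strictly increasing.
#' @param volume tumor volumes (mm^3, `width^2 * length / 2` convention),
#'   positive, same length as `day`.
#' @param fate one of `"reached_endpoint"`, `"treatment_death"`,
#'   `"nontreatment_death"`, `"survived_to_end"`. `"reached_endpoint"` (the
#'   default) triggers the regression rule; use `"survived_to_end"` for
#'   animals whose tumors never attained the endpoint.
#' @param fate_day day of death for the two death fates.
#' @param endpoint_volume endpoint volume in mm^3. Default 2000.
#' @param last_day final study day for censored animals. Default 34.
#' @return list of class `tte_outcome`: `tte` (days, NA when excluded),
#'   `event` (logical), `excluded` (logical), `method` (one of
#'   `"regression"`, `"interpolation"`, `"first_observation"`,
#'   `"assigned_death_day"`, `"assigned_last_day"`, `"excluded"`).
#' @export
compute_tte <- function(day, volume,
                        fate = c("reached_endpoint", "treatment_death",
                                 "nontreatment_death", "survived_to_end"),
                        fate_day = NA_real_,
                        endpoint_volume = 2000, last_day = 34) {
  fate <- match.arg(fate)
  out <- function(tte, event, excluded, method) {
    structure(list(tte = tte, event = event, excluded = excluded,
                   method = method), class = "tte_outcome")
  }
  if (fate == "nontreatment_death") {
    return(out(NA_real_, FALSE, TRUE, "excluded"))
  }
  if (fate == "treatment_death") {
    stopifnot(is.finite(fate_day), fate_day > 0)
    return(out(fate_day, TRUE, FALSE, "assigned_death_day"))
  }
  if (fate == "survived_to_end") {
    return(out(last_day, FALSE, FALSE, "assigned_last_day"))
  }

  stopifnot(length(day) >= 1L, length(day) == length(volume))
  if (is.unsorted(day, strictly = TRUE)) {
    stop("study days must be strictly increasing", call. = FALSE)
  }
  if (any(volume <= 0)) stop("volumes must be positive", call. = FALSE)

  attained <- which(volume >= endpoint_volume)
  if (!length(attained)) {
    # trajectory never attained the endpoint: treat as survived to study end
    return(out(last_day, FALSE, FALSE, "assigned_last_day"))
  }
  exceeding <- which(volume > endpoint_volume)
  anchor <- if (length(exceeding)) exceeding[1L] else attained[1L]

  if (anchor == 1L) {
    # already beyond the endpoint at first measurement; no bracket exists
    return(out(day[1L], TRUE, FALSE, "first_observation"))
  }

  interpolate <- function() {
    i <- anchor
    lv <- log10(volume)
    le <- log10(endpoint_volume)
    tte <- day[i - 1L] +
      (le - lv[i - 1L]) / (lv[i] - lv[i - 1L]) * (day[i] - day[i - 1L])
    out(tte, TRUE, FALSE, "interpolation")
  }

  window <- seq.int(max(1L, anchor - 3L), anchor)
  wd <- day[window]; wv <- log10(volume[window])
  if (length(unique(wd)) < 2L) return(interpolate())
  fit <- stats::lm.fit(cbind(1, wd), wv)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  if (!is.finite(slope) || slope <= 0) return(interpolate())
  tte <- (log10(endpoint_volume) - intercept) / slope
  # crossing estimate must fall between the day preceding attainment and
  # the day of attainment, otherwise fall back to interpolation
  if (tte < day[anchor - 1L] || tte > day[anchor]) return(interpolate())
  out(tte, TRUE, FALSE, "regression")
}

#' @export
print.tte_outcome <- function(x, ...) {
  if (x$excluded) {
    cat("TTE: excluded (non-treatment death)\n")
  } else {
    cat("TTE:", signif(x$tte, 5), "days, event =", x$event,
        "(", x$method, ")\n")
  }
  invisible(x)
}

#' Per-animal TTE table from long volume data
#'
#' Applies [compute_tte()] to every animal in a long-format volume table,
#' joining fate assignments where given.
#'
#' @param volumes data.frame with columns `animal_id`, `group`, `day`,
#'   `volume_mm3`.
#' @param fates optional data.frame with columns `animal_id`, `fate`, `day`;
#'   animals absent from it default to the endpoint/censoring rule.
#' @inheritParams compute_tte
#' @return data.frame with one row per animal: `animal_id`, `group`, `tte`,
#'   `event`, `excluded`, `method`.
#' @export
compute_tte_table <- function(volumes, fates = NULL,
                              endpoint_volume = 2000, last_day = 34) {
  req <- c("animal_id", "group", "day", "volume_mm3")
  stopifnot(all(req %in% names(volumes)))
  ids <- unique(volumes$animal_id)
  rows <- lapply(ids, function(id) {
    sub <- volumes[volumes$animal_id == id, ]
    sub <- sub[order(sub$day), ]
    fate <- "reached_endpoint"; fd <- NA_real_
    if (!is.null(fates) && id %in% fates$animal_id) {
      fr <- fates[fates$animal_id == id, ][1L, ]
      fate <- fr$fate; fd <- fr$day
    }
    o <- compute_tte(sub$day, sub$volume_mm3, fate = fate, fate_day = fd,
                     endpoint_volume = endpoint_volume, last_day = last_day)
    data.frame(animal_id = id, group = sub$group[1L], tte = o$tte,
               event = o$event, excluded = o$excluded, method = o$method)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier curve and median survival
#'
#' Kaplan-Meier estimator over per-animal TTE outcomes, with excluded
#' animals dropped. The KM median is the first time at which the estimated
#' survival drops to <= 0.5 (reported as NA, "not reached", when the curve
#' never does); the plain median of the TTE values is reported alongside,
#' since with little censoring the two coincide.
#'
#' @param tte numeric vector of times to endpoint (days), or a data.frame
#'   from [compute_tte_table()] (columns `tte`, `event`, optionally
#'   `excluded`).
#' @param event logical event indicators (TRUE = endpoint reached); ignored
#'   when `tte` is a data.frame.
#' @return list with `curve` (data.frame `time`, `n_risk`, `n_event`,
#'   `survival`), `median_km`, `median_plain`, `n`.
#' @export
km_curve_and_median <- function(tte, event = NULL) {
  if (is.data.frame(tte)) {
    df <- tte
    if ("excluded" %in% names(df)) df <- df[!df$excluded, ]
    event <- df$event
    tte <- df$tte
  }
  stopifnot(length(tte) == length(event))
  keep <- is.finite(tte)
  tte <- tte[keep]; event <- as.logical(event[keep])
  if (!length(tte)) stop("no non-excluded outcomes", call. = FALSE)
  sf <- survival::survfit(survival::Surv(tte, event) ~ 1)
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, survival = sf$surv)
  drop_idx <- which(curve$survival <= 0.5 + 1e-12)
  median_km <- if (length(drop_idx)) curve$time[drop_idx[1L]] else NA_real_
  list(curve = curve, median_km = median_km,
       median_plain = stats::median(tte), n = length(tte))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Standard Mantel-Cox test comparing event-time distributions of two
#' groups, with the chi-square statistic on 1 degree of freedom.
#'
#' @param tte_a,tte_b times to endpoint per group (excluded animals already
#'   removed), or data.frames from [compute_tte_table()].
#' @param event_a,event_b logical event indicators; ignored for data.frames.
#' @param labels group labels for reporting.
#' @return list of class `logrank_result` with `chi_square`, `p_value`,
#'   `groups`.
#' @export
logrank_test <- function(tte_a, tte_b, event_a = NULL, event_b = NULL,
                         labels = c("a", "b")) {
  unpack <- function(x, ev) {
    if (is.data.frame(x)) {
      if ("excluded" %in% names(x)) x <- x[!x$excluded, ]
      list(t = x$tte, e = as.logical(x$event))
    } else {
      list(t = x, e = as.logical(ev))
    }
  }
  a <- unpack(tte_a, event_a); b <- unpack(tte_b, event_b)
  if (!any(a$e) && !any(b$e)) stop("no events in either group", call. = FALSE)
  time <- c(a$t, b$t)
  event <- c(a$e, b$e)
  grp <- factor(rep(labels, c(length(a$t), length(b$t))), levels = labels)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  structure(
    list(chi_square = unname(sd$chisq),
         p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         groups = labels),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank (Mantel-Cox):", paste(x$groups, collapse = " vs "),
      " chi-square =", signif(x$chi_square, 4),
      " p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}
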