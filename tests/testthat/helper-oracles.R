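# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: explicit loops and textbook formulas only.

# Mantel-Cox log-rank statistic by direct per-event-time 2x2 hypergeometric
# tabulation.
logrank_brute_force <- function(t1, e1, t2, e2) {
  time <- c(t1, t2)
  event <- c(as.logical(e1), as.logical(e2))
  grp <- rep(1:2, c(length(t1), length(t2)))
  times <- sort(unique(time[event]))
  O <- 0; E <- 0; V <- 0
  for (tt in times) {
    at1 <- sum(time >= tt & grp == 1)
    at2 <- sum(time >= tt & grp == 2)
    d1 <- sum(time == tt & event & grp == 1)
    d2 <- sum(time == tt & event & grp == 2)
    n <- at1 + at2; d <- d1 + d2
    if (n < 2 || d == 0) next
    O <- O + d1
    E <- E + d * at1 / n
    V <- V + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Weighted KS enrichment score by an explicit cumulative walk.
enrichment_score_brute_force <- function(genes, scores, set, p = 1) {
  n <- length(genes)
  hit <- genes %in% set
  n_hit <- sum(hit)
  denom <- sum(abs(scores[hit])^p)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- if (hit[i]) run + abs(scores[i])^p / denom else run - 1 / (n - n_hit)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Exact endpoint-crossing time of V(t) = v0 * exp(g t).
analytic_crossing <- function(v0, g, endpoint) log(endpoint / v0) / g

# A median-effect fit object straight from known parameters (no regression).
fit_from_truth <- function(m, Dm) {
  structure(list(m = m, Dm = Dm, r = 1, n_points = NA_integer_,
                 flags = character()),
            class = "median_effect_fit")
}

# Dose pairs constructed so that d1/Dx1(fa) + d2/Dx2(fa) = ci at a given
# drug-1 share of the additivity budget.
loewe_point <- function(m1, Dm1, m2, Dm2, fa, ci = 1, share_1 = 0.5) {
  dx1 <- Dm1 * (fa / (1 - fa))^(1 / m1)
  dx2 <- Dm2 * (fa / (1 - fa))^(1 / m2)
  list(dose_1 = ci * share_1 * dx1, dose_2 = ci * (1 - share_1) * dx2,
       fa = fa)
}
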