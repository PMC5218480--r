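#' Simulate a monotherapy dose-response table
#'
#' Draws viability responses from the median-effect model with
#' multiplicative Gaussian noise: `fa = 1 / (1 + (Dm/D)^m)`,
#' `response = (1 - fa) * (1 + eps)`, `eps ~ N(0, cv^2)` independently per
#' replicate. The default 11-dose grid spans 0.1-100 uM in quadruplicate,
#' the standard viability-screen design this pipeline targets.
#'
#' @param m,Dm true median-effect slope and median-effect dose (uM), both
#'   positive.
#' @param doses dose grid (uM). Default 11 half-log steps from 0.1 to 100.
#' @param n_replicates replicates per dose. Default 4.
#' @param cv coefficient of variation of the multiplicative noise.
#'   Default 0.05.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return data.frame with columns `dose_uM`, `replicate`, `response`,
#'   `fa_true`; attributes `m` and `Dm` carry the truth.
#' @export
simulate_dose_response <- function(m, Dm,
                                   doses = 10^seq(-1, 2, length.out = 11),
                                   n_replicates = 4, cv = 0.05, seed = 1) {
  if (!is.finite(m) || m <= 0 || !is.finite(Dm) || Dm <= 0) {
    stop("truth parameters m and Dm must be positive", call. = FALSE)
  }
  stopifnot(cv >= 0, all(doses > 0))
  set.seed(as.integer(seed))
  grid <- expand.grid(replicate = seq_len(n_replicates), dose_uM = doses)
  fa <- 1 / (1 + (Dm / grid$dose_uM)^m)
  eps <- stats::rnorm(nrow(grid), 0, cv)
  out <- data.frame(dose_uM = grid$dose_uM, replicate = grid$replicate,
                    response = (1 - fa) * (1 + eps), fa_true = fa)
  attr(out, "m") <- m
  attr(out, "Dm") <- Dm
  out
}

# Solve the fraction affected at which a fixed dose pair yields the target
# combination index: d1/Dx1(fa) + d2/Dx2(fa) = ci. The left side decreases
# monotonically from +Inf to 0 as fa runs over (0, 1), so the root is unique.
solve_fa_for_ci <- function(fit_1, fit_2, dose_1, dose_2, ci) {
  f <- function(fa) {
    (if (dose_1 > 0) dose_1 / dose_for_effect(fit_1, fa) else 0) +
      (if (dose_2 > 0) dose_2 / dose_for_effect(fit_2, fa) else 0) - ci
  }
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

me_fit_from_truth <- function(m, Dm) {
  structure(list(m = m, Dm = Dm, r = 1, n_points = NA_integer_,
                 flags = character()), class = "median_effect_fit")
}

#' Simulate a drug-combination response table with known true CI
#'
#' Constructs combination dose pairs whose true combination index equals
#' `true_ci` exactly, then adds multiplicative response noise. Two designs:
#' \describe{
#'   \item{constant_ratio}{for each target effect level, the dose pair at
#'     the fixed drug-1 : drug-2 ratio satisfying
#'     `d1/Dx1(fa) + d2/Dx2(fa) = true_ci` is dosed and the response set to
#'     that effect level (the 7-point IC50:IC50-ratio series).}
#'   \item{checkerboard}{a fixed grid of dose pairs is dosed and the
#'     response at each pair is the effect level at which that pair's CI
#'     equals `true_ci` (the 3x3-minus-one patient-sample matrix).}
#' }
#'
#' @param m_1,Dm_1,m_2,Dm_2 true monotherapy median-effect parameters.
#' @param true_ci target combination index, > 0.
#' @param design `"constant_ratio"` or `"checkerboard"`.
#' @param fa_targets effect levels for the constant-ratio series.
#' @param ratio drug-1 : drug-2 dose ratio for the constant-ratio design.
#'   Default `Dm_1 / Dm_2` (the IC50:IC50 convention).
#' @param doses_1,doses_2 dose grids for the checkerboard design (uM).
#' @param drop_cell index (1-9, row-major) of the grid cell to omit, so 8
#'   combinations are dosed; `NA` keeps the full grid. Default 5.
#' @param n_replicates replicates per point. Default 4.
#' @param cv multiplicative response noise. Default 0.05.
#' @param seed integer seed.
#' @return data.frame with columns `dose_1`, `dose_2`, `replicate`,
#'   `response`, `fa_true`; attribute `true_ci`.
#' @export
simulate_combination <- function(m_1, Dm_1, m_2, Dm_2, true_ci,
                                 design = c("constant_ratio", "checkerboard"),
                                 fa_targets = seq(0.15, 0.9, length.out = 7),
                                 ratio = Dm_1 / Dm_2,
                                 doses_1 = NULL, doses_2 = NULL,
                                 drop_cell = 5L,
                                 n_replicates = 4, cv = 0.05, seed = 1) {
  design <- match.arg(design)
  if (!is.finite(true_ci) || true_ci <= 0) {
    stop("`true_ci` must be positive", call. = FALSE)
  }
  fit_1 <- me_fit_from_truth(m_1, Dm_1)
  fit_2 <- me_fit_from_truth(m_2, Dm_2)
  set.seed(as.integer(seed))

  if (design == "constant_ratio") {
    pts <- do.call(rbind, lapply(fa_targets, function(f) {
      dx1 <- dose_for_effect(fit_1, f)
      dx2 <- dose_for_effect(fit_2, f)
      # d1 at ratio r (= d1/d2) meeting the additivity fraction true_ci
      d1 <- true_ci / (1 / dx1 + 1 / (ratio * dx2))
      data.frame(dose_1 = d1, dose_2 = d1 / ratio, fa_true = f)
    }))
  } else {
    if (is.null(doses_1)) doses_1 <- c(0.9, 1.8, 2.8)
    if (is.null(doses_2)) doses_2 <- c(0.5, 1.0, 1.5)
    grid <- expand.grid(dose_1 = doses_1, dose_2 = doses_2)
    if (!is.na(drop_cell)) grid <- grid[-drop_cell, , drop = FALSE]
    fa <- vapply(seq_len(nrow(grid)), function(i) {
      solve_fa_for_ci(fit_1, fit_2, grid$dose_1[i], grid$dose_2[i], true_ci)
    }, numeric(1))
    pts <- data.frame(dose_1 = grid$dose_1, dose_2 = grid$dose_2,
                      fa_true = fa)
  }

  out <- pts[rep(seq_len(nrow(pts)), each = n_replicates), ]
  out$replicate <- rep(seq_len(n_replicates), nrow(pts))
  eps <- stats::rnorm(nrow(out), 0, cv)
  out$response <- (1 - out$fa_true) * (1 + eps)
  rownames(out) <- NULL
  out <- out[, c("dose_1", "dose_2", "replicate", "response", "fa_true")]
  attr(out, "true_ci") <- true_ci
  out
}

#' Simulate a patient-sample synergy cohort
#'
#' Emulates an ex-vivo bone-marrow cohort: each sample carries its own
#' monotherapy median-effect parameters; a known true CI is drawn from a
#' two-component mixture (synergistic, CI < 1, vs non-synergistic); each
#' sample is assayed with 8-dose monotherapy series for both drugs plus a
#' 3x3-minus-one checkerboard. Defaults mirror a 30-sample cohort with 22
#' synergistic samples, drug-1 doses 0.9/1.8/2.8 uM and drug-2 doses
#' 0.5/1.0/1.5 uM.
#'
#' @param n_samples cohort size. Default 30.
#' @param n_synergistic samples with true CI < 1. Default 22.
#' @param ci_synergistic,ci_nonsynergistic ranges from which true CIs are
#'   drawn uniformly. Defaults (0.45, 0.8) and (1.05, 1.35).
#' @param doses_1,doses_2 checkerboard dose grids (uM).
#' @param cv multiplicative response noise. Default 0.05.
#' @param seed integer seed.
#' @return list with `data` (long data.frame: `sample_id`, `drug_1`,
#'   `dose_1_uM`, `drug_2`, `dose_2_uM`, `response`, `replicate`;
#'   monotherapy rows have one dose 0) and `truth` (per-sample
#'   `true_ci`, `synergistic`, monotherapy parameters).
#' @export
simulate_patient_cohort <- function(n_samples = 30, n_synergistic = 22,
                                    ci_synergistic = c(0.45, 0.8),
                                    ci_nonsynergistic = c(1.05, 1.35),
                                    doses_1 = c(0.9, 1.8, 2.8),
                                    doses_2 = c(0.5, 1.0, 1.5),
                                    cv = 0.05, seed = 1) {
  stopifnot(n_samples >= 1, n_synergistic >= 0, n_synergistic <= n_samples)
  set.seed(as.integer(seed))
  syn <- rep(c(TRUE, FALSE), c(n_synergistic, n_samples - n_synergistic))
  true_ci <- ifelse(syn,
                    stats::runif(n_samples, ci_synergistic[1], ci_synergistic[2]),
                    stats::runif(n_samples, ci_nonsynergistic[1], ci_nonsynergistic[2]))
  # sample-specific monotherapy parameters around the cohort-typical IC50s
  m_1 <- stats::runif(n_samples, 1.0, 2.0)
  m_2 <- stats::runif(n_samples, 1.0, 2.0)
  Dm_1 <- exp(stats::rnorm(n_samples, log(1.8), 0.2))
  Dm_2 <- exp(stats::rnorm(n_samples, log(1.0), 0.2))
  sub_seeds <- sample.int(2^20, 3 * n_samples)

  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    sid <- sprintf("sample_%02d", i)
    mono_doses_1 <- Dm_1[i] * 2^seq(-3, 3, length.out = 8)
    mono_doses_2 <- Dm_2[i] * 2^seq(-3, 3, length.out = 8)
    m1 <- simulate_dose_response(m_1[i], Dm_1[i], mono_doses_1,
                                 n_replicates = 3, cv = cv,
                                 seed = sub_seeds[3 * i - 2])
    m2 <- simulate_dose_response(m_2[i], Dm_2[i], mono_doses_2,
                                 n_replicates = 3, cv = cv,
                                 seed = sub_seeds[3 * i - 1])
    cb <- simulate_combination(m_1[i], Dm_1[i], m_2[i], Dm_2[i], true_ci[i],
                               design = "checkerboard",
                               doses_1 = doses_1, doses_2 = doses_2,
                               drop_cell = 5L, n_replicates = 3, cv = cv,
                               seed = sub_seeds[3 * i])
    rows[[i]] <- rbind(
      data.frame(sample_id = sid, drug_1 = "drug_a", dose_1_uM = m1$dose_uM,
                 drug_2 = "drug_b", dose_2_uM = 0, response = m1$response,
                 replicate = m1$replicate),
      data.frame(sample_id = sid, drug_1 = "drug_a", dose_1_uM = 0,
                 drug_2 = "drug_b", dose_2_uM = m2$dose_uM,
                 response = m2$response, replicate = m2$replicate),
      data.frame(sample_id = sid, drug_1 = "drug_a", dose_1_uM = cb$dose_1,
                 drug_2 = "drug_b", dose_2_uM = cb$dose_2,
                 response = cb$response, replicate = cb$replicate)
    )
  }
  list(
    data = do.call(rbind, rows),
    truth = data.frame(sample_id = sprintf("sample_%02d", seq_len(n_samples)),
                       true_ci = true_ci, synergistic = syn,
                       m_1 = m_1, Dm_1 = Dm_1, m_2 = m_2, Dm_2 = Dm_2)
  )
}

#' Simulate a xenograft tumor-growth study
#'
#' Exponential tumor growth `V(t) = V0 * exp(g * t)` with lognormal
#' measurement noise and animal-level growth-rate variability. Each group's
#' typical growth rate is parameterised by its median time to endpoint:
#' `g = log(endpoint_volume / v0) / median_tte`. Animals are measured on a
#' twice-weekly schedule and observation stops at the first measurement
#' exceeding the endpoint (the euthanasia rule); animals whose tumors never
#' reach the endpoint by the last day survive to study end. The defaults
#' emulate a four-arm study (vehicle, each single agent, combination) with
#' 10 animals per group, a 2000 mm^3 endpoint and a 34-day cap, with group
#' medians of 14, 17, 17.6 and 33.7 days.
#'
#' @param median_tte named numeric vector of group median times to endpoint
#'   (days); names are the group labels.
#' @param n_per_group animals per group. Default 10.
#' @param v0 volume at randomisation (mm^3). Default 125.
#' @param endpoint_volume endpoint (mm^3). Default 2000.
#' @param last_day final study day. Default 34.
#' @param measurement_days twice-weekly schedule by default.
#' @param sigma_log lognormal measurement noise (sd of log volume).
#'   Default 0.05.
#' @param animal_cv sd of the animal-level log growth-rate multiplier.
#'   Default 0.15.
#' @param n_nontreatment_deaths animals (chosen at random across groups) to
#'   assign a non-treatment-related death, exercising the exclusion rule.
#'   Default 0.
#' @param seed integer seed.
#' @return list with `volumes` (`animal_id`, `group`, `day`, `volume_mm3`),
#'   `fates` (`animal_id`, `fate`, `day`), and `truth` (`animal_id`,
#'   `group`, `growth_rate`, `true_crossing` in days, NA when the true
#'   trajectory never crosses by `last_day`).
#' @export
simulate_tumor_growth_study <- function(median_tte = c(vehicle = 14,
                                                       drug_a = 17,
                                                       drug_b = 17.6,
                                                       combination = 33.7),
                                        n_per_group = 10, v0 = 125,
                                        endpoint_volume = 2000, last_day = 34,
                                        measurement_days = c(0, 3, 7, 10, 14, 17,
                                                             21, 24, 28, 31, 34),
                                        sigma_log = 0.05, animal_cv = 0.15,
                                        n_nontreatment_deaths = 0, seed = 1) {
  stopifnot(!is.null(names(median_tte)), all(median_tte > 0),
            v0 > 0, endpoint_volume > v0, sigma_log >= 0, animal_cv >= 0)
  set.seed(as.integer(seed))
  groups <- names(median_tte)
  g_group <- log(endpoint_volume / v0) / median_tte

  vol_rows <- list(); fate_rows <- list(); truth_rows <- list()
  k <- 0L
  for (gr in groups) {
    for (j in seq_len(n_per_group)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", gr, j)
      g <- g_group[[gr]] * exp(stats::rnorm(1, 0, animal_cv))
      true_v <- v0 * exp(g * measurement_days)
      obs_v <- true_v * exp(stats::rnorm(length(true_v), 0, sigma_log))
      exceed <- which(obs_v > endpoint_volume)
      keep <- if (length(exceed)) seq_len(exceed[1L]) else
        seq_along(measurement_days)
      vol_rows[[k]] <- data.frame(animal_id = id, group = gr,
                                  day = measurement_days[keep],
                                  volume_mm3 = obs_v[keep])
      fate_rows[[k]] <- data.frame(
        animal_id = id,
        fate = if (length(exceed)) "reached_endpoint" else "survived_to_end",
        day = NA_real_)
      crossing <- log(endpoint_volume / v0) / g
      truth_rows[[k]] <- data.frame(
        animal_id = id, group = gr, growth_rate = g,
        true_crossing = if (crossing <= last_day) crossing else NA_real_)
    }
  }
  volumes <- do.call(rbind, vol_rows)
  fates <- do.call(rbind, fate_rows)
  truth <- do.call(rbind, truth_rows)

  if (n_nontreatment_deaths > 0) {
    victims <- sample(truth$animal_id, n_nontreatment_deaths)
    for (id in victims) {
      dday <- stats::runif(1, 5, 15)
      fates$fate[fates$animal_id == id] <- "nontreatment_death"
      fates$day[fates$animal_id == id] <- dday
      volumes <- volumes[!(volumes$animal_id == id & volumes$day > dday), ]
    }
  }
  list(volumes = volumes, fates = fates, truth = truth)
}

#' Planted combinatorial-response design for the expression simulator
#'
#' The region allocation used by [simulate_expression_experiment()]: for
#' each disjoint Venn region of the three >= 2-fold contrast lists (drug A,
#' drug B, combination), the number of planted genes and its up/down split.
#' The default allocation reproduces per-contrast totals of 62 up / 12 down
#' (drug A), 386 up / 72 down (drug B) and 581 up / 539 down (combination),
#' with 752 genes exclusive to the combination list out of a 1120-gene
#' union — the fold-change landscape of an azacitidine + HDAC1/2-inhibitor
#' profiling experiment.
#'
#' @return data.frame with columns `region`, `n_up`, `n_down`.
#' @export
planted_expression_design <- function() {
  data.frame(
    region = c("only_a", "only_b", "only_ab", "a_b", "a_ab", "b_ab", "a_b_ab"),
    n_up   = c(17, 76, 258, 2, 15, 280, 28),
    n_down = c(5, 32, 494, 0, 5, 38, 2),
    stringsAsFactors = FALSE
  )
}

#' Simulate a four-condition expression profiling experiment
#'
#' Generates a qualifier-level log2 intensity matrix for vehicle, drug A,
#' drug B and combination conditions, with genes planted into the disjoint
#' Venn regions of a [planted_expression_design()] at known fold-change
#' effect sizes. Planted single-agent effects have |log2 FC| drawn from
#' [1.5, 2.5] (comfortably past the 2-fold threshold); regions where the
#' combination responds "more than" a single agent add log2(1.5) on top of
#' the larger single-agent effect, past the 1.25-fold margin. Each symbol
#' is probed by one or more qualifiers with probe-specific baseline offsets
#' (collapse keeps the brightest), and a fraction of qualifiers is left
#' unmapped. The planted truth implies category labels: combination-only
#' genes are categories A/B, single-agent-plus-combination genes C-F, and
#' genes responding to all three contrasts G/H.
#'
#' @param n_genes total gene symbols (planted + null); must be at least the
#'   planted total (1232 by default). Default 20000.
#' @param n_per_condition arrays per condition. Default 3.
#' @param sigma_log2 additive Gaussian noise on log2 per sample.
#'   Default 0.1.
#' @param baseline_mean,baseline_sd gene baseline log2 distribution.
#'   Defaults 7 and 1.5.
#' @param design region allocation, see [planted_expression_design()].
#' @param mean_qualifiers_per_gene average probe redundancy; ~2.5 gives the
#'   ~50,000 probes for ~20,000 genes typical of the array. Default 2.5.
#' @param frac_unmapped fraction of extra unmapped qualifiers. Default 0.02.
#' @param n_random_sets random control gene sets to emit alongside the
#'   planted one. Default 25.
#' @param seed integer seed.
#' @return list with `values` (qualifier x sample log2 matrix),
#'   `qualifier_map`, `conditions` (per column), `truth` (per planted or
#'   null gene: region, direction, true log2 fold changes, category) and
#'   `gene_sets` (named list; `"PLANTED_TF_TARGETS_SYNTHETIC"` occupies the
#'   top of the combination-vs-drug-A ranking).
#' @export
simulate_expression_experiment <- function(n_genes = 20000,
                                           n_per_condition = 3,
                                           sigma_log2 = 0.1,
                                           baseline_mean = 7,
                                           baseline_sd = 1.5,
                                           design = planted_expression_design(),
                                           mean_qualifiers_per_gene = 2.5,
                                           frac_unmapped = 0.02,
                                           n_random_sets = 25,
                                           seed = 1) {
  set.seed(as.integer(seed))
  n_planted <- sum(design$n_up + design$n_down)
  if (n_genes < n_planted) {
    stop("`n_genes` must be at least the planted total (", n_planted, ")",
         call. = FALSE)
  }
  genes <- sprintf("GENE%05d", seq_len(n_genes))

  # per-gene truth: region, direction, log2 effects per contrast
  region <- rep("null", n_genes)
  direction <- rep(0L, n_genes)
  idx <- 1L
  for (i in seq_len(nrow(design))) {
    for (dir in c(1L, -1L)) {
      nn <- if (dir == 1L) design$n_up[i] else design$n_down[i]
      if (nn == 0) next
      sel <- idx:(idx + nn - 1L)
      region[sel] <- design$region[i]
      direction[sel] <- dir
      idx <- idx + nn
    }
  }
  changed_a <- region %in% c("only_a", "a_b", "a_ab", "a_b_ab")
  changed_b <- region %in% c("only_b", "a_b", "b_ab", "a_b_ab")
  changed_ab <- region %in% c("only_ab", "a_ab", "b_ab", "a_b_ab")
  amp <- function(sel) {
    out <- numeric(n_genes)
    out[sel] <- direction[sel] * stats::runif(sum(sel), 1.5, 2.5)
    out
  }
  l2_a <- amp(changed_a)
  l2_b <- amp(changed_b)
  extra <- log2(1.5)
  l2_ab <- numeric(n_genes)
  l2_ab[region == "only_ab"] <-
    direction[region == "only_ab"] * stats::runif(sum(region == "only_ab"), 1.5, 2.5)
  sel <- region == "a_ab"
  l2_ab[sel] <- l2_a[sel] + direction[sel] * extra
  sel <- region == "b_ab"
  l2_ab[sel] <- l2_b[sel] + direction[sel] * extra
  sel <- region == "a_b_ab"
  l2_ab[sel] <- direction[sel] * (pmax(abs(l2_a[sel]), abs(l2_b[sel])) + extra)

  category <- rep("none", n_genes)
  category[region == "only_ab" & direction == 1L] <- "A"
  category[region == "only_ab" & direction == -1L] <- "B"
  category[region == "a_ab" & direction == 1L] <- "C"
  category[region == "a_ab" & direction == -1L] <- "D"
  category[region == "b_ab" & direction == 1L] <- "E"
  category[region == "b_ab" & direction == -1L] <- "F"
  category[region == "a_b_ab" & direction == 1L] <- "G"
  category[region == "a_b_ab" & direction == -1L] <- "H"

  truth <- data.frame(gene = genes, region = region, direction = direction,
                      log2fc_a = l2_a, log2fc_b = l2_b, log2fc_ab = l2_ab,
                      category = category, stringsAsFactors = FALSE)

  # qualifier layer: >= 1 probe per gene, probe-specific brightness offsets
  n_extra <- stats::rpois(n_genes, mean_qualifiers_per_gene - 1)
  n_qual_per_gene <- 1L + n_extra
  gene_of_qual <- rep(seq_len(n_genes), n_qual_per_gene)
  n_mapped <- length(gene_of_qual)
  n_unmapped <- ceiling(frac_unmapped * n_mapped)
  n_qual <- n_mapped + n_unmapped
  qualifiers <- sprintf("Q%06d_at", seq_len(n_qual))
  qualifier_map <- data.frame(
    qualifier = qualifiers[seq_len(n_mapped)],
    symbol = genes[gene_of_qual], stringsAsFactors = FALSE)

  conditions <- rep(c("vehicle", "drug_a", "drug_b", "combination"),
                    each = n_per_condition)
  baseline_gene <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
  probe_offset <- stats::rnorm(n_qual, 0, 0.5)

  effect_by_cond <- cbind(vehicle = numeric(n_genes), drug_a = l2_a,
                          drug_b = l2_b, combination = l2_ab)
  base_q <- c(baseline_gene[gene_of_qual],
              stats::rnorm(n_unmapped, baseline_mean, baseline_sd)) +
    probe_offset
  eff_q <- rbind(effect_by_cond[gene_of_qual, , drop = FALSE],
                 matrix(0, n_unmapped, 4,
                        dimnames = list(NULL, colnames(effect_by_cond))))
  values <- base_q + eff_q[, conditions, drop = FALSE] +
    matrix(stats::rnorm(n_qual * length(conditions), 0, sigma_log2),
           n_qual, length(conditions))
  rownames(values) <- qualifiers
  colnames(values) <- paste0(conditions, "_", rep(seq_len(n_per_condition),
                                                  times = 4))

  # gene sets: one planted set enriched at the top of combination vs drug A,
  # plus random control sets
  up_ab_only <- genes[region == "only_ab" & direction == 1L]
  null_genes <- genes[region == "null"]
  planted_set <- c(sample(up_ab_only, min(60, length(up_ab_only))),
                   sample(null_genes, 40))
  gene_sets <- c(
    list(PLANTED_TF_TARGETS_SYNTHETIC = planted_set),
    stats::setNames(
      lapply(seq_len(n_random_sets), function(i) {
        sample(genes, sample(50:200, 1))
      }),
      sprintf("RANDOM_SET_%02d", seq_len(n_random_sets)))
  )

  list(values = values, qualifier_map = qualifier_map,
       conditions = conditions, truth = truth, gene_sets = gene_sets)
}
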