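#' Read a combination-study CSV
#'
#' Long format, one row per well: `sample_id, drug_1, dose_1_uM, drug_2,
#' dose_2_uM, response, replicate`. Monotherapy rows carry 0 in one dose
#' column. Malformed rows raise line-numbered errors.
#'
#' @param path CSV path (comma-separated, header row, '.' decimal).
#' @return validated data.frame.
#' @export
read_combination_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "drug_1", "dose_1_uM", "drug_2", "dose_2_uM",
           "response", "replicate")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop(path, ": no data rows", call. = FALSE)
  bad <- which(!is.finite(df$dose_1_uM) | !is.finite(df$dose_2_uM) |
                 df$dose_1_uM < 0 | df$dose_2_uM < 0 |
                 (df$dose_1_uM == 0 & df$dose_2_uM == 0) |
                 !is.finite(df$response))
  if (length(bad)) {
    stop(path, ": malformed row(s) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "),
         " (doses must be non-negative, not both zero; response numeric)",
         call. = FALSE)
  }
  df
}

#' @rdname read_combination_csv
#' @param data data.frame in the same layout.
#' @export
write_combination_csv <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tumor-volume and animal-fate CSVs
#'
#' Volumes: `animal_id, group, day, volume_mm3` (long). Fates:
#' `animal_id, fate, day`.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_volumes_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "group", "day", "volume_mm3")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop(path, ": no data rows", call. = FALSE)
  bad <- which(!is.finite(df$day) | !is.finite(df$volume_mm3) |
                 df$volume_mm3 <= 0)
  if (length(bad)) {
    stop(path, ": malformed row(s) at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_volumes_csv
#' @export
read_fates_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "fate", "day")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  known <- c("reached_endpoint", "treatment_death", "nontreatment_death",
             "survived_to_end")
  bad <- which(!df$fate %in% known)
  if (length(bad)) {
    stop(path, ": unknown fate at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  df
}

#' Synergy analysis over a combination-study table
#'
#' For each sample: fits the median-effect model to each drug's monotherapy
#' rows (response averaged over replicates per dose, fa = 1 - response,
#' clipped), computes per-point CIs at the combination rows' observed
#' effects, summarises the sample by its median CI, and summarises the
#' cohort by the fraction of samples with median CI < 1.
#'
#' @param data data.frame in the [read_combination_csv()] layout, or a path
#'   to such a CSV.
#' @param epsilon clipping bound for fraction affected. Default 0.005.
#' @return list with `fits` (per sample x drug median-effect parameters),
#'   `per_point` (per combination point CI table), `per_sample` (median CI
#'   per sample) and `cohort` (from [cohort_synergy_fraction()]).
#' @export
run_synergy <- function(data, epsilon = 0.005) {
  if (is.character(data)) data <- read_combination_csv(data)
  samples <- unique(data$sample_id)
  fits <- list(); per_point <- list(); per_sample <- list()
  for (sid in samples) {
    sub <- data[data$sample_id == sid, ]
    mono_1 <- sub[sub$dose_1_uM > 0 & sub$dose_2_uM == 0, ]
    mono_2 <- sub[sub$dose_2_uM > 0 & sub$dose_1_uM == 0, ]
    combo <- sub[sub$dose_1_uM > 0 & sub$dose_2_uM > 0, ]
    if (nrow(mono_1) < 2 || nrow(mono_2) < 2) {
      stop("sample ", sid, ": insufficient monotherapy data", call. = FALSE)
    }
    fa_of <- function(x) suppressMessages(
      normalize_to_fraction_affected(x, 1, epsilon)$fa)
    fit_1 <- suppressWarnings(fit_median_effect(mono_1$dose_1_uM,
                                                fa_of(mono_1$response)))
    fit_2 <- suppressWarnings(fit_median_effect(mono_2$dose_2_uM,
                                                fa_of(mono_2$response)))
    fits[[sid]] <- data.frame(
      sample_id = sid, drug = c(sub$drug_1[1], sub$drug_2[1]),
      m = c(fit_1$m, fit_2$m), Dm = c(fit_1$Dm, fit_2$Dm),
      r = c(fit_1$r, fit_2$r),
      flagged = c(length(fit_1$flags) > 0, length(fit_2$flags) > 0))
    # average replicates per dose pair before scoring
    key <- interaction(combo$dose_1_uM, combo$dose_2_uM, drop = TRUE)
    agg <- do.call(rbind, lapply(split(combo, key), function(g) {
      data.frame(dose_1 = g$dose_1_uM[1], dose_2 = g$dose_2_uM[1],
                 fa = fa_of(mean(g$response)))
    }))
    summ <- checkerboard_ci(fit_1, fit_2, agg, sample_id = sid)
    pp <- summ$ci_table
    pp$sample_id <- sid
    per_point[[sid]] <- pp
    per_sample[[sid]] <- data.frame(sample_id = sid,
                                    median_ci = summ$median_ci,
                                    n_valid = summ$n_valid)
  }
  per_sample <- do.call(rbind, per_sample)
  rownames(per_sample) <- NULL
  list(fits = do.call(rbind, fits),
       per_point = do.call(rbind, per_point),
       per_sample = per_sample,
       cohort = cohort_synergy_fraction(per_sample$median_ci))
}

#' Survival analysis over a tumor-volume study
#'
#' Computes per-animal TTE (regression rule, with the fate overrides),
#' per-group Kaplan-Meier medians, and pairwise log-rank tests.
#'
#' @param volumes long volume table or CSV path
#'   (see [read_volumes_csv()]).
#' @param fates fate table or CSV path, optional.
#' @inheritParams compute_tte
#' @return list with `tte` (per-animal table), `medians` (per group:
#'   `median_km`, `median_plain`, `n`, `n_events`), `logrank` (pairwise
#'   results).
#' @export
run_survival <- function(volumes, fates = NULL,
                         endpoint_volume = 2000, last_day = 34) {
  if (is.character(volumes)) volumes <- read_volumes_csv(volumes)
  if (is.character(fates)) fates <- read_fates_csv(fates)
  tte <- compute_tte_table(volumes, fates,
                           endpoint_volume = endpoint_volume,
                           last_day = last_day)
  groups <- unique(tte$group)
  medians <- do.call(rbind, lapply(groups, function(gr) {
    sub <- tte[tte$group == gr & !tte$excluded, ]
    km <- km_curve_and_median(sub)
    data.frame(group = gr, median_km = km$median_km,
               median_plain = km$median_plain, n = km$n,
               n_events = sum(sub$event))
  }))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  logrank <- do.call(rbind, lapply(pairs, function(p) {
    res <- logrank_test(tte[tte$group == p[1], ], tte[tte$group == p[2], ],
                        labels = p)
    data.frame(group_a = p[1], group_b = p[2],
               chi_square = res$chi_square, p_value = res$p_value)
  }))
  list(tte = tte, medians = medians, logrank = logrank)
}

#' Expression-response analysis over a four-condition experiment
#'
#' Runs the full microarray stage: collapse qualifiers to symbols by
#' maximum mean signal, per-gene fold changes of each treatment vs vehicle,
#' >= 2-fold up/down lists and Venn region counts, category A-H
#' classification, row z-scoring of the classified genes, the
#' difference-of-means ranking of combination vs drug A, and gene-set
#' enrichment with gene-set permutation FDR.
#'
#' @param values qualifier-level log2 matrix (or a GCT path).
#' @param qualifier_map data.frame `qualifier`, `symbol` (or a TSV path
#'   with those two columns).
#' @param conditions character vector per column: vehicle / drug_a /
#'   drug_b / combination.
#' @param gene_sets named list of gene sets (or a GMT path); `NULL` skips
#'   enrichment.
#' @param fold_threshold list-selection threshold. Default 2.
#' @param filters category thresholds, see [category_filter_config()].
#' @param n_perm gene-set permutations. Default 1000.
#' @param seed seed for the permutation null. Default 1.
#' @return list with `collapsed`, `fc`, `lists`, `venn`, `categories`,
#'   `category_counts`, `zscored` (classified genes only), `ranked`,
#'   `enrichment`.
#' @export
run_expression <- function(values, qualifier_map, conditions,
                           gene_sets = NULL, fold_threshold = 2,
                           filters = category_filter_config(),
                           n_perm = 1000, seed = 1) {
  if (is.character(values)) values <- read_gct(values)
  if (is.character(qualifier_map)) {
    qualifier_map <- utils::read.delim(qualifier_map,
                                       stringsAsFactors = FALSE)
  }
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  collapsed <- collapse_to_symbols(values, qualifier_map)
  fc <- fold_changes(collapsed, conditions)
  lists <- threshold_gene_lists(fc, fold_threshold)
  venn <- venn_counts(c(lists$a$up, lists$a$down),
                      c(lists$b$up, lists$b$down),
                      c(lists$ab$up, lists$ab$down))
  categories <- classify_combination_categories(fc, filters)
  classified <- categories$gene[categories$category != "none"]
  zscored <- if (length(classified) >= 1L) {
    zscore_rows(collapsed[classified, , drop = FALSE])
  } else {
    NULL
  }
  ranked <- rank_by_class_difference(collapsed,
                                     which(conditions == "combination"),
                                     which(conditions == "drug_a"))
  enrichment <- if (!is.null(gene_sets)) {
    gsea_permutation_test(ranked, gene_sets, n_perm = n_perm, seed = seed)
  } else {
    NULL
  }
  list(collapsed = collapsed, fc = fc, lists = lists, venn = venn,
       categories = categories,
       category_counts = table(categories$category),
       zscored = zscored, ranked = ranked, enrichment = enrichment)
}

#' Generate the full set of synthetic study inputs on disk
#'
#' Writes every fixture the three analyses consume, in the CSV/GCT/GMT
#' dialects the readers expect, plus the ground-truth tables.
#'
#' @param outdir output directory (created if needed).
#' @param seed master seed; stage seeds are derived from it.
#' @param n_genes genes for the expression experiment. Default 20000.
#' @param cohort_kwargs,tumor_kwargs,expression_kwargs named lists of
#'   overrides passed to the respective simulators.
#' @return (invisibly) named list of the written file paths.
#' @export
run_simulate <- function(outdir, seed = 1, n_genes = 20000,
                         cohort_kwargs = list(), tumor_kwargs = list(),
                         expression_kwargs = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  cohort <- do.call(simulate_patient_cohort,
                    c(list(seed = seed), cohort_kwargs))
  tumor <- do.call(simulate_tumor_growth_study,
                   c(list(seed = seed + 1L), tumor_kwargs))
  expr <- do.call(simulate_expression_experiment,
                  c(list(n_genes = n_genes, seed = seed + 2L),
                    expression_kwargs))
  paths <- list(
    combination = file.path(outdir, "combination_cohort.csv"),
    cohort_truth = file.path(outdir, "combination_cohort_truth.csv"),
    volumes = file.path(outdir, "tumor_volumes.csv"),
    fates = file.path(outdir, "animal_fates.csv"),
    tumor_truth = file.path(outdir, "tumor_truth.csv"),
    expression = file.path(outdir, "expression_log2.gct"),
    qualifier_map = file.path(outdir, "qualifier_map.tsv"),
    gene_sets = file.path(outdir, "gene_sets.gmt"),
    conditions = file.path(outdir, "sample_conditions.csv"),
    expression_truth = file.path(outdir, "expression_truth.csv"))
  write_combination_csv(cohort$data, paths$combination)
  utils::write.csv(cohort$truth, paths$cohort_truth, row.names = FALSE)
  utils::write.csv(tumor$volumes, paths$volumes, row.names = FALSE)
  utils::write.csv(tumor$fates, paths$fates, row.names = FALSE)
  utils::write.csv(tumor$truth, paths$tumor_truth, row.names = FALSE)
  write_gct(expr$values, paths$expression)
  utils::write.table(expr$qualifier_map, paths$qualifier_map, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_gmt(expr$gene_sets, paths$gene_sets)
  utils::write.csv(data.frame(sample = colnames(expr$values),
                              condition = expr$conditions),
                   paths$conditions, row.names = FALSE)
  utils::write.csv(expr$truth, paths$expression_truth, row.names = FALSE)
  invisible(paths)
}
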