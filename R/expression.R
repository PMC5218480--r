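#' Collapse a qualifier-level matrix to gene symbols
#'
#' For each gene symbol, keeps the single array qualifier (probe set) with
#' the maximum mean signal across samples; qualifiers with no symbol mapping
#' are dropped (count attached as attribute `n_unmapped`).
#'
#' @param values numeric matrix of log2 intensities, qualifiers in rows
#'   (rownames required), samples in columns.
#' @param qualifier_map data.frame with columns `qualifier` and `symbol`.
#'   Qualifiers absent from the map, or mapped to `NA`/empty symbols, are
#'   treated as unmapped.
#' @return matrix with one row per distinct mapped symbol (rownames are
#'   symbols), attribute `n_unmapped` giving the dropped qualifier count.
#' @export
collapse_to_symbols <- function(values, qualifier_map) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (!all(c("qualifier", "symbol") %in% names(qualifier_map)) ||
      nrow(qualifier_map) == 0L) {
    stop("empty or malformed qualifier-to-symbol mapping", call. = FALSE)
  }
  map <- qualifier_map$symbol[match(rownames(values), qualifier_map$qualifier)]
  map[!is.na(map) & map == ""] <- NA_character_
  mapped <- !is.na(map)
  n_unmapped <- sum(!mapped)
  if (!any(mapped)) stop("no qualifier maps to a symbol", call. = FALSE)
  vals <- values[mapped, , drop = FALSE]
  sym <- map[mapped]
  means <- rowMeans(vals)
  # within each symbol keep the row with the largest mean signal
  ord <- order(sym, -means)
  keep <- ord[!duplicated(sym[ord])]
  out <- vals[keep, , drop = FALSE]
  rownames(out) <- sym[keep]
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Per-gene fold changes of each treatment vs vehicle
#'
#' Linear-scale fold change for each of the three treatment conditions
#' relative to vehicle: `fc = 2 ^ (mean log2 treatment - mean log2 vehicle)`
#' (a ratio of geometric means on the linear scale).
#'
#' @param values log2 expression matrix, genes x samples.
#' @param conditions character vector (length = ncol) assigning each sample
#'   to one of `"vehicle"`, `"drug_a"`, `"drug_b"`, `"combination"`.
#' @return data.frame with columns `gene`, `fc_a`, `fc_b`, `fc_ab`.
#' @export
fold_changes <- function(values, conditions) {
  stopifnot(is.matrix(values), length(conditions) == ncol(values))
  need <- c("vehicle", "drug_a", "drug_b", "combination")
  missing_cond <- setdiff(need, unique(conditions))
  if (length(missing_cond)) {
    stop("missing condition(s): ", paste(missing_cond, collapse = ", "),
         call. = FALSE)
  }
  cond_mean <- function(cond) {
    rowMeans(values[, conditions == cond, drop = FALSE])
  }
  veh <- cond_mean("vehicle")
  data.frame(gene = rownames(values),
             fc_a = 2^(cond_mean("drug_a") - veh),
             fc_b = 2^(cond_mean("drug_b") - veh),
             fc_ab = 2^(cond_mean("combination") - veh),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' At-least-k-fold up/down gene lists per contrast
#'
#' Selects genes changed by at least `threshold`-fold in each direction:
#' `up = {fc >= threshold}`, `down = {fc <= 1/threshold}` ("at least" is
#' inclusive).
#'
#' @param fc data.frame from [fold_changes()].
#' @param threshold fold-change cutoff, > 1. Default 2.
#' @return nested list: `$a`, `$b`, `$ab`, each with character vectors `up`
#'   and `down`.
#' @export
threshold_gene_lists <- function(fc, threshold = 2) {
  stopifnot(threshold > 1)
  pick <- function(col) {
    list(up = fc$gene[fc[[col]] >= threshold],
         down = fc$gene[fc[[col]] <= 1 / threshold])
  }
  list(a = pick("fc_a"), b = pick("fc_b"), ab = pick("fc_ab"))
}

#' Three-set Venn region counts
#'
#' Counts of the seven disjoint regions of a three-set Venn diagram plus the
#' union. "Exclusive to" a set means present in it and absent from both
#' others.
#'
#' @param set_a,set_b,set_ab character vectors (the two single-agent lists
#'   and the combination list; order only affects labels).
#' @return named list of counts: `only_a`, `only_b`, `only_ab`, `a_b`,
#'   `a_ab`, `b_ab`, `a_b_ab`, `union`.
#' @export
venn_counts <- function(set_a, set_b, set_ab) {
  set_a <- unique(set_a); set_b <- unique(set_b); set_ab <- unique(set_ab)
  u <- unique(c(set_a, set_b, set_ab))
  in_a <- u %in% set_a; in_b <- u %in% set_b; in_ab <- u %in% set_ab
  list(only_a  = sum(in_a & !in_b & !in_ab),
       only_b  = sum(!in_a & in_b & !in_ab),
       only_ab = sum(!in_a & !in_b & in_ab),
       a_b     = sum(in_a & in_b & !in_ab),
       a_ab    = sum(in_a & !in_b & in_ab),
       b_ab    = sum(!in_a & in_b & in_ab),
       a_b_ab  = sum(in_a & in_b & in_ab),
       union   = length(u))
}

#' Default fold-change filter configuration for category classification
#'
#' @param t_change fold-change defining "up/down-regulated". Default 2.
#' @param unaffected_band a gene counts as "unaffected" by a single agent
#'   when its fold change lies within `[1/unaffected_band, unaffected_band]`.
#'   Default 1.5.
#' @param t_extra margin defining "more than the single agent alone": the
#'   combination fold change must exceed `t_extra` times the single-agent
#'   fold change in the same direction. Default 1.25.
#' @return list with the three thresholds.
#' @export
category_filter_config <- function(t_change = 2, unaffected_band = 1.5,
                                   t_extra = 1.25) {
  stopifnot(t_change > 1, unaffected_band >= 1, t_extra >= 1)
  if (t_change <= unaffected_band) {
    warning("`t_change` does not exceed the unaffected band; ",
            "'changed' and 'unaffected' overlap", call. = FALSE)
  }
  list(t_change = t_change, unaffected_band = unaffected_band,
       t_extra = t_extra)
}

#' Classify combinatorial expression responses into categories A-H
#'
#' Assigns each gene exactly one of eight mutually exclusive combinatorial
#' response categories (or `"none"`), based on its fold changes under drug A
#' alone, drug B alone, and the combination:
#' \describe{
#'   \item{A / B}{unaffected by both single agents, up- / down-regulated by
#'     the combination.}
#'   \item{C / D}{up- / down-regulated by drug A, unaffected by drug B, and
#'     changed more by the combination than by drug A alone.}
#'   \item{E / F}{unaffected by drug A, up- / down-regulated by drug B, and
#'     changed more by the combination than by drug B alone.}
#'   \item{G / H}{up- / down-regulated by both single agents and changed
#'     more by the combination than by either alone.}
#' }
#' Genes falling between the "unaffected" band and the "changed" threshold
#' for a single agent are conservatively `"none"`.
#'
#' @param fc data.frame from [fold_changes()].
#' @param filters list from [category_filter_config()].
#' @return data.frame with columns `gene`, `category` (factor with levels
#'   A-H, none).
#' @export
classify_combination_categories <- function(fc,
                                            filters = category_filter_config()) {
  tc <- filters$t_change; ub <- filters$unaffected_band; tx <- filters$t_extra
  up   <- function(x) x >= tc
  down <- function(x) x <= 1 / tc
  unaf <- function(x) x >= 1 / ub & x <= ub
  a <- fc$fc_a; b <- fc$fc_b; ab <- fc$fc_ab
  cat <- rep("none", nrow(fc))
  cat[unaf(a) & unaf(b) & up(ab)]   <- "A"
  cat[unaf(a) & unaf(b) & down(ab)] <- "B"
  cat[up(a)   & unaf(b) & up(ab)   & ab >= tx * a]      <- "C"
  cat[down(a) & unaf(b) & down(ab) & ab <= a / tx]      <- "D"
  cat[unaf(a) & up(b)   & up(ab)   & ab >= tx * b]      <- "E"
  cat[unaf(a) & down(b) & down(ab) & ab <= b / tx]      <- "F"
  cat[up(a)   & up(b)   & up(ab)   & ab >= tx * pmax(a, b)]   <- "G"
  cat[down(a) & down(b) & down(ab) & ab <= pmin(a, b) / tx]   <- "H"
  data.frame(gene = fc$gene,
             category = factor(cat, levels = c(LETTERS[1:8], "none")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Row-standardise a matrix for heatmap display
#'
#' Normalises every row to mean zero and variance one (population standard
#' deviation, i.e. divisor `n`, the matrix2png convention). Constant rows
#' become all zeros and are flagged.
#'
#' @param values numeric matrix.
#' @return matrix of the same shape; attribute `constant_rows` holds the
#'   indices of rows that were constant.
#' @export
zscore_rows <- function(values) {
  stopifnot(is.matrix(values), ncol(values) >= 2L)
  mu <- rowMeans(values)
  centered <- values - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  const <- which(sd_pop == 0)
  sd_pop[sd_pop == 0] <- 1
  out <- centered / sd_pop
  if (length(const)) {
    out[const, ] <- 0
    warning(length(const), " constant row(s) set to zero", call. = FALSE)
  }
  attr(out, "constant_rows") <- const
  out
}

#' Rank genes by difference of class means
#'
#' Scores every gene by `mean(log2 class A) - mean(log2 class B)` and sorts
#' the list descending; ties are broken by symbol in lexicographic order so
#' the ranking is fully reproducible. This difference-of-means ranking is
#' the input metric for the weighted enrichment score.
#'
#' @param values log2 expression matrix, genes x samples.
#' @param cols_a,cols_b column indices (or names) of the two sample classes.
#' @return data.frame with columns `gene`, `score`, ordered by decreasing
#'   score.
#' @export
rank_by_class_difference <- function(values, cols_a, cols_b) {
  stopifnot(is.matrix(values), length(cols_a) >= 1L, length(cols_b) >= 1L)
  score <- rowMeans(values[, cols_a, drop = FALSE]) -
    rowMeans(values[, cols_b, drop = FALSE])
  ord <- order(-score, rownames(values))
  data.frame(gene = rownames(values)[ord], score = unname(score[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}
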