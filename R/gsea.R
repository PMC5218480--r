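#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down a ranked gene list accumulating a running sum that increases
#' by `|score|^p / sum_hits |score|^p` at each gene in the set (a "hit") and
#' decreases by `1 / (N - N_hits)` at each gene outside it. The enrichment
#' score is the maximum deviation of the running sum from zero, signed.
#' With `weight_exponent = 0` this is the classical KS statistic; the
#' default `p = 1` weights hits by their ranking scores.
#'
#' @param ranked data.frame from [rank_by_class_difference()] (columns
#'   `gene`, `score`, already sorted), or a named numeric vector of scores
#'   sorted in decreasing order.
#' @param set character vector of member gene symbols.
#' @param weight_exponent hit weight exponent `p`. Default 1.
#' @return list with `es`, `position` (index of the extreme deviation) and
#'   `running` (the running-sum profile, length = number of genes).
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1) {
  if (is.data.frame(ranked)) {
    genes <- ranked$gene
    scores <- ranked$score
  } else {
    genes <- names(ranked)
    scores <- unname(ranked)
  }
  n <- length(genes)
  hit <- genes %in% set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set has empty intersection with the ranked list",
                        call. = FALSE)
  if (n_hit == n) stop("gene set covers the entire ranked list", call. = FALSE)
  w <- abs(scores)^weight_exponent
  hit_w <- w * hit
  denom_hit <- sum(hit_w)
  incr <- if (denom_hit > 0) hit_w / denom_hit else hit / n_hit
  decr <- (!hit) / (n - n_hit)
  running <- cumsum(incr - decr)
  pos <- which.max(abs(running))
  list(es = running[pos], position = pos, running = running)
}

#' Gene-set enrichment with gene-set permutation null
#'
#' For each gene set, computes the observed enrichment score, then builds a
#' null distribution by scoring `n_perm` random gene sets of the same size
#' drawn from the ranked list (gene-set permutation). The normalised
#' enrichment score (NES) divides the observed ES by the mean magnitude of
#' same-sign null ES values; the nominal p-value is the fraction of
#' same-sign null ES at least as extreme. FDR follows the standard GSEA
#' procedure: for a set with NES*, the fraction of all (set, permutation)
#' null NES values at least as extreme (same sign) is divided by the
#' fraction of observed NES values at least as extreme, clipped to [0, 1].
#'
#' @inheritParams enrichment_score
#' @param sets named list of character vectors (gene sets).
#' @param n_perm number of random sets per gene set, >= 100. Default 1000.
#' @param seed integer seed; results are fully reproducible given it.
#' @return data.frame with one row per set: `set`, `size` (genes in the
#'   ranked list), `es`, `nes`, `p_nominal`, `fdr`.
#' @export
gsea_permutation_test <- function(ranked, sets, n_perm = 1000, seed = 1,
                                  weight_exponent = 1) {
  if (n_perm < 100) {
    warning("n_perm < 100 gives poor p-value and FDR resolution",
            call. = FALSE)
  }
  if (is.null(names(sets))) names(sets) <- paste0("set_", seq_along(sets))
  genes <- if (is.data.frame(ranked)) ranked$gene else names(ranked)
  n <- length(genes)
  set.seed(as.integer(seed))

  sizes <- vapply(sets, function(s) sum(genes %in% s), integer(1))
  if (any(sizes == 0L)) {
    stop("gene set(s) with empty intersection: ",
         paste(names(sets)[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  es_obs <- vapply(sets, function(s) {
    enrichment_score(ranked, s, weight_exponent)$es
  }, numeric(1))

  # one shared null matrix per distinct set size
  uniq_sizes <- sort(unique(sizes))
  null_by_size <- lapply(uniq_sizes, function(k) {
    vapply(seq_len(n_perm), function(i) {
      enrichment_score(ranked, sample(genes, k), weight_exponent)$es
    }, numeric(1))
  })
  names(null_by_size) <- as.character(uniq_sizes)

  normalise <- function(es, null_es) {
    mean_pos <- mean(null_es[null_es > 0])
    mean_neg <- mean(abs(null_es[null_es < 0]))
    out <- es
    out[es >= 0] <- es[es >= 0] / mean_pos
    out[es < 0] <- es[es < 0] / mean_neg
    out
  }

  nes_obs <- numeric(length(sets))
  p_nom <- numeric(length(sets))
  nes_null_all <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    e <- es_obs[i]
    same_sign <- if (e >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p_nom[i] <- if (length(same_sign)) {
      mean(abs(same_sign) >= abs(e))
    } else {
      1 / n_perm
    }
    nes_obs[i] <- normalise(e, null_es)
    nes_null_all[[i]] <- normalise(null_es, null_es)
  }
  nes_null <- unlist(nes_null_all)

  fdr <- vapply(seq_along(sets), function(i) {
    ns <- nes_obs[i]
    if (ns >= 0) {
      num_pool <- nes_null[nes_null >= 0]
      obs_pool <- nes_obs[nes_obs >= 0]
      num <- if (length(num_pool)) mean(num_pool >= ns) else 0
      den <- mean(obs_pool >= ns)
    } else {
      num_pool <- nes_null[nes_null < 0]
      obs_pool <- nes_obs[nes_obs < 0]
      num <- if (length(num_pool)) mean(num_pool <= ns) else 0
      den <- mean(obs_pool <= ns)
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(set = names(sets), size = sizes, es = es_obs, nes = nes_obs,
             p_nominal = p_nom, fdr = fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member symbols, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed GMT line (need name, description, >= 1 gene): ",
           substr(l, 1, 50), call. = FALSE)
    }
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled). Default `"na"`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(!is.null(names(sets)))
  lines <- mapply(function(nm, s) {
    paste(c(nm, description, s), collapse = "\t")
  }, names(sets), sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from a GCT (v1.2) file
#'
#' @param path GCT file path.
#' @return numeric matrix with row names from the `Name` column; the
#'   `Description` column is attached as attribute `description`.
#' @export
read_gct <- function(path) {
  header <- readLines(path, n = 3L)
  if (length(header) < 3L || !startsWith(header[1], "#1.2")) {
    stop("not a GCT 1.2 file: ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(header[2], "\t")[[1]][1:2])
  tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2]) {
    stop("GCT dimension line does not match table: ", path, call. = FALSE)
  }
  mat <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(mat) <- tab[[1]]
  attr(mat, "description") <- tab[[2]]
  mat
}

#' Write an expression matrix to a GCT (v1.2) file
#'
#' @param values numeric matrix with row and column names.
#' @param path output path.
#' @param description per-row description column. Default row names.
#' @export
write_gct <- function(values, path, description = rownames(values)) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(values)),
                   collapse = "\t"), con)
  body <- cbind(rownames(values), description,
                format(values, trim = TRUE, digits = 15))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
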