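make_matrix <- function(rows, samples = 4) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("symbol collapse keeps the brightest qualifier per symbol", {
  vals <- rbind(q1 = c(7.0, 7.2, 7.1), q2 = c(9.2, 9.3, 9.4),
                q3 = c(5.0, 5.1, 5.2), q4 = c(6.0, 6.1, 6.2))
  colnames(vals) <- paste0("s", 1:3)
  map <- data.frame(qualifier = c("q1", "q2", "q3"),
                    symbol = c("GATA2", "GATA2", "HES1"))
  out <- collapse_to_symbols(vals, map)
  expect_equal(rownames(out), c("GATA2", "HES1"))
  expect_equal(unname(out["GATA2", ]), c(9.2, 9.3, 9.4))
  expect_equal(attr(out, "n_unmapped"), 1L)  # q4 dropped
  # one qualifier per symbol: identity transform up to row order
  map1 <- data.frame(qualifier = paste0("q", 1:4),
                     symbol = paste0("G", 1:4))
  out1 <- collapse_to_symbols(vals, map1)
  expect_equal(nrow(out1), 4L)
  expect_equal(unname(out1["G1", ]), unname(vals["q1", ]))
  # collapsed row count equals the number of distinct mapped symbols
  set.seed(2)
  n <- 200
  vals2 <- matrix(rnorm(n * 4, 7), n, 4,
                  dimnames = list(sprintf("q%03d", 1:n), paste0("s", 1:4)))
  map2 <- data.frame(qualifier = rownames(vals2),
                     symbol = sprintf("G%02d", sample(60, n, replace = TRUE)))
  expect_equal(nrow(collapse_to_symbols(vals2, map2)),
               length(unique(map2$symbol)))
  expect_error(collapse_to_symbols(vals, map[0, ]), "empty")
})

test_that("fold changes are geometric-mean ratios vs vehicle", {
  vals <- rbind(g1 = c(5, 5, 7, 7, 5, 5, 5, 5),
                g2 = c(6, 6, 6, 6, 6, 6, 6, 6))
  colnames(vals) <- paste0("s", 1:8)
  cond <- rep(c("vehicle", "drug_a", "drug_b", "combination"), each = 2)
  fc <- fold_changes(vals, cond)
  expect_equal(fc$fc_a[fc$gene == "g1"], 4)
  expect_equal(fc$fc_b[fc$gene == "g1"], 1)
  expect_equal(fc$fc_a[fc$gene == "g2"], 1)
  # order invariance over samples
  perm <- sample(8)
  fc2 <- fold_changes(vals[, perm], cond[perm])
  expect_equal(fc2, fc)
  expect_error(fold_changes(vals[, 1:6], cond[1:6]), "missing condition")
})

test_that("2-fold lists are boundary-inclusive and symmetric under inversion", {
  fc <- data.frame(gene = c("g1", "g2", "g3"),
                   fc_a = c(2.0, 1.9, 0.5),
                   fc_b = 1, fc_ab = 1)
  l <- threshold_gene_lists(fc)
  expect_equal(l$a$up, "g1")
  expect_equal(l$a$down, "g3")
  expect_equal(l$b$up, character(0))
  # inverting all fold changes swaps up and down exactly
  fci <- fc
  fci[, 2:4] <- 1 / fci[, 2:4]
  li <- threshold_gene_lists(fci)
  expect_equal(li$a$up, l$a$down)
  expect_equal(li$a$down, l$a$up)
  expect_error(threshold_gene_lists(fc, threshold = 1), "threshold > 1")
})

test_that("Venn regions are disjoint and sum to the union", {
  v <- venn_counts(c("a", "b", "c"), c("b", "c", "d"), c("c", "e"))
  expect_equal(v$only_ab, 1)   # {e}
  expect_equal(v$a_b_ab, 1)    # {c}
  expect_equal(v$union, 5)
  v2 <- venn_counts(c("x", "y"), c("x", "y"), c("x", "y"))
  expect_equal(v2$a_b_ab, 2)
  expect_equal(v2$only_a + v2$only_b + v2$only_ab + v2$a_b + v2$a_ab +
                 v2$b_ab, 0)
  # property: region counts always total the union
  set.seed(31)
  for (i in 1:20) {
    pool <- sprintf("g%03d", 1:60)
    s1 <- sample(pool, sample(40, 1)); s2 <- sample(pool, sample(40, 1))
    s3 <- sample(pool, sample(40, 1))
    v <- venn_counts(s1, s2, s3)
    expect_equal(v$only_a + v$only_b + v$only_ab + v$a_b + v$a_ab + v$b_ab +
                   v$a_b_ab, v$union)
    expect_equal(length(unique(c(s1, s2, s3))), v$union)
    # combination regions reproduce the combination list size
    expect_equal(v$only_ab + v$a_ab + v$b_ab + v$a_b_ab, length(unique(s3)))
  }
})

test_that("category definitions classify canonical fold-change patterns", {
  fc <- data.frame(
    gene = c("gA", "gG", "gD", "gC", "gE", "gNone1", "gNone2", "gB"),
    fc_a = c(1.0, 2.5, 0.4, 2.5, 1.0, 1.7, 1.0, 1.2),
    fc_b = c(1.0, 2.5, 1.0, 1.0, 2.0, 1.0, 1.0, 0.9),
    fc_ab = c(4.0, 8.0, 0.2, 4.0, 3.0, 4.0, 1.2, 0.25))
  got <- classify_combination_categories(fc)
  expect_equal(as.character(got$category),
               c("A", "G", "D", "C", "E", "none", "none", "B"))
  # gNone1: fc_a = 1.7 sits between the unaffected band and the changed
  # threshold -> conservatively none even though the combination responds
})

test_that("categories are mutually exclusive and order-invariant", {
  set.seed(17)
  fc <- data.frame(gene = sprintf("g%03d", 1:300),
                   fc_a = 2^rnorm(300, 0, 1.2),
                   fc_b = 2^rnorm(300, 0, 1.2),
                   fc_ab = 2^rnorm(300, 0, 1.5))
  got <- classify_combination_categories(fc)
  expect_equal(nrow(got), 300L)
  expect_true(all(!is.na(got$category)))
  perm <- sample(300)
  got_perm <- classify_combination_categories(fc[perm, ])
  expect_equal(got_perm$category[order(got_perm$gene)],
               got$category[order(got$gene)])
})

test_that("an inconsistent filter configuration warns", {
  expect_warning(category_filter_config(t_change = 1.4,
                                        unaffected_band = 1.5),
                 "overlap")
})

test_that("row z-scoring gives population-variance-one rows and flags constants", {
  z <- zscore_rows(matrix(c(1, 2, 3), 1, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_warning(zc <- zscore_rows(rbind(c(1, 2, 3), c(5, 5, 5))),
                 "constant")
  expect_equal(unname(zc[2, ]), c(0, 0, 0))
  expect_equal(attr(zc, "constant_rows"), 2L)
  set.seed(6)
  m <- matrix(rnorm(50 * 8, 7, 2), 50, 8)
  z <- zscore_rows(m)
  expect_equal(rowMeans(z), rep(0, 50), tolerance = 1e-12)
  expect_equal(rowMeans(z^2), rep(1, 50), tolerance = 1e-12)
})

test_that("class-difference ranking is antisymmetric and shift-invariant", {
  set.seed(8)
  m <- matrix(rnorm(40 * 6, 7), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:6)))
  r <- rank_by_class_difference(m, 1:3, 4:6)
  expect_equal(r$score[r$gene == "g01"],
               mean(m["g01", 1:3]) - mean(m["g01", 4:6]))
  expect_true(all(diff(r$score) <= 0))
  swapped <- rank_by_class_difference(m, 4:6, 1:3)
  expect_equal(swapped$score[match(r$gene, swapped$gene)], -r$score)
  shifted <- rank_by_class_difference(m + 3.21, 1:3, 4:6)
  expect_equal(shifted$gene, r$gene)
  expect_equal(shifted$score, r$score, tolerance = 1e-12)
})
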