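#!/usr/bin/env Rscript
# Stage 4: combinatorial expression response and gene-set enrichment.
#
# Collapses qualifiers to symbols, computes the three fold-change
# contrasts, the >= 2-fold lists and Venn regions, the A-H category
# classification, a z-scored heatmap matrix of the classified genes, and
# GSEA (combination vs drug A) with gene-set permutation FDR.

library(combind)

fixtures <- "results/fixtures"
cond <- utils::read.csv(file.path(fixtures, "sample_conditions.csv"))$condition
res <- run_expression(file.path(fixtures, "expression_log2.gct"),
                      file.path(fixtures, "qualifier_map.tsv"),
                      cond,
                      gene_sets = file.path(fixtures, "gene_sets.gmt"),
                      n_perm = 1000, seed = 2)

dir.create("results", showWarnings = FALSE)
utils::write.csv(res$fc, "results/expression_fold_changes.csv",
                 row.names = FALSE)
utils::write.csv(res$categories, "results/expression_categories.csv",
                 row.names = FALSE)
utils::write.csv(res$enrichment, "results/expression_enrichment.csv",
                 row.names = FALSE)
write_gct(res$zscored, "results/expression_heatmap_zscores.gct")
writeLines(paste(names(res$venn), unlist(res$venn), sep = "\t"),
           "results/expression_venn_regions.tsv")

cat(sprintf("Collapsed to %d symbols (%d qualifiers unmapped)\n",
            nrow(res$collapsed), attr(res$collapsed, "n_unmapped")))
cat(sprintf("2-fold lists  drug A: %d up / %d down   drug B: %d up / %d down   combination: %d up / %d down\n",
            length(res$lists$a$up), length(res$lists$a$down),
            length(res$lists$b$up), length(res$lists$b$down),
            length(res$lists$ab$up), length(res$lists$ab$down)))
cat(sprintf("Combination-exclusive genes: %d of a %d-gene combination list\n",
            res$venn$only_ab,
            res$venn$only_ab + res$venn$a_ab + res$venn$b_ab +
              res$venn$a_b_ab))
cat("Category counts:\n")
print(res$category_counts)
top <- res$enrichment[order(res$enrichment$fdr, -abs(res$enrichment$nes)), ]
cat("Top enriched gene sets:\n")
print(utils::head(top, 3), digits = 3)
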