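#!/usr/bin/env Rscript
# One-vs-rest logistic burden association per phenotype group, across
# quality-filter tiers, with Bonferroni-significant gene counts and QQ
# inflation diagnostics. Demonstrates how WGA confounding inflates
# associations in the amplified group and how filtering deflates them.

suppressPackageStartupMessages(library(wgaQC))
co <- readRDS("scratch/cohort.rds")
enr <- readRDS("scratch/enrichment.rds")
bu <- readRDS("scratch/burden.rds")

keys <- allele_key(co$alleles)
calib <- co$alleles$qs[keys %in% co$truth_panel]
prim <- co$meta$is_primary
groups <- sort(unique(co$meta$group))
tiers <- c(0.99, 0.95, 0.90)

assoc <- lapply(tiers, function(s) {
  ret <- keys[apply_quality_filter(co$alleles, s, calib)]
  b <- build_burden(co$alleles, co$geno, bu$consequence, enr$contexts,
                    genes = co$genes, retained_keys = ret,
                    per_gene = TRUE)
  do.call(rbind, lapply(groups, function(g)
    one_vs_rest_test(b$gene_matrix[prim, , drop = FALSE],
                     co$meta[prim, , drop = FALSE], g)))
})
names(assoc) <- sprintf("TS%g", tiers * 100)

rep <- inflation_report(assoc)
cat("Bonferroni-significant genes per group and tier:\n")
print(rep$significant)
cat("\nCutoffs per tier:\n"); print(signif(rep$cutoffs, 3))
cat("\nThe confounded group (G1, aligned with WGA) dominates at the\n")
cat("lenient tier and attenuates as filtering tightens; unconfounded\n")
cat("groups stay near zero throughout.\n")

for (nm in names(assoc))
  data.table::fwrite(assoc[[nm]],
                     sprintf("results/analysis/association_%s.tsv", nm),
                     sep = "\t")
data.table::fwrite(rep$qq, "results/analysis/qq.tsv", sep = "\t")
sig <- data.frame(tier = rownames(rep$significant), rep$significant)
data.table::fwrite(sig, "results/analysis/significant_counts.tsv",
                   sep = "\t")
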