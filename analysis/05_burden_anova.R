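#!/usr/bin/env Rscript
# Per-sample LOF burden and Type II ANOVA decomposition of burden
# variance over the technical covariates, with bootstrap CIs for the
# group means.

suppressPackageStartupMessages(library(wgaQC))
co <- readRDS("scratch/cohort.rds")
enr <- readRDS("scratch/enrichment.rds")

cons <- classify_consequence(co$alleles, co$genes, co$ref)
b <- build_burden(co$alleles, co$geno, cons, enr$contexts,
                  genes = co$genes)
s <- b$samples
cat(sprintf("Median LOF burden: WGA %d vs DNA %d\n",
            median(s$lof_total[co$meta$wga]),
            median(s$lof_total[!co$meta$wga])))
for (grp in c(TRUE, FALSE)) {
  x <- s$lof_indel[co$meta$wga == grp]
  ci <- bootstrap_ci(x, reps = 1000, seed = 1)
  cat(sprintf("Mean LOF indel burden (%s): %.2f [%.2f, %.2f]\n",
              if (grp) "WGA" else "DNA", mean(x), ci[1], ci[2]))
}
cat("\nBy indel category (WGA means):\n")
w <- co$meta$wga
print(colMeans(s[w, c("lof_indel_homopolymer_plus", "lof_indel_large",
                      "lof_indel_other")]), digits = 3)

dec_i <- anova_decomposition(s$lof_indel, co$meta)
dec_s <- anova_decomposition(s$lof_snv, co$meta)
cat("\nType II ANOVA, LOF indel burden (% variance explained):\n")
print(dec_i, digits = 3)
cat("\nType II ANOVA, LOF SNV burden:\n")
print(dec_s, digits = 3)

data.table::fwrite(s, "results/analysis/burden.tsv", sep = "\t")
data.table::fwrite(dec_i, "results/analysis/anova_lof_indel.tsv", sep = "\t")
data.table::fwrite(dec_s, "results/analysis/anova_lof_snv.tsv", sep = "\t")
saveRDS(list(burden = b, consequence = cons), "scratch/burden.rds")
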