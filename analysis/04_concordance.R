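#!/usr/bin/env Rscript
# Genotype discordance between replicate samples of the same individual,
# by pair type and indel category, and evaluation of the quality-filter
# tiers against the concordant/discordant partition and the truth panel.

suppressPackageStartupMessages(library(wgaQC))
co <- readRDS("scratch/cohort.rds")
enr <- readRDS("scratch/enrichment.rds")
ctx <- enr$contexts

pd <- pairwise_discordance(co$geno, co$pairs, co$alleles, ctx)
cat("Median indel discordance by pair type:\n")
print(discordance_by_pair_type(pd, "indel"), digits = 3)
cat("\nBy indel category (WGA:WGA pairs):\n")
ww <- pd[pd$pair_type == "WGA:WGA", ]
print(vapply(c("homopolymer_plus", "large", "other"),
             function(cl) median(ww[[cl]], na.rm = TRUE), numeric(1)),
      digits = 3)
out <- flag_outlier_pairs(pd)
if (any(out)) cat(sprintf("\n%d pair(s) exceed the discordance ceiling\n",
                          sum(out)))

keys <- allele_key(co$alleles)
calib <- co$alleles$qs[keys %in% co$truth_panel]
tiers <- c(0.99, 0.95, 0.90)
ev <- do.call(rbind, lapply(tiers, function(s) {
  ret <- keys[apply_quality_filter(co$alleles, s, calib)]
  cbind(filter = sprintf("TS%g", s * 100),
        evaluate_filter(co$geno, co$pairs, co$alleles, ret,
                        co$truth_panel))
}))
cat("\nFilter evaluation (stricter tiers remove more of both classes):\n")
print(ev, digits = 3)

data.table::fwrite(pd, "results/analysis/discordance_pairs.tsv", sep = "\t")
data.table::fwrite(ev, "results/analysis/filter_eval.tsv", sep = "\t")
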