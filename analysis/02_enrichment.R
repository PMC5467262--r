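#!/usr/bin/env Rscript
# Call WGA-enriched indel alleles with the one-sided Fisher screen and
# summarize the indel taxonomy by enrichment status.

suppressPackageStartupMessages(library(wgaQC))
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)
co <- readRDS("scratch/cohort.rds")

en <- call_enriched(co$alleles, co$geno, co$meta)
thr <- attr(en, "threshold")
cat(sprintf("Enrichment threshold (WGA-only singleton p): %.4f\n", thr))
cat(sprintf("%d of %d indel alleles called WGA-enriched\n",
            sum(en$enriched), nrow(en)))

led <- co$ledger[match(en$key, co$ledger$key), ]
art <- led$origin != "true_variant"
cat(sprintf("Sensitivity on ledgered artifact sites: %.3f\n",
            mean(en$enriched[art])))
cat(sprintf("Fraction of enriched calls that are ledgered artifacts: %.3f\n",
            mean(art[en$enriched])))

ind <- co$alleles$type != "SNV"
ctx <- classify_indels(co$alleles[ind, ], co$ref)
lab <- ifelse(en$enriched[match(ctx$key, en$key)], "WGA-enriched",
              "non-enriched")
ts <- taxonomy_summary(ctx, lab)
cat("\nIndel taxonomy by enrichment status (fractions):\n")
print(ts$fractions, digits = 3)

enr_keys <- en$key[en$enriched]
sel <- allele_key(co$alleles) %in% enr_keys
ct <- enrichment_af_contrast(co$alleles[sel, ], co$geno[sel, , drop = FALSE],
                             co$meta, ctx, seed = 1)
cat("\nMean WGA allele frequency among enriched indels,",
    "homopolymer+ vs other:\n")
print(ct, digits = 3)
cat(sprintf("Contrast (homopolymer+ minus other): %.4f\n",
            attr(ct, "contrast")))

data.table::fwrite(en, "results/analysis/enrichment.tsv", sep = "\t")
data.table::fwrite(ctx, "results/analysis/indel_contexts.tsv", sep = "\t")
data.table::fwrite(ts$fractions, "results/analysis/taxonomy_by_enrichment.tsv",
                   sep = "\t")
saveRDS(list(enrichment = en, contexts = ctx), "scratch/enrichment.rds")
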