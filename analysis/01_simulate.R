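#!/usr/bin/env Rscript
# Simulate the default synthetic cohort: ~2,000 diploid exome samples
# over 200 genes, with a WGA subgroup carrying homopolymer slippage
# indels, chimeric large insertions and coverage dropout, and one
# phenotype group (G1) confounded with amplification.

suppressPackageStartupMessages(library(wgaQC))
dir.create("results/simulation", recursive = TRUE, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)
print(cohort)

write_reference_fasta(cohort$ref, "results/simulation/reference.fa")
write_genes_bed(cohort$genes, "results/simulation/genes.bed")
data.table::fwrite(cohort$meta, "results/simulation/meta.tsv", sep = "\t")
data.table::fwrite(cohort$ledger, "results/simulation/ledger.tsv",
                   sep = "\t")
write_vcf(cohort$alleles, cohort$geno, "results/simulation/cohort.vcf",
          contig_lengths = setNames(ref_length(cohort$ref),
                                    cohort$ref$name))
writeLines(cohort$truth_panel, "results/simulation/truth_panel.txt")
saveRDS(cohort, "scratch/cohort.rds")

tab <- table(cohort$ledger$origin)
cat("\nAllele origins:\n"); print(tab)
cat(sprintf("WGA samples: %d of %d; group G1 is %.0f%% WGA\n",
            sum(cohort$meta$wga), nrow(cohort$meta),
            100 * mean(cohort$meta$wga[cohort$meta$group == "G1"])))
cat("Outputs in results/simulation/; cohort cached in scratch/cohort.rds\n")
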