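# wgaQC — detecting whole-genome-amplification artifacts in germline variant calls

Whole genome amplification (WGA) by multiple displacement amplification
(MDA) is used when too little DNA is available for direct sequencing.
It leaves fingerprints in cohort-scale germline variant calls:
recurrent small indels at homopolymer tracts (polymerase slippage),
large insertions whose sequence is copied from reference a short
distance away (chimeric rearrangements), and missing genotypes from
highly uneven coverage. Because these artifact indels rarely preserve
the reading frame, they inflate per-sample **loss-of-function (LOF)
burden** — and when amplification is correlated with a phenotype
(whole disease cohorts were amplified), they manufacture spurious
burden–phenotype associations that survive standard variant filtering.

`wgaQC` is for analysts who need to quantify and demonstrate this
failure mode. It provides a synthetic diploid exome cohort simulator
with a per-allele truth ledger, plus the detection analyses:

| stage | core quantity |
|---|---|
| indel taxonomy | `HOMOPOLYMER_PLUS` (single-base indel with a ≥4-run of that base within ±1 bp of the indel start), `LARGE` (≥15 bp), `OTHER` |
| WGA enrichment | one-sided Fisher exact p on the 2×2 allele-count table (alt/ref × WGA/DNA); threshold = singleton p = n_wga / (n_wga + n_dna) |
| chimera search | best ungapped match of the inserted sequence within ±10 kb; for deletions the deleted span itself is excluded |
| replicate discordance | 1 − \|A∩B\| / \|A∪B\| over call sets keyed by (position, alt), zygosity disregarded |
| burden ANOVA | Type II sums of squares of LOF burden over c20x, WGA, center, BWA version, race; % variance = factor SS / total SS |
| association | per gene g and group k: `glm(1[group=k] ~ burden_g + race + age, binomial)`, Bonferroni cutoff α/(n_groups × n_genes) |

## Worked example

```r
library(wgaQC)

# the enrichment threshold for a 614-WGA / 9004-DNA cohort
singleton_threshold(614, 9004)
#> [1] 0.06383864        # printed to three decimals: 0.063

# simulate the default confounded cohort and call enriched indels
cohort <- simulate_cohort(sim_config(seed = 1))
cohort
#> <wga_cohort> 3043 alleles x 2026 samples (453 WGA), 200 genes, 63 replicate pairs

en <- call_enriched(cohort$alleles, cohort$geno, cohort$meta)
sum(en$enriched)
#> [1] 1405
```

Against the truth ledger, 94.2% of injected artifact sites are called
enriched and 96.8% of enriched calls are ledgered artifacts. The
taxonomy splits cleanly by enrichment status (fractions per row):

```
         label    n frac_other frac_homopolymer frac_large frac_mod3
  non-enriched  356      0.764           0.0562      0.180     0.553
  WGA-enriched 1405      0.032           0.5673      0.401     0.361
```

Enriched indels are dominated by homopolymer+ and large indels and show
no reading-frame preservation (mod-3 fraction ≈ 1/3), while
non-enriched (mostly true) indels are frame-biased. Copy-origin search
finds a perfect proximal match for every simulated chimeric insertion
(median distance 883 bp, 80% within 2 kb) and — by construction of the
exclusion rule — none for large deletions. Median indel discordance
steps 0.000 → 0.488 → 0.687 across DNA:DNA → WGA:DNA → WGA:WGA
replicate pairs, and Type II ANOVA attributes 60.7% of LOF indel burden
variance to WGA (0.15% for LOF SNV burden). In the WGA-confounded
phenotype group the count of Bonferroni-significant genes falls
22 → 7 → 4 across quality tiers TS99 → TS95 → TS90 while unconfounded
groups stay at zero.

The numbered drivers under `analysis/` run these stages end to end and
write the tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort, VCF, metadata, truth ledger
Rscript analysis/02_enrichment.R    # Fisher screen + taxonomy
Rscript analysis/03_chimera.R       # copy-origin search
Rscript analysis/04_concordance.R   # replicate discordance + filter metrics
Rscript analysis/05_burden_anova.R  # LOF burden + variance decomposition
Rscript analysis/06_association.R   # one-vs-rest association across tiers
```

`run_pipeline(sim_config(seed = 1), out_dir = "out")` performs the same
sweep in one call and writes a versionable `summary.json`.

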