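---
title: "Detecting whole-genome-amplification artifacts in germline variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting whole-genome-amplification artifacts in germline variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multiple displacement amplification (MDA), the chemistry behind whole
genome amplification (WGA) of limited DNA, introduces characteristic
errors into downstream exome sequencing: polymerase slippage at
homopolymer tracts, chimeric rearrangements that join noncontiguous
stretches of the template, and highly uneven coverage. In cohort-scale
germline variant calls these errors surface as

* recurrent 1–6 bp indels adjacent to homopolymer runs,
* large (>= 15 bp) insertions whose inserted sequence is a verbatim copy
  of reference sequence a short distance away, and
* missing genotypes in genes whose amplified coverage collapsed.

Because slippage and chimera indels rarely respect the reading frame,
they are preferentially annotated as frameshift — i.e.
loss-of-function (LOF) — variants. When amplification is correlated
with a phenotype (entire cohorts of some cancer types were amplified),
the inflated LOF indel burden masquerades as burden–phenotype
association. `wgaQC` simulates such cohorts with a per-allele truth
ledger and implements the analyses that expose the artifact classes.

## The synthetic cohort

`sim_config()` / `simulate_cohort()` generate one contig carrying
`n_genes` single-exon, plus-strand genes (single-exon genes are the
simplest structure that exercises every downstream stage; splice and
strand complexity contribute nothing to the artifact mechanisms being
studied). The background sequence is drawn with runs capped at two
bases and homopolymer tracts of length 4–8 are injected at
`hp_tract_density` with flanks forced to differ, so the maximal-run
density observed by `scan_homopolymers()` is the configured density
rather than the much higher density of unconstrained random sequence.

True variants are shared across all samples at a Beta allele-frequency
spectrum and genotyped per individual under Hardy–Weinberg draws.
True coding indels are in-frame (length divisible by 3) with
probability `inframe_bias` (default 0.6), reflecting purifying
selection on frameshifts; artifact indels draw their lengths uniformly
from supports whose size is a multiple of three (1–6 for slippage,
15–44 for chimeras), so their mod-3 fraction has expectation exactly
1/3 — no frame selection.

The three artifact classes are injected **only into WGA samples**:

* **Homopolymer slippage.** Each tract receives a propensity
  `hp_error_rate * Gamma(shape = hp_recurrence, rate = hp_recurrence)`
  (mean `hp_error_rate`) and one canonical slippage allele (insertion
  or deletion of 1–6 copies of the tract base). Every WGA sample
  carries the tract's allele independently with that propensity. The
  Gamma propensity is the exchangeable tract-propensity scheme chosen
  here: with a small shape (default 0.3) it is heavy-tailed, so a few
  tracts slip in many WGA samples and reach high artifact allele
  frequency — the recurrence that drives both the elevated WGA allele
  frequency of homopolymer+ indels and the gene-level association
  signal.
* **Chimeric large indels.** Per WGA sample, `Poisson(chimera_rate)`
  events, mostly insertions (`chimera_insertion_frac = 0.85`): a
  15–44 bp sequence copied in forward orientation from the reference
  at an exponential distance (`chimera_origin_scale = 1200` bp, hard
  cap 10 kb), so most copy-origins lie within 2 kb. Deletion artifacts
  are rare and carry no copy-origin by construction. Candidate
  representations that are not already left-aligned are redrawn so
  ledgered positions and normalized VCF positions agree.
* **Coverage dropout.** Per sample and gene, depth is Normal truncated
  at zero — mean 165x with standard deviation 140x for WGA samples
  versus 40x for unamplified ones — and all genotypes in a gene fall
  missing when depth drops below `missing_threshold` (10x). Dropout is
  all-or-none per gene; within-gene partial dropout adds nothing the
  analyses would distinguish.

Replicate samples of one individual share the individual's true
genotypes but re-draw artifacts and missingness independently, which is
what makes WGA:WGA pairs the most discordant.

Site quality scores are Normal: mean 10 (sd 1) for true alleles, mean 8
for artifacts. The overlap is deliberate — tiers of the
quality filter trade removal of discordant (artifact) indels against
removal of concordant (true) ones, rather than separating the classes
cleanly, which is the regime the filter-evaluation analysis is about.

One phenotype group (`G1`) is confounded with amplification: WGA
individuals land in `G1` with probability `phenotype_confound` (default
0.95, matching cohorts in which practically every affected sample was
amplified), unamplified individuals with probability `dna_g1_frac`
(0.05).

### Default scale and calibration

The default cohort is ~2,026 samples (1,500 DNA + 400 WGA singletons,
plus 30 DNA:DNA, 13 WGA:DNA and 20 WGA:WGA replicate pairs) over 200
genes of 1,500 coding bases. Artifact rates (`hp_error_rate = 0.012`
per tract per WGA sample, `chimera_rate = 1.5` per sample) were fixed
once, during design, so that the default cohort reproduces the
qualitative regime the analyses target: WGA explains more than half of
the LOF indel burden variance while leaving LOF SNV burden untouched;
median WGA:WGA indel discordance sits near 60% and steps down through
WGA:DNA to DNA:DNA; and the confounded group shows dozens of spurious
Bonferroni-significant genes at the lenient filter tier, attenuating
with stringency. They are conditions of the simulated study, not
tuning knobs; the package reports whatever a given configuration
produces.

### What the generator does not emulate

No read-level simulation (no FASTQ/BAM, no mapping error), no somatic
variation, no population structure beyond a categorical ancestry label,
no linkage disequilibrium (sites are independent), no genotyping
uncertainty (dosages are exact), single-exon genes only, and chimera
copies in forward orientation only. Passing tests therefore show that
the analysis machinery recovers the artifact structure it formalizes —
not that it would recover every artifact in real amplified exomes,
where alignment error and context effects blur all of these signals.

## The analyses

**Indel taxonomy.** An indel is `LARGE` when 15 or more bases are
inserted or deleted; length takes precedence, making the classes
mutually exclusive. A shorter indel is homopolymer-eligible when its
inserted/deleted bases are all one base type, and `HOMOPOLYMER_PLUS`
when a run of >= 4 consecutive copies of that base starts within one
base of the indel start. The run is sought in the *reference* sequence
only — not in the alternate haplotype the insertion would create; the
choice is conservative and symmetric between insertions and deletions.
Because indels are left-aligned first, an indel inside or immediately
right of a run anchors at the run's left edge, which is what the
±1 bp window is checking. Everything else is `OTHER`.

**WGA enrichment.** For each indel allele, a 2x2 table of alternate
vs reference allele counts in WGA vs DNA samples, with reference
counts `2 * (non-missing samples) - alt`. The one-sided (upper-tail
hypergeometric) Fisher p is compared against the singleton threshold —
the p of one alternate allele found only in the WGA group,
`n_wga / (n_wga + n_dna)` in closed form. A WGA-only singleton with no
missing genotypes sits *exactly at* this threshold, so the default
flag is `p <= threshold`; `mode = "strict"` reproduces the printed
`p < threshold` convention, under which an isolated singleton is not
enriched. Missing genotypes shrink a group's diploid total rather than
being imputed, consistent with joint-calling semantics that distinguish
no-call from homozygous reference. The screen is deliberately
uncorrected for multiple testing: it is a labeling rule for
characterizing artifact candidates, not an inference procedure.

**Chimera origin search.** For each large indel, the inserted (or
deleted) sequence is aligned, ungapped, against the reference within
10 kb of the indel start — the proximal region within which MDA
chimeras act. Ungapped identity suffices because chimeric insertions
are verbatim copies; `min_identity` (default 0.9) admits near-matches.
For deletions, candidates overlapping the deleted span are excluded —
the deleted bases trivially match their own reference. Best match =
highest identity, ties to the smaller distance; reverse-complement
search sits behind a flag and is off by default. The production
matcher (mismatch-tolerant exact matching from Biostrings) is checked
against an exhaustive sliding-window scan in the tests.

**Replicate discordance.** `1 - |A ∩ B| / |A ∪ B|` over call sets
keyed by position and alternate allele, zygosity disregarded; both
sets empty is undefined (`NA`), not zero. Missing genotypes count as
absent calls, which is precisely how coverage dropout converts depth
variability into discordance. Filters are evaluated by the fraction of
discordant and of concordant indel instances they remove, plus the
truth-panel overlap of retained indels (the panel — a random 70% of
true alleles — stands in for an external database of validated
variants).

**Burden and variance decomposition.** Per-sample LOF (stop-gained or
frameshift) dosage at sites with cohort allele frequency strictly
below 0.05, total, by variant class, by indel category, and per gene.
The burden response enters a linear model on `c20x` (continuous),
`wga`, `center`, `bwa_version` and `race` (dummy-coded factors, first
level as reference, no interactions); Type II sums of squares
(each factor after all others, via `car::Anova`) are divided by the
total of the table's sums of squares including the residual, so the
shares plus the residual share sum to one. Raw counts are used as the
response; aliased (perfectly confounded) factors raise an error naming
the pair rather than being dropped silently. Bootstrap intervals for
means are the basic (reflected percentile) construction from 1,000
resamples.

**Association.** One-vs-rest logistic regression per gene and group:
`glm(group indicator ~ gene LOF burden + race + age, binomial)`, genes
eligible only with at least two carriers, sex-specific groups
restricted to the stated sex, individuals with missing covariates
dropped (and counted). The reported p is the Wald p of the burden
coefficient. Complete separation — routine for rare burdens — is
detected (non-convergence, divergent coefficients, or the fitted-
probability warning) and re-fit with a hand-rolled Firth-penalized
(Jeffreys prior, hat-adjusted score) Newton iteration; such genes are
flagged. The Bonferroni cutoff is `alpha / (n_groups * n_genes)` with
the actually-tested gene count by default and an optional fixed
denominator for the rounded convention. `inflation_report()` returns
QQ coordinates (`-log10` expected vs observed p), per-group significant
counts and cross-group overlap of significant gene sets.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; 1-based only in VCF.
* Normalization trims shared suffixes (borrowing upstream reference
  bases when a side would empty, which left-aligns indels) and then
  shared prefixes beyond the anchor base. Multi-allelic records are
  split per ALT before normalization; per-allele dosage counts only
  that ALT, so a `1/2` genotype contributes one copy to each record.
* Variants overlapping an exon boundary are `noncoding` rather than
  partially evaluated; a trailing partial codon (not produced by the
  simulator) classifies as `silent`.
* The quality filter retains alleles scoring at least the
  `(1 - stringency)` quantile of the truth-panel calibration scores;
  `stringency = 1` retains everything. Tiers are nested by
  construction. The Gaussian-mixture machinery of production variant
  recalibration is intentionally not reproduced — only the property
  downstream analyses consume (tiered truth sensitivity) is.
* All randomness derives from one seed through named substreams
  (`substream_seed`), so each simulation stage is independently
  reproducible and a re-run is byte-identical.
* Degenerate inputs are signalled, not silently absorbed: empty call
  sets give `NA` discordance, an all-missing genotype vector gives `NA`
  frequency with a warning, a constant vector gives a zero-width
  bootstrap interval, a filter retaining nothing flags its truth-panel
  overlap as undefined.

## Problem sizes used by the test suite

The checked-in tests run the default ~2,026 x 200 cohort once for the
artifact-recovery and confounding checks; oracle equivalences use every
2x2 table with total at most 60, ten thousand random indels against an
independent character scan, sequences up to 100 kb against a naive run
scan, and 200 simulated chimeras against an exhaustive sliding-window
scan. Null calibration uses 200 artifact-free cohorts of 300 samples x
40 genes (family-wise error at the Bonferroni cutoff) and one 600 x 400
cohort with permuted labels (Kolmogorov–Smirnov uniformity). These
sizes were chosen as the smallest at which the checked properties are
statistically stable.

## Known limitations

The enrichment screen's sensitivity depends on dropout asymmetry when
artifacts are singletons (a WGA-only singleton sits exactly on the
threshold; DNA-side missingness could push it over). The ungapped
origin matcher understates match rates for diverged or gapped copies —
sufficient here because simulated chimeras are verbatim, but a gapped
aligner would be needed for real data. Wald p-values from rare-carrier
logistic fits are conservative near the null and the Firth fallback's
Wald intervals are approximate. The Type II decomposition's variance
shares are exact only for balanced designs; for the simulated
covariates the factors are nearly orthogonal and the shares are
interpretable as reported.

```{r example}
library(wgaQC)
cohort <- simulate_cohort(sim_config(seed = 1))
bundle <- run_pipeline(sim_config(seed = 1), out_dir = "wgaqc-out")
str(bundle$summary)
```
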