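# Shared simulated cohorts, built once per test run and annotated with
# consequences / contexts / enrichment on demand.

.cohort_cache <- new.env(parent = emptyenv())

annotate_cohort <- function(co) {
  co$consequence <- classify_consequence(co$alleles, co$genes, co$ref)
  ind <- co$alleles$type != "SNV"
  co$contexts <- classify_indels(co$alleles[ind, , drop = FALSE], co$ref)
  co$keys <- allele_key(co$alleles)
  co
}

# small cohort for unit tests
tiny_cohort <- function() {
  if (is.null(.cohort_cache$tiny)) {
    cfg <- sim_config(seed = 7, n_genes = 30, n_dna_samples = 120,
                      n_wga_samples = 40, n_pairs_dna_dna = 5,
                      n_pairs_wga_dna = 3, n_pairs_wga_wga = 4)
    .cohort_cache$tiny <- annotate_cohort(simulate_cohort(cfg))
  }
  .cohort_cache$tiny
}

# the default study conditions (~2,000 samples x 200 genes)
default_cohort <- function() {
  if (is.null(.cohort_cache$default)) {
    .cohort_cache$default <- annotate_cohort(simulate_cohort(
      sim_config(seed = 1)))
  }
  .cohort_cache$default
}

# artifact-free, balanced-group cohort for null calibration
null_config <- function(seed, n_genes = 40L, n_dna = 300L, ...) {
  sim_config(seed = seed, n_genes = n_genes, gene_length = 1500,
             n_dna_samples = n_dna, n_wga_samples = 0,
             n_pairs_dna_dna = 0, n_pairs_wga_dna = 0,
             n_pairs_wga_wga = 0, n_groups = 4,
             phenotype_confound = 0.25, dna_g1_frac = 0.25,
             hp_error_rate = 0, chimera_rate = 0, ...)
}

# group labels for significant-gene counting
count_significant <- function(res, cutoff) {
  tapply(res$tested & !is.na(res$p) & res$p < cutoff, res$group, sum)
}

association_by_tier <- function(co, tiers, af_max = 0.05) {
  calib <- co$alleles$qs[co$keys %in% co$truth_panel]
  prim <- co$meta$is_primary
  groups <- sort(unique(co$meta$group))
  out <- lapply(tiers, function(s) {
    ret <- co$keys[apply_quality_filter(co$alleles, s, calib)]
    b <- build_burden(co$alleles, co$geno, co$consequence, co$contexts,
                      genes = co$genes, af_max = af_max,
                      retained_keys = ret, per_gene = TRUE)
    do.call(rbind, lapply(groups, function(g)
      one_vs_rest_test(b$gene_matrix[prim, , drop = FALSE],
                       co$meta[prim, , drop = FALSE], g)))
  })
  names(out) <- paste0("TS", tiers * 100)
  out
}
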