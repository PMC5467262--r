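#' Simulation configuration
#'
#' Parameters of the synthetic diploid exome cohort. The defaults
#' define a cohort of roughly 2,000 samples over 200 single-exon genes
#' in which a WGA subgroup carries the three artifact classes that
#' multiple displacement amplification induces: recurrent slippage
#' indels at homopolymer tracts, large (>= 15 bp) insertions copied from
#' nearby reference sequence, and highly variable per-gene depth causing
#' missing genotypes; non-WGA samples carry true coding indels biased
#' toward in-frame lengths.
#'
#' @param seed integer; one global seed, from which every stage derives
#'   a named substream.
#' @param n_genes,gene_length gene count and coding length (bp; rounded
#'   up to a codon multiple).
#' @param intergenic gap between genes (bp).
#' @param contig_length optional fixed contig length; error if the gene
#'   layout does not fit. Default `NULL` sizes the contig to the layout.
#' @param n_dna_samples,n_wga_samples singleton individuals per
#'   preparation.
#' @param n_pairs_dna_dna,n_pairs_wga_dna,n_pairs_wga_wga replicate-pair
#'   individuals contributing two samples each.
#' @param n_groups number of phenotype groups (`G1`, `G2`, ...).
#' @param phenotype_confound probability a WGA individual is assigned to
#'   group `G1`, aligning that group with amplification (as in cohorts
#'   where practically every affected sample was amplified); non-WGA
#'   individuals enter `G1` with probability `dna_g1_frac`.
#' @param dna_g1_frac see above.
#' @param true_snv_rate,true_indel_rate per-bp per-cohort site rates for
#'   true variants (before dropping monomorphic draws).
#' @param af_shape1,af_shape2 Beta parameters of the allele-frequency
#'   spectrum of true variants.
#' @param inframe_bias probability a true coding indel has length
#'   divisible by 3.
#' @param hp_tract_density injected homopolymer tracts per bp.
#' @param hp_error_rate mean per-tract per-WGA-sample slippage
#'   probability.
#' @param hp_recurrence Gamma concentration of tract-specific slippage
#'   propensities; small values give a heavy tail, making some tracts
#'   recurrent (high artifact allele frequency) across WGA samples.
#' @param chimera_rate expected chimeric large-indel artifacts per WGA
#'   sample.
#' @param chimera_origin_scale exponential scale (bp) of the copy-origin
#'   distance; the default puts most origins within 2 kb.
#' @param chimera_origin_cap hard cap on origin distance (bp).
#' @param chimera_insertion_frac fraction of chimera artifacts that are
#'   insertions (deletions are rare).
#' @param depth_mean_dna,depth_sd_dna,depth_mean_wga,depth_sd_wga
#'   per-gene depth model (Normal truncated at 0) per preparation; the
#'   WGA standard deviation mirrors the highly variable amplified
#'   coverage (mean 165x, sd 140x).
#' @param missing_threshold per-gene depth below which all genotypes in
#'   the gene are missing for that sample.
#' @param qs_mean_true,qs_mean_artifact,qs_sd site quality score model;
#'   artifacts score lower on average, overlapping the true
#'   distribution so filtering trades sensitivity for specificity.
#' @param truth_panel_frac fraction of true alleles included in the
#'   simulated truth panel (the external-database stand-in).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L, gene_length = 1500L,
                       intergenic = 600L, contig_length = NULL,
                       n_dna_samples = 1500L, n_wga_samples = 400L,
                       n_pairs_dna_dna = 30L, n_pairs_wga_dna = 13L,
                       n_pairs_wga_wga = 20L,
                       n_groups = 4L,
                       phenotype_confound = 0.95, dna_g1_frac = 0.05,
                       true_snv_rate = 0.005, true_indel_rate = 0.0012,
                       af_shape1 = 0.15, af_shape2 = 8,
                       inframe_bias = 0.6,
                       hp_tract_density = 1 / 300,
                       hp_error_rate = 0.012, hp_recurrence = 0.3,
                       chimera_rate = 1.5,
                       chimera_origin_scale = 1200,
                       chimera_origin_cap = 10000,
                       chimera_insertion_frac = 0.85,
                       depth_mean_dna = 165, depth_sd_dna = 40,
                       depth_mean_wga = 165, depth_sd_wga = 140,
                       missing_threshold = 10,
                       qs_mean_true = 10, qs_mean_artifact = 8,
                       qs_sd = 1,
                       truth_panel_frac = 0.7) {
  cfg <- as.list(environment())
  probs <- c("phenotype_confound", "dna_g1_frac", "true_snv_rate",
             "true_indel_rate", "inframe_bias", "hp_tract_density",
             "hp_error_rate", "chimera_insertion_frac",
             "truth_panel_frac")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  counts <- c("n_genes", "n_dna_samples", "n_wga_samples",
              "n_pairs_dna_dna", "n_pairs_wga_dna", "n_pairs_wga_wga")
  for (p in counts)
    if (cfg[[p]] < 0) stop(p, " must be >= 0")
  if (cfg$n_groups < 2) stop("need at least 2 phenotype groups")
  if (cfg$depth_sd_dna < 0 || cfg$depth_sd_wga < 0)
    stop("depth_sd must be >= 0")
  if (cfg$gene_length < 3) stop("gene_length must be >= 3")
  cfg$gene_length <- as.integer(3 * ceiling(cfg$gene_length / 3))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

# independent, reproducible substream seed per named stage
substream_seed <- function(seed, name) {
  (as.integer(seed) * 7919L +
     sum(utf8ToInt(name)) * 131L) %% 2147483563L
}
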