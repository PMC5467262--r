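#' Run the full artifact-detection pipeline on a simulated cohort
#'
#' End-to-end driver: simulate a cohort, classify indel contexts, call
#' WGA-enriched indels, search chimera copy-origins for large indels,
#' compute replicate discordance and filter evaluations across quality
#' tiers, build LOF burdens with Type II ANOVA decompositions, and run
#' one-vs-rest burden association per group and tier. Writes one TSV
#' per stage plus a machine-readable JSON of headline numbers; the
#' bundle is deterministic given the configured seed.
#'
#' @param config a [sim_config()], a list of `sim_config()` arguments,
#'   or a path to a YAML file with top-level keys `sim` (arguments),
#'   `tiers` (stringency tiers, default `c(0.99, 0.95, 0.90)`) and
#'   `af_max` (default 0.05).
#' @param out_dir output directory (created if needed). `NULL` skips all
#'   file output and just returns the bundle.
#' @param write_vcf_file also write the cohort VCF (off by default; the
#'   matrix form in the returned bundle is the working representation).
#' @return invisible list with every stage's tables and the `summary`
#'   list written to `summary.json`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         write_vcf_file = FALSE) {
  tiers <- c(0.99, 0.95, 0.90)
  af_max <- 0.05
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    if (!is.null(y$tiers)) tiers <- as.numeric(y$tiers)
    if (!is.null(y$af_max)) af_max <- as.numeric(y$af_max)
    config <- do.call(sim_config, if (is.null(y$sim)) list() else y$sim)
  } else if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, config)
  }
  emit <- function(...) message("[wgaQC] ", ...)

  emit("simulating cohort (seed ", config$seed, ")")
  cohort <- simulate_cohort(config)
  alleles <- cohort$alleles; geno <- cohort$geno; meta <- cohort$meta
  keys <- allele_key(alleles)

  emit("annotating consequences and indel contexts")
  consequence <- classify_consequence(alleles, cohort$genes, cohort$ref)
  indels <- alleles$type != "SNV"
  contexts <- classify_indels(alleles[indels, , drop = FALSE], cohort$ref)

  enrich <- NULL
  if (any(meta$wga)) {
    emit("calling WGA-enriched indels")
    enrich <- call_enriched(alleles, geno, meta)
  } else emit("no WGA samples: enrichment stage skipped")

  emit("searching chimera copy-origins for large indels")
  large <- alleles[indels & alleles$indel_len >= 15L, , drop = FALSE]
  hits <- if (nrow(large)) find_origins(large, cohort$ref) else NULL

  calib_qs <- alleles$qs[keys %in% cohort$truth_panel]
  retained <- lapply(tiers, function(s)
    keys[apply_quality_filter(alleles, s, calib_qs)])
  names(retained) <- paste0("TS", tiers * 100)

  disc <- disc_unfiltered <- filter_eval <- NULL
  if (nrow(cohort$pairs) > 0) {
    emit("replicate discordance and filter evaluation")
    disc <- lapply(retained, function(k)
      pairwise_discordance(geno, cohort$pairs, alleles, contexts,
                           retained_keys = k))
    disc_unfiltered <- pairwise_discordance(geno, cohort$pairs, alleles,
                                            contexts)
    filter_eval <- do.call(rbind, lapply(names(retained), function(nm)
      cbind(filter = nm,
            evaluate_filter(geno, cohort$pairs, alleles, retained[[nm]],
                            cohort$truth_panel))))
  } else emit("no replicate pairs: concordance stage skipped")

  emit("LOF burden and variance decomposition")
  burden <- build_burden(alleles, geno, consequence, contexts,
                         genes = cohort$genes, af_max = af_max)
  # constant covariates (e.g. wga in an unamplified cohort) carry no
  # variance and are dropped from the decomposition
  anova_factors <- Filter(function(f) length(unique(meta[[f]])) > 1,
                          c("c20x", "wga", "center", "bwa_version", "race"))
  safe_anova <- function(y, what) {
    if (stats::var(y) == 0) {
      emit("constant ", what, " burden: variance decomposition skipped")
      return(NULL)
    }
    anova_decomposition(y, meta, factors = anova_factors)
  }
  anova_indel <- safe_anova(burden$samples$lof_indel, "LOF indel")
  anova_snv <- safe_anova(burden$samples$lof_snv, "LOF SNV")

  emit("one-vs-rest burden association per tier")
  prim <- meta$is_primary
  groups <- sort(unique(meta$group))
  assoc_by_tier <- lapply(retained, function(k) {
    b <- build_burden(alleles, geno, consequence, contexts,
                      genes = cohort$genes, af_max = af_max,
                      retained_keys = k, per_gene = TRUE)
    do.call(rbind, lapply(groups, function(g)
      one_vs_rest_test(b$gene_matrix[prim, , drop = FALSE],
                       meta[prim, , drop = FALSE], g)))
  })
  inflation <- inflation_report(assoc_by_tier)

  summary <- list(
    n_samples = nrow(meta), n_wga = sum(meta$wga),
    n_alleles = nrow(alleles), n_indels = sum(indels),
    enrichment_threshold = if (!is.null(enrich))
      attr(enrich, "threshold") else NA,
    n_enriched = if (!is.null(enrich)) sum(enrich$enriched) else NA,
    median_lof_burden_wga = stats::median(
      burden$samples$lof_total[meta$wga]),
    median_lof_burden_dna = stats::median(
      burden$samples$lof_total[!meta$wga]),
    median_indel_discordance = if (!is.null(disc_unfiltered)) as.list(
      discordance_by_pair_type(disc_unfiltered)) else NULL,
    anova_pct_wga_indel = if (!is.null(anova_indel) &&
                                "wga" %in% anova_indel$term)
      anova_indel$pct_var_explained[anova_indel$term == "wga"] else NA,
    anova_pct_wga_snv = if (!is.null(anova_snv) &&
                              "wga" %in% anova_snv$term)
      anova_snv$pct_var_explained[anova_snv$term == "wga"] else NA,
    chimera_match_rate = if (!is.null(hits)) mean(hits$matched) else NA,
    n_significant = lapply(seq_len(nrow(inflation$significant)),
                           function(i) as.list(inflation$significant[i, ])),
    tiers = tiers)
  names(summary$n_significant) <- rownames(inflation$significant)

  bundle <- list(cohort = cohort, consequence = consequence,
                 contexts = contexts, enrichment = enrich,
                 chimera_hits = hits, discordance = disc,
                 discordance_unfiltered = disc_unfiltered,
                 filter_eval = filter_eval, burden = burden,
                 anova_indel = anova_indel, anova_snv = anova_snv,
                 association = assoc_by_tier, inflation = inflation,
                 summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) data.table::fwrite(x, file.path(out_dir, f),
                                           sep = "\t")
    write_reference_fasta(cohort$ref, file.path(out_dir, "reference.fa"))
    if (!is.null(cohort$genes))
      write_genes_bed(cohort$genes, file.path(out_dir, "genes.bed"))
    w(meta, "meta.tsv")
    w(cohort$ledger, "ledger.tsv")
    w(cbind(alleles, consequence = consequence), "alleles.tsv")
    w(contexts, "indel_contexts.tsv")
    if (!is.null(enrich)) w(enrich, "enrichment.tsv")
    if (!is.null(hits)) w(hits, "chimera_hits.tsv")
    for (nm in names(disc)) w(disc[[nm]], paste0("discordance_", nm, ".tsv"))
    if (!is.null(filter_eval)) w(filter_eval, "filter_eval.tsv")
    w(burden$samples, "burden.tsv")
    if (!is.null(anova_indel)) w(anova_indel, "anova_lof_indel.tsv")
    if (!is.null(anova_snv)) w(anova_snv, "anova_lof_snv.tsv")
    for (nm in names(assoc_by_tier))
      w(assoc_by_tier[[nm]], paste0("association_", nm, ".tsv"))
    w(inflation$qq, "qq.tsv")
    if (write_vcf_file)
      write_vcf(alleles, geno, file.path(out_dir, "cohort.vcf"),
                contig_lengths = stats::setNames(ref_length(cohort$ref),
                                                 cohort$ref$name))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}
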