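#' Per-sample loss-of-function burden
#'
#' Counts alternate-allele dosage at LOF sites with cohort allele
#' frequency strictly below `af_max`, per sample: total, split by
#' SNV/indel, by indel context category, and (optionally) per gene.
#' Missing genotypes contribute zero.
#'
#' @param alleles allele table.
#' @param geno dosage matrix (alleles x samples).
#' @param consequence labels from [classify_consequence()], one per
#'   allele.
#' @param contexts [classify_indels()] output for the indel subset
#'   (matched by key); may be `NULL` if category splits are not needed.
#' @param genes gene model (needed for `per_gene = TRUE`).
#' @param af_max cohort AF cutoff, strict `<` (default 0.05).
#' @param retained_keys optional filter restriction.
#' @param per_gene also return a samples x genes LOF count matrix.
#' @return list with `samples` (data.frame of per-sample counts) and,
#'   if requested, `gene_matrix`.
#' @export
build_burden <- function(alleles, geno, consequence, contexts = NULL,
                         genes = NULL, af_max = 0.05,
                         retained_keys = NULL, per_gene = FALSE) {
  keys <- allele_key(alleles)
  af <- allele_frequency(geno)
  use <- is_lof(consequence) & !is.na(af) & af < af_max
  if (!is.null(retained_keys)) use <- use & keys %in% retained_keys

  count_rows <- function(rows) {
    if (!any(rows)) return(numeric(ncol(geno)))
    colSums(geno[rows, , drop = FALSE], na.rm = TRUE)
  }
  is_indel <- alleles$type != "SNV"
  samples <- data.frame(
    sample_id = colnames(geno),
    lof_total = count_rows(use),
    lof_snv = count_rows(use & !is_indel),
    lof_indel = count_rows(use & is_indel),
    stringsAsFactors = FALSE)
  if (!is.null(contexts)) {
    cat_of <- contexts$category[match(keys, contexts$key)]
    for (cat in c("HOMOPOLYMER_PLUS", "LARGE", "OTHER"))
      samples[[paste0("lof_indel_", tolower(cat))]] <-
        count_rows(use & is_indel & !is.na(cat_of) & cat_of == cat)
  }
  out <- list(samples = samples)
  if (per_gene) {
    stopifnot(!is.null(genes))
    gidx <- gene_index(alleles, genes)
    gm <- sapply(unique(genes$gene_id), function(g)
      count_rows(use & !is.na(gidx) & gidx == g))
    rownames(gm) <- colnames(geno)
    out$gene_matrix <- gm
  }
  out
}

# gene id containing each allele's first affected base (NA if intergenic)
gene_index <- function(alleles, genes) {
  ex <- genes[order(genes$start), ]
  x <- ifelse(alleles$type == "SNV", alleles$pos - 1L, alleles$pos)
  i <- findInterval(x, ex$start)
  ok <- i >= 1L & x < ex$end[pmax(i, 1L)]
  ifelse(ok, ex$gene_id[pmax(i, 1L)], NA_character_)
}

#' Type II ANOVA variance decomposition of burden
#'
#' Linear model of a per-sample burden on technical covariates, with
#' each factor's sum of squares computed after all other factors
#' (Type II, no interactions), via `car::Anova`. Percent variance
#' explained is the factor sum of squares divided by the total of the
#' table's sums of squares (factors + residual). Collinear (aliased)
#' factors raise an error naming the offending terms rather than being
#' silently dropped.
#'
#' @param response numeric burden vector, one per sample.
#' @param meta sample metadata data.frame.
#' @param factors column names of `meta` to decompose over (default the
#'   technical covariates `c20x`, `wga`, `center`, `bwa_version`,
#'   `race`).
#' @return data.frame with one row per factor plus a residual row:
#'   `sum_sq`, `df`, `F`, `p`, `pct_var_explained`.
#' @export
anova_decomposition <- function(response, meta,
                                factors = c("c20x", "wga", "center",
                                            "bwa_version", "race")) {
  stopifnot(all(factors %in% names(meta)),
            length(response) == nrow(meta))
  df <- data.frame(.y = response, meta[factors], stringsAsFactors = FALSE)
  for (f in factors) if (!is.numeric(df[[f]])) df[[f]] <- factor(df[[f]])
  fml <- stats::reformulate(factors, response = ".y")
  if (length(response) <= sum(vapply(df[factors], function(x)
    if (is.factor(x)) nlevels(x) - 1L else 1L, integer(1))) + 1L)
    stop("fewer samples than model degrees of freedom")
  fit <- stats::lm(fml, data = df)
  al <- stats::alias(fit)$Complete
  if (!is.null(al))
    stop("collinear (aliased) factors: ",
         paste(rownames(al), collapse = ", "),
         " aliased with ", paste(colnames(al)[colSums(al != 0) > 0],
                                 collapse = ", "))
  tab <- car::Anova(fit, type = 2)
  total_ss <- sum(tab$`Sum Sq`)
  data.frame(term = rownames(tab),
             sum_sq = tab$`Sum Sq`,
             df = tab$Df,
             F = tab$`F value`,
             p = tab$`Pr(>F)`,
             pct_var_explained = tab$`Sum Sq` / total_ss,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Basic bootstrap confidence interval for a mean
#'
#' The basic (reflected percentile) interval: with observed mean m and
#' bootstrap-mean quantiles q, the interval is
#' (2m - q_hi, 2m - q_lo), from `reps` resamples. Deterministic given
#' `seed`. A constant vector yields a zero-width interval at the
#' constant.
#'
#' @param values numeric vector, length >= 2.
#' @param reps bootstrap replicates (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return numeric length-2 vector (lower, upper).
#' @export
bootstrap_ci <- function(values, reps = 1000L, level = 0.95, seed = 1L) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (stats::var(values) == 0)
    return(c(values[1], values[1]))
  set.seed(seed)
  b <- boot::boot(values, function(d, i) mean(d[i]), R = reps)
  ci <- boot::boot.ci(b, conf = level, type = "basic")
  ci$basic[1, 4:5]
}
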