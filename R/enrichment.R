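#' One-sided Fisher exact test for WGA excess
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' alternate allele count in the WGA column of the 2x2 table
#' (alt/ref x WGA/DNA) with margins fixed. Vectorized over tables. An
#' all-zero table yields p = 1 by convention.
#'
#' @param alt_wga,ref_wga,alt_dna,ref_dna non-negative integer allele
#'   counts (vectors recycle).
#' @return numeric vector of one-sided p-values in (0, 1\].
#' @examples
#' fisher_one_sided(1, 2 * 614 - 1, 0, 2 * 9004)  # 1228/19236
#' @export
fisher_one_sided <- function(alt_wga, ref_wga, alt_dna, ref_dna) {
  if (any(c(alt_wga, ref_wga, alt_dna, ref_dna) < 0))
    stop("counts must be non-negative")
  K <- alt_wga + alt_dna            # alt-allele margin
  n <- alt_wga + ref_wga            # WGA column total
  N <- K + ref_wga + ref_dna
  p <- stats::phyper(alt_wga - 1, K, N - K, n, lower.tail = FALSE)
  p[N == 0] <- 1
  p
}

#' Singleton enrichment threshold
#'
#' The one-sided Fisher p-value of a single alternate allele observed
#' only in the WGA group, given diploid allele totals `2 * n_wga` and
#' `2 * n_dna`; in closed form `(2 n_wga) / (2 n_wga + 2 n_dna)`. This
#' is the screening threshold for calling an indel WGA-enriched.
#'
#' @param n_wga,n_dna sample counts (at least 1 each).
#' @return numeric threshold.
#' @examples
#' singleton_threshold(614, 9004)  # ~0.0638, printed as 0.063
#' @export
singleton_threshold <- function(n_wga, n_dna) {
  stopifnot(n_wga >= 1, n_dna >= 1)
  fisher_one_sided(1, 2 * n_wga - 1, 0, 2 * n_dna)
}

#' Call WGA-enriched indel alleles
#'
#' For every indel allele, computes group allele counts on the WGA/DNA
#' sample partition (missing genotypes reduce the group's diploid
#' total), the one-sided Fisher p for WGA excess, and an enrichment
#' flag. The default flag mode `"lte"` calls `p <= threshold` enriched,
#' so that a WGA-only singleton with no missing genotypes (which sits
#' exactly at the threshold) is enriched; `mode = "strict"` uses
#' `p < threshold`.
#'
#' @param alleles allele table.
#' @param geno dosage matrix (alleles x samples).
#' @param meta sample metadata with logical column `wga`; rows align
#'   with `geno` columns.
#' @param mode `"lte"` or `"strict"`.
#' @return data.frame: key, type, alt/ref counts per group, `p`,
#'   `enriched`, plus the `threshold` as an attribute.
#' @export
call_enriched <- function(alleles, geno, meta, mode = c("lte", "strict")) {
  mode <- match.arg(mode)
  stopifnot(nrow(meta) == ncol(geno))
  is_indel <- alleles$type != "SNV"
  if (!any(meta$wga)) stop("no WGA samples in cohort")
  alleles <- alleles[is_indel, , drop = FALSE]
  geno <- geno[is_indel, , drop = FALSE]
  cnt <- allele_counts(geno, ifelse(meta$wga, "WGA", "DNA"))
  p <- fisher_one_sided(cnt$alt[, "WGA"], cnt$ref[, "WGA"],
                        cnt$alt[, "DNA"], cnt$ref[, "DNA"])
  thr <- singleton_threshold(sum(meta$wga), sum(!meta$wga))
  res <- data.frame(key = allele_key(alleles),
                    type = alleles$type,
                    alt_wga = cnt$alt[, "WGA"], ref_wga = cnt$ref[, "WGA"],
                    alt_dna = cnt$alt[, "DNA"], ref_dna = cnt$ref[, "DNA"],
                    p = p,
                    enriched = if (mode == "lte") p <= thr else p < thr,
                    stringsAsFactors = FALSE)
  attr(res, "threshold") <- thr
  res
}

#' WGA allele-frequency contrast: homopolymer+ vs other indels
#'
#' Mean WGA-sample allele frequency of homopolymer+ indels versus all
#' other indels, with basic bootstrap confidence intervals for each
#' group mean. Intended to be applied to the WGA-enriched indel set
#' (pass the enriched subset of `alleles`/`geno`); recurrent slippage
#' at homopolymer tracts then shows as an elevated mean frequency
#' relative to the mostly private chimeric insertions. Degenerate groups (fewer than 2 indels) are flagged and
#' get an `NA` interval.
#'
#' @param alleles,geno,meta as in [call_enriched()].
#' @param contexts output of [classify_indels()] for the same indels
#'   (matched by key).
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with one row per group (`homopolymer_plus`,
#'   `other`) and the mean AF difference as attribute `contrast`.
#' @export
enrichment_af_contrast <- function(alleles, geno, meta, contexts,
                                   reps = 1000L, seed = 1L) {
  is_indel <- alleles$type != "SNV"
  alleles <- alleles[is_indel, , drop = FALSE]
  geno <- geno[is_indel, meta$wga, drop = FALSE]
  keys <- allele_key(alleles)
  ctx <- contexts[match(keys, contexts$key), ]
  af <- allele_frequency(geno)
  grp <- ifelse(ctx$category == "HOMOPOLYMER_PLUS", "homopolymer_plus",
                "other")
  rows <- lapply(c("homopolymer_plus", "other"), function(g) {
    x <- af[grp == g & !is.na(af)]
    degenerate <- length(x) < 2L
    ci <- if (degenerate) c(NA_real_, NA_real_)
          else bootstrap_ci(x, reps = reps, seed = seed)
    data.frame(group = g, n = length(x),
               mean_wga_af = if (length(x)) mean(x) else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2], degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "contrast") <- out$mean_wga_af[1] - out$mean_wga_af[2]
  out
}
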