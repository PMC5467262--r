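#' Per-sample variant call set
#'
#' Keys of alleles called non-reference in a sample (dosage >= 1).
#' Missing genotypes count as absent: coverage dropout therefore drives
#' discordance between replicates, the mechanism by which variable WGA
#' depth degrades reproducibility.
#'
#' @param geno dosage matrix with allele keys as rownames.
#' @param sample column name.
#' @param keys optional restriction to a key subset (e.g. a filter's
#'   retained alleles or one indel category).
#' @return character vector of keys.
#' @export
call_set <- function(geno, sample, keys = NULL) {
  d <- geno[, sample]
  k <- rownames(geno)[!is.na(d) & d >= 1L]
  if (!is.null(keys)) k <- intersect(k, keys)
  k
}

#' Genotype discordance between two call sets
#'
#' `1 - |A intersect B| / |A union B|`, calls matched by position and
#' alternate allele, zygosity disregarded. Undefined (NA) when both
#' sets are empty.
#'
#' @param calls_a,calls_b character vectors of allele keys.
#' @return numeric in \[0, 1\], or `NA` if undefined.
#' @examples
#' discordance(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
#' @export
discordance <- function(calls_a, calls_b) {
  u <- length(union(calls_a, calls_b))
  if (u == 0L) return(NA_real_)
  1 - length(intersect(calls_a, calls_b)) / u
}

#' Discordance for all replicate pairs
#'
#' Computes per-pair discordance overall, for SNVs, for indels, and for
#' each indel context category, under an optional allele filter.
#'
#' @param geno dosage matrix (keys x samples).
#' @param pairs data.frame with `individual_id`, `sample_a`, `sample_b`,
#'   `pair_type`.
#' @param alleles allele table aligned with `geno` rows.
#' @param contexts optional [classify_indels()] output for category
#'   splits.
#' @param retained_keys optional filter: only these keys are considered.
#' @return data.frame, one row per pair with columns `overall`, `snv`,
#'   `indel` and one per category.
#' @export
pairwise_discordance <- function(geno, pairs, alleles, contexts = NULL,
                                 retained_keys = NULL) {
  keys <- allele_key(alleles)
  class_keys <- list(overall = keys,
                     snv = keys[alleles$type == "SNV"],
                     indel = keys[alleles$type != "SNV"])
  if (!is.null(contexts))
    for (cat in c("HOMOPOLYMER_PLUS", "LARGE", "OTHER"))
      class_keys[[tolower(cat)]] <- contexts$key[contexts$category == cat]
  if (!is.null(retained_keys))
    class_keys <- lapply(class_keys, intersect, retained_keys)

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- call_set(geno, pairs$sample_a[i], retained_keys)
    b <- call_set(geno, pairs$sample_b[i], retained_keys)
    vals <- vapply(class_keys, function(k)
      discordance(intersect(a, k), intersect(b, k)), numeric(1))
    cbind(pairs[i, c("individual_id", "pair_type"), drop = FALSE],
          as.data.frame(as.list(vals)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median discordance by pair type
#'
#' @param pd output of [pairwise_discordance()].
#' @param column which discordance column to summarize (default
#'   `"indel"`).
#' @return named numeric vector of medians by pair type.
#' @export
discordance_by_pair_type <- function(pd, column = "indel") {
  tapply(pd[[column]], pd$pair_type, stats::median, na.rm = TRUE)
}

#' Flag replicate pairs exceeding a discordance ceiling
#'
#' Outlier pairs (e.g. suspected sample label mismatches) can be
#' excluded from downstream summaries by flagging pairs whose overall
#' discordance exceeds a ceiling.
#'
#' @param pd output of [pairwise_discordance()].
#' @param ceiling maximum tolerated overall discordance (default 0.9).
#' @return logical vector: pair flagged for exclusion.
#' @export
flag_outlier_pairs <- function(pd, ceiling = 0.9) {
  !is.na(pd$overall) & pd$overall > ceiling
}

#' Evaluate an indel filter against replicate pairs and a truth panel
#'
#' Partitions each pair's indel calls into concordant (present in both
#' members) and discordant (present in exactly one) instances, then
#' measures the fraction of each removed by the filter, and the overlap
#' of retained indel alleles with a truth panel (the stand-in for an
#' external database of validated variants).
#'
#' @param geno dosage matrix (keys x samples).
#' @param pairs replicate pair table.
#' @param alleles allele table.
#' @param retained_keys keys retained by the filter.
#' @param truth_panel character vector of truth-panel allele keys.
#' @return one-row data.frame: `frac_discordant_removed`,
#'   `frac_concordant_removed`, `truth_panel_overlap`,
#'   `n_retained_indels`. Overlap is `NA` (flagged) when the filter
#'   retains nothing.
#' @export
evaluate_filter <- function(geno, pairs, alleles, retained_keys,
                            truth_panel) {
  stopifnot(nrow(pairs) > 0L)
  indel_keys <- allele_key(alleles)[alleles$type != "SNV"]
  disc <- character(0); conc <- character(0)
  for (i in seq_len(nrow(pairs))) {
    a <- intersect(call_set(geno, pairs$sample_a[i]), indel_keys)
    b <- intersect(call_set(geno, pairs$sample_b[i]), indel_keys)
    conc <- c(conc, intersect(a, b))
    disc <- c(disc, setdiff(union(a, b), intersect(a, b)))
  }
  retained_indels <- intersect(retained_keys, indel_keys)
  frac_removed <- function(x) {
    if (!length(x)) return(NA_real_)
    mean(!(x %in% retained_keys))
  }
  data.frame(
    frac_discordant_removed = frac_removed(disc),
    frac_concordant_removed = frac_removed(conc),
    truth_panel_overlap = if (length(retained_indels))
      mean(retained_indels %in% truth_panel) else NA_real_,
    n_retained_indels = length(retained_indels))
}
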