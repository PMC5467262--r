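#' Normalize one allele (left-align + parsimony)
#'
#' Reduces a (pos, ref, alt) pair to its canonical representation:
#' shared trailing bases are trimmed (extending to the left from the
#' reference when a side would become empty, which left-aligns indels),
#' then shared leading bases beyond the single anchor base are trimmed.
#'
#' @param pos 1-based VCF position.
#' @param ref,alt reference and alternate allele strings.
#' @param refseq a [ref_seq()] providing upstream bases for left
#'   alignment.
#' @return list with normalized `pos`, `ref`, `alt`.
#' @export
normalize_allele <- function(pos, ref, alt, refseq) {
  if (ref == alt) stop("ref and alt identical")
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (substr(ref, nr, nr) == substr(alt, na, na)) {
      if (nr > 1L && na > 1L) {
        ref <- substr(ref, 1L, nr - 1L); alt <- substr(alt, 1L, na - 1L)
      } else if (pos > 1L) {
        prev <- ref_subseq(refseq, pos - 2L, pos - 1L)
        ref <- paste0(prev, substr(ref, 1L, nr - 1L))
        alt <- paste0(prev, substr(alt, 1L, na - 1L))
        pos <- pos - 1L
      } else break
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

allele_type <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "SNV",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' Allele keys
#'
#' Variant calls are matched by contig, position and alternate allele
#' (disregarding zygosity), so the key is `contig:pos:ref>alt`.
#'
#' @param alleles allele table.
#' @return character vector of keys.
#' @export
allele_key <- function(alleles) {
  paste0(alleles$contig, ":", alleles$pos, ":", alleles$ref, ">",
         alleles$alt)
}

#' Construct an allele table
#'
#' Builds the package's tabular allele representation from parallel
#' vectors; `type` and `indel_len` are derived. Alleles are assumed to
#' be normalized (see [normalize_allele()]).
#'
#' @param contig,pos,ref,alt,qs parallel vectors (`pos` is the 1-based
#'   VCF position, `qs` the site quality score).
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `type`, `indel_len`, `qs`.
#' @export
new_allele_table <- function(contig, pos, ref, alt, qs) {
  data.frame(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
             type = allele_type(ref, alt),
             indel_len = abs(nchar(alt) - nchar(ref)),
             qs = qs, stringsAsFactors = FALSE)
}

#' Read a multi-sample VCF into normalized per-ALT alleles
#'
#' Multi-allelic records are split into one allele per ALT; each split
#' allele is normalized against the reference, and genotype dosage
#' (0/1/2, `NA` for missing) is computed per allele: only copies of that
#' ALT count, so at a `1/2` site each of the two alleles receives
#' dosage 1. Genotypes must be diploid.
#'
#' @param path VCF file (VCFv4.2, GT format field; site INFO key `QS`
#'   carries a per-ALT quality score when present).
#' @param refseq a [ref_seq()] for normalization.
#' @return list with `alleles` (data.frame: contig, pos, ref, alt, type,
#'   indel_len, qs), `geno` (integer matrix alleles x samples) and
#'   `samples` (column order).
#' @export
read_vcf <- function(path, refseq) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt[, -1, drop = FALSE]
  samples <- colnames(gt)
  n_rec <- nrow(fix)

  out_alleles <- vector("list", n_rec)
  out_geno <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    qs <- rep(NA_real_, length(alts))
    info <- fix[r, "INFO"]
    if (!is.na(info) && grepl("QS=", info, fixed = TRUE)) {
      qs_str <- sub(".*QS=([^;]*).*", "\\1", info)
      qs <- as.numeric(strsplit(qs_str, ",", fixed = TRUE)[[1]])
      if (length(qs) != length(alts))
        stop("malformed QS at record ", r)
    }
    g <- gt[r, ]
    g <- sub(":.*$", "", g)               # GT is the first field
    miss <- is.na(g) | g %in% c(".", "./.", ".|.")
    parts <- strsplit(ifelse(miss, "./.", g), "[/|]")
    if (any(lengths(parts) != 2L))
      stop("non-diploid genotype at record ", r)
    am <- matrix(unlist(parts), nrow = 2L)
    dose <- matrix(0L, nrow = length(alts), ncol = length(samples))
    miss <- miss | am[1, ] == "." | am[2, ] == "."
    for (j in seq_along(alts)) {
      dose[j, ] <- (am[1, ] == as.character(j)) + (am[2, ] == as.character(j))
      dose[j, miss] <- NA_integer_
    }
    pos <- as.integer(fix[r, "POS"])
    if (is.na(pos)) stop("malformed record ", r, ": bad POS")
    norm <- lapply(alts, function(a)
      normalize_allele(pos, fix[r, "REF"], a, refseq))
    out_alleles[[r]] <- new_allele_table(
      contig = rep(fix[r, "CHROM"], length(alts)),
      pos = vapply(norm, `[[`, integer(1), "pos"),
      ref = vapply(norm, `[[`, character(1), "ref"),
      alt = vapply(norm, `[[`, character(1), "alt"),
      qs = qs)
    out_geno[[r]] <- dose
  }
  alleles <- do.call(rbind, out_alleles)
  geno <- do.call(rbind, out_geno)
  colnames(geno) <- samples
  rownames(geno) <- allele_key(alleles)
  list(alleles = alleles, geno = geno, samples = samples)
}

#' Write alleles + genotype matrix as VCFv4.2
#'
#' Alleles sharing (contig, pos) are merged into one multi-allelic
#' record: REF is padded to the longest reference allele and each ALT is
#' padded with the corresponding reference suffix. Per-ALT quality
#' scores are written in INFO as `QS=`.
#'
#' @param alleles allele table.
#' @param geno integer dosage matrix (alleles x samples, `NA` missing).
#' @param path output path.
#' @param contig_lengths named integer vector for `##contig` headers.
#' @return the path, invisibly.
#' @export
write_vcf <- function(alleles, geno, path, contig_lengths = NULL) {
  samples <- colnames(geno)
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     contig_lengths),
           "##INFO=<ID=QS,Number=A,Type=Float,Description=\"Simulated site quality score\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))

  ord <- order(alleles$contig, alleles$pos, alleles$ref, alleles$alt)
  alleles <- alleles[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  site <- paste0(alleles$contig, ":", alleles$pos)
  lines <- vapply(split(seq_len(nrow(alleles)), factor(site, unique(site))),
                  function(idx) {
    a <- alleles[idx, , drop = FALSE]
    ext_ref <- a$ref[which.max(nchar(a$ref))]
    pad <- substring(ext_ref, nchar(a$ref) + 1L)
    alts <- paste0(a$alt, pad)
    d <- geno[idx, , drop = FALSE]
    gt <- apply(d, 2, function(col) {
      if (anyNA(col)) return("./.")
      idxs <- rep.int(seq_along(col), col)
      paste(sort(c(idxs, rep.int(0L, max(0L, 2L - length(idxs)))))[1:2],
            collapse = "/")
    })
    paste(c(a$contig[1], a$pos[1], ".", ext_ref, paste(alts, collapse = ","),
            ".", "PASS", paste0("QS=", paste(format(a$qs, trim = TRUE),
                                             collapse = ",")),
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Group allele counts
#'
#' Alternate allele count is the dosage sum over non-missing genotypes;
#' the reference count is twice the number of non-missing genotypes in
#' the group minus the alternate count (with no missing genotypes this
#' is the classical 2N minus alt count).
#'
#' @param geno dosage matrix (alleles x samples) or a single-allele
#'   dosage vector.
#' @param groups factor/character of group labels, one per sample.
#' @return list of matrices `alt` and `ref` (alleles x groups).
#' @export
allele_counts <- function(geno, groups) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(geno))
  alt <- sapply(levels(groups), function(g)
    rowSums(geno[, groups == g, drop = FALSE], na.rm = TRUE))
  nonmiss <- sapply(levels(groups), function(g)
    rowSums(!is.na(geno[, groups == g, drop = FALSE])))
  if (is.null(dim(alt))) { # single allele
    alt <- matrix(alt, nrow = 1, dimnames = list(NULL, levels(groups)))
    nonmiss <- matrix(nonmiss, nrow = 1,
                      dimnames = list(NULL, levels(groups)))
  }
  list(alt = alt, ref = 2L * nonmiss - alt)
}

#' Cohort alternate-allele frequency
#'
#' `alt_count / (2 * non-missing sample count)` per allele. Missing
#' genotypes are excluded from numerator and denominator.
#'
#' @param geno dosage matrix or vector.
#' @return numeric vector of frequencies; `NA` (with a warning) where
#'   every genotype is missing.
#' @export
allele_frequency <- function(geno) {
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1)
  nonmiss <- rowSums(!is.na(geno))
  af <- rowSums(geno, na.rm = TRUE) / (2 * nonmiss)
  if (any(nonmiss == 0))
    warning("allele frequency undefined where all genotypes are missing")
  af
}

#' Tiered quality filtering by truth-calibrated quantiles
#'
#' Emulates truth-sensitivity tiers: an allele is retained when its
#' quality score `qs` reaches the `(1 - stringency)` quantile of the
#' scores of a truth-calibration allele set. `stringency = 1` retains
#' every allele scoring at least the calibration minimum; decreasing
#' stringency tightens the threshold, and tiers are nested. Filtering is
#' per allele, not per site.
#'
#' @param alleles allele table with a `qs` column.
#' @param stringency fraction in (0, 1\].
#' @param calibration_qs numeric vector of quality scores of the
#'   calibration (truth-panel) alleles.
#' @return logical vector: allele retained.
#' @export
apply_quality_filter <- function(alleles, stringency, calibration_qs) {
  stopifnot(stringency > 0, stringency <= 1)
  calibration_qs <- calibration_qs[!is.na(calibration_qs)]
  if (length(calibration_qs) == 0L) stop("empty calibration set")
  thr <- if (stringency == 1) -Inf
         else stats::quantile(calibration_qs, probs = 1 - stringency,
                              names = FALSE, type = 7)
  !is.na(alleles$qs) & alleles$qs >= thr
}
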