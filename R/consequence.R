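#' Minimal coding-consequence rule
#'
#' Classifies normalized alleles against a gene model into
#' `stop_gained`, `frameshift`, `inframe_indel`, `missense`, `silent`
#' or `noncoding`. This is a deliberately minimal stand-in for
#' transcript-aware effect predictors: a CDS indel whose length is not a
#' multiple of three is a frameshift, a CDS single-nucleotide variant
#' creating a stop codon is stop-gained, and loss-of-function (LOF) is
#' defined as stop-gained or frameshift. Variants overlapping an exon
#' boundary are classified `noncoding` rather than partially evaluated;
#' splice effects are out of scope.
#'
#' @param alleles allele table (see [read_vcf()]): columns `pos`
#'   (1-based), `ref`, `alt`, `type`, `indel_len`.
#' @param genes gene model exon table ([gene_model()]).
#' @param ref a [ref_seq()].
#' @return character vector of consequence labels, one per allele.
#' @export
classify_consequence <- function(alleles, genes, ref) {
  validate_gene_model(genes)
  ex <- genes[order(genes$start), , drop = FALSE]
  # cumulative CDS offset of each exon within its gene (genomic order)
  ex$cds_before <- stats::ave(ex$end - ex$start, ex$gene_id,
                              FUN = function(L) cumsum(c(0L, L[-length(L)])))
  gene_len <- tapply(ex$end - ex$start, ex$gene_id, sum)
  cds_cache <- new.env(parent = emptyenv())
  get_cds <- function(gid) {
    if (is.null(cds_cache[[gid]]))
      cds_cache[[gid]] <- gene_cds_seq(ex[ex$gene_id == gid, ], ref)
    cds_cache[[gid]]
  }

  exon_at <- function(x) {
    i <- findInterval(x, ex$start)
    if (i >= 1L && x < ex$end[i]) i else NA_integer_
  }

  n <- nrow(alleles)
  out <- character(n)
  for (k in seq_len(n)) {
    type <- alleles$type[k]
    a0 <- alleles$pos[k] - 1L   # 0-based anchor / SNV position
    if (type == "SNV") {
      i <- exon_at(a0)
      if (is.na(i)) { out[k] <- "noncoding"; next }
      gid <- ex$gene_id[i]
      off <- ex$cds_before[i] + (a0 - ex$start[i])
      alt_base <- alleles$alt[k]
      if (ex$strand[i] == "-") {
        off <- gene_len[[gid]] - 1L - off
        alt_base <- chartr("ACGT", "TGCA", alt_base)
      }
      cds <- get_cds(gid)
      c0 <- (off %/% 3L) * 3L
      codon <- substr(cds, c0 + 1L, c0 + 3L)
      if (nchar(codon) < 3L) { out[k] <- "silent"; next } # trailing partial codon
      new <- codon
      substr(new, off %% 3L + 1L, off %% 3L + 1L) <- alt_base
      out[k] <-
        if (new %in% c("TAA", "TAG", "TGA")) "stop_gained"
        else if (translate_codon(new) == translate_codon(codon)) "silent"
        else "missense"
    } else if (type == "insertion") {
      # inserted bases fall between a0 and a0+1; both must be in one exon
      i <- exon_at(a0)
      cds <- !is.na(i) && (a0 + 1L) < ex$end[i]
      out[k] <- indel_class(cds, alleles$indel_len[k])
    } else { # deletion of [a0+1, a0+1+L)
      L <- alleles$indel_len[k]
      i <- exon_at(a0 + 1L)
      inside <- !is.na(i) && (a0 + 1L + L) <= ex$end[i]
      # partial exon overlap (boundary-spanning) is excluded -> noncoding
      cds <- inside
      out[k] <- indel_class(cds, L)
    }
  }
  out
}

indel_class <- function(in_cds, len) {
  if (!in_cds) "noncoding"
  else if (len %% 3L != 0L) "frameshift"
  else "inframe_indel"
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Loss-of-function predicate
#'
#' @param consequence character vector of labels from
#'   [classify_consequence()].
#' @return logical vector; `TRUE` for `stop_gained` and `frameshift`.
#' @export
is_lof <- function(consequence) {
  consequence %in% c("stop_gained", "frameshift")
}
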