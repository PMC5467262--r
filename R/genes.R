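#' Gene models as exon interval tables
#'
#' A gene model is a data.frame of coding exons with columns `gene_id`,
#' `contig`, `start`, `end` (0-based half-open) and `strand` (`+`/`-`).
#' Exons of one gene must be non-overlapping and sorted; the total
#' coding length must be at least one codon.
#'
#' @param gene_id,contig,start,end,strand vectors of equal length (one
#'   row per exon).
#' @return validated exon data.frame.
#' @export
gene_model <- function(gene_id, contig, start, end, strand = "+") {
  g <- data.frame(gene_id = as.character(gene_id),
                  contig = as.character(contig),
                  start = as.integer(start), end = as.integer(end),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_gene_model(g)
  g
}

validate_gene_model <- function(genes) {
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in%
                  names(genes)))
  if (any(genes$end <= genes$start)) stop("empty exon interval")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  for (g in split(genes, genes$gene_id)) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
      stop("overlapping exons in gene ", g$gene_id[1])
    if (sum(g$end - g$start) < 3L)
      stop("coding length < 3 in gene ", g$gene_id[1])
  }
  invisible(genes)
}

#' Concatenated coding sequence of one gene
#'
#' Exonic sequence concatenated in genomic order; reverse-complemented
#' for minus-strand genes so the result reads 5' to 3' on the coding
#' strand.
#'
#' @param gene exon rows for a single gene (see [gene_model()]).
#' @param ref a [ref_seq()].
#' @return character scalar CDS.
#' @export
gene_cds_seq <- function(gene, ref) {
  stopifnot(length(unique(gene$gene_id)) == 1L)
  gene <- gene[order(gene$start), ]
  if (any(gene$start < 0L) || any(gene$end > ref_length(ref)))
    stop("gene exons outside reference bounds")
  s <- paste(mapply(function(a, b) ref_subseq(ref, a, b),
                    gene$start, gene$end), collapse = "")
  if (gene$strand[1] == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x)
           paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

#' Homopolymer content of a gene's coding sequence
#'
#' Counts maximal homopolymer tracts (length >= `min_run`) in the
#' concatenated exonic sequence and reports tract counts per exonic
#' base pair, with G and C tracts pooled and A and T tracts pooled.
#'
#' @param gene exon rows for a single gene.
#' @param ref a [ref_seq()].
#' @param min_run minimum tract length (default 4).
#' @return named numeric vector `c(gc = ..., at = ...)`, tracts per bp.
#' @examples
#' g <- gene_model("g1", "c", 0, 9)
#' gene_homopolymer_content(g, ref_seq("c", "AAAAGGGGC"))
#' @export
gene_homopolymer_content <- function(gene, ref, min_run = 4L) {
  cds <- gene_cds_seq(gene, ref)
  n <- nchar(cds)
  if (n == 0L) stop("zero-length coding region")
  tr <- scan_homopolymers(ref_seq("cds", cds), min_run = min_run)
  c(gc = sum(tr$base %in% c("G", "C")) / n,
    at = sum(tr$base %in% c("A", "T")) / n)
}

#' Read / write gene exons as BED
#'
#' BED is 0-based half-open; column 4 is the gene id and column 6 the
#' strand, matching the internal convention of [gene_model()].
#'
#' @param path file path.
#' @return `read_genes_bed()` returns a gene model data.frame.
#' @export
read_genes_bed <- function(path) {
  b <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE)
  if (ncol(b) < 6L) stop("BED must have 6 columns (name in 4, strand in 6)")
  gene_model(b[[4]], b[[1]], b[[2]], b[[3]], b[[6]])
}

#' @param genes gene model data.frame to write.
#' @rdname read_genes_bed
#' @export
write_genes_bed <- function(genes, path) {
  validate_gene_model(genes)
  out <- data.frame(genes$contig, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
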