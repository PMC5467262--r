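#' Reference sequence container
#'
#' A minimal single-contig reference: a contig name plus an uppercase
#' DNA string over the alphabet A, C, G, T. All package-internal
#' coordinates on a `ref_seq` are 0-based half-open; 1-based coordinates
#' appear only at the VCF boundary.
#'
#' @param name contig identifier.
#' @param seq character scalar, DNA sequence (coerced to upper case).
#' @return An object of class `ref_seq`: a list with elements `name` and
#'   `seq`.
#' @examples
#' ref_seq("chrSim", "ACGTACGT")
#' @export
ref_seq <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("reference sequence must be non-empty")
  if (grepl("[^ACGT]", seq))
    stop("reference alphabet is restricted to A, C, G, T")
  structure(list(name = name, seq = seq), class = "ref_seq")
}

#' @export
print.ref_seq <- function(x, ...) {
  cat(sprintf("<ref_seq> %s: %d bp\n", x$name, nchar(x$seq)))
  invisible(x)
}

#' Reference length in bases
#' @param ref a [ref_seq()].
#' @return integer length.
#' @export
ref_length <- function(ref) nchar(ref$seq)

#' Extract a 0-based half-open subsequence
#' @param ref a [ref_seq()].
#' @param start,end 0-based half-open interval, clipped to the contig.
#' @return character scalar.
#' @export
ref_subseq <- function(ref, start, end) {
  n <- ref_length(ref)
  start <- max(0L, as.integer(start))
  end <- min(n, as.integer(end))
  if (end <= start) return("")
  substr(ref$seq, start + 1L, end)
}

#' Read / write a single-contig FASTA
#'
#' Thin wrappers over Biostrings for the reference format.
#'
#' @param path file path.
#' @return `read_reference_fasta()` returns a [ref_seq()] (first record).
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequences in FASTA: ", path)
  ref_seq(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]))
}

#' @param ref a [ref_seq()] to write.
#' @rdname read_reference_fasta
#' @export
write_reference_fasta <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seq)
  names(ss) <- ref$name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Scan a reference for maximal homopolymer tracts
#'
#' Finds all maximal runs of a single base of length at least `min_run`.
#' Runs are maximal: the flanking bases (where they exist) differ from
#' the run base.
#'
#' @param ref a [ref_seq()].
#' @param min_run minimum run length (default 4, the conventional
#'   threshold for exonic homopolymer content).
#' @return data.frame with columns `contig`, `start` (0-based), `length`,
#'   `base`, sorted by `start`.
#' @examples
#' scan_homopolymers(ref_seq("c", "AAAAGGGGC"))
#' @export
scan_homopolymers <- function(ref, min_run = 4L) {
  stopifnot(inherits(ref, "ref_seq"), min_run >= 2L)
  r <- rle(strsplit(ref$seq, "", fixed = TRUE)[[1]])
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= min_run
  data.frame(contig = rep(ref$name, sum(keep)),
             start = as.integer(starts[keep]),
             length = as.integer(r$lengths[keep]),
             base = r$values[keep],
             stringsAsFactors = FALSE)
}

#' GC fraction of a window around a position
#'
#' Computes (G+C)/(window length) over `pos` plus/minus `flank` bases,
#' clipping the window at the contig ends.
#'
#' @param ref a [ref_seq()].
#' @param pos 0-based position; must lie on the contig.
#' @param flank half-window in bases (default 10).
#' @return numeric fraction in \[0, 1\].
#' @export
window_gc <- function(ref, pos, flank = 10L) {
  n <- ref_length(ref)
  if (any(pos < 0L | pos >= n)) stop("pos outside contig")
  vapply(pos, function(p) {
    s <- ref_subseq(ref, p - flank, p + flank + 1L)
    (nchar(s) - nchar(gsub("[GC]", "", s))) / nchar(s)
  }, numeric(1))
}
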