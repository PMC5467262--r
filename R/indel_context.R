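#' Indel context taxonomy
#'
#' Assigns each indel allele to exactly one of three categories:
#' \describe{
#'   \item{LARGE}{15 or more inserted or deleted bases (length takes
#'     precedence over homopolymer context).}
#'   \item{HOMOPOLYMER_PLUS}{indel shorter than 15 bp whose
#'     inserted/deleted bases are all one base type, with a run of at
#'     least 4 consecutive copies of that base in the reference starting
#'     within one base of the indel start position.}
#'   \item{OTHER}{everything else.}
#' }
#' Also records the GC fraction of the 10 bp flanking window and whether
#' the indel length is a multiple of three.
#'
#' @param alleles allele table restricted to indels (normalized).
#' @param ref a [ref_seq()].
#' @param min_run homopolymer run length (default 4).
#' @param flank GC window half-width (default 10).
#' @return data.frame with columns `key`, `category`,
#'   `homopolymer_eligible`, `gc10`, `mod3`, `is_insertion`, `length`.
#' @export
classify_indels <- function(alleles, ref, min_run = 4L, flank = 10L) {
  if (any(alleles$type == "SNV")) stop("classify_indels expects indels only")
  n <- nrow(alleles)
  seqs <- ifelse(alleles$type == "insertion",
                 substring(alleles$alt, 2L), substring(alleles$ref, 2L))
  first <- substr(seqs, 1L, 1L)
  # eligible: all inserted/deleted bases are one base type
  eligible <- vapply(seq_len(n), function(i)
    seqs[i] == strrep(first[i], nchar(seqs[i])), logical(1))
  start0 <- alleles$pos            # 0-based first inserted/deleted base
  is_hp <- logical(n)
  for (i in seq_len(n)) {
    if (!eligible[i]) next
    b <- first[i]
    for (s in (start0[i] - 1L):(start0[i] + 1L)) {
      if (s >= 0L && ref_subseq(ref, s, s + min_run) ==
            strrep(b, min_run)) { is_hp[i] <- TRUE; break }
    }
  }
  large <- alleles$indel_len >= 15L
  category <- ifelse(large, "LARGE",
                     ifelse(eligible & is_hp, "HOMOPOLYMER_PLUS", "OTHER"))
  data.frame(key = allele_key(alleles),
             category = category,
             homopolymer_eligible = eligible,
             gc10 = window_gc(ref, pmin(start0, ref_length(ref) - 1L),
                              flank = flank),
             mod3 = alleles$indel_len %% 3L == 0L,
             is_insertion = alleles$type == "insertion",
             length = alleles$indel_len,
             stringsAsFactors = FALSE)
}

#' Taxonomy summary by label group
#'
#' Per label group (e.g. WGA-enriched vs non-enriched), the fraction of
#' indels in each category, the insertion fraction, the mod-3 fraction,
#' and a size histogram.
#'
#' @param contexts output of [classify_indels()].
#' @param labels character/factor vector, one label per context row.
#' @return list with `fractions` (data.frame) and `size_hist` (table of
#'   length x label counts).
#' @export
taxonomy_summary <- function(contexts, labels) {
  stopifnot(nrow(contexts) > 0L, length(labels) == nrow(contexts))
  labels <- as.factor(labels)
  fr <- do.call(rbind, lapply(levels(labels), function(l) {
    x <- contexts[labels == l, , drop = FALSE]
    data.frame(label = l,
               n = nrow(x),
               frac_other = mean(x$category == "OTHER"),
               frac_homopolymer = mean(x$category == "HOMOPOLYMER_PLUS"),
               frac_large = mean(x$category == "LARGE"),
               frac_insertion = mean(x$is_insertion),
               frac_mod3 = mean(x$mod3),
               stringsAsFactors = FALSE)
  }))
  list(fractions = fr,
       size_hist = table(length = contexts$length, label = labels))
}
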