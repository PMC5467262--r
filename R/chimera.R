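#' Locate the copy-origin of a large indel's sequence
#'
#' Searches the reference within `window` bases of the indel start for
#' the best ungapped match to the inserted (insertions) or deleted
#' (deletions) sequence. Chimeric insertions produced by multiple
#' displacement amplification are verbatim copies of proximal reference
#' sequence, so an ungapped identity scan is sufficient; `min_identity`
#' allows mismatch tolerance. For deletions, candidate matches
#' overlapping the deleted span itself are excluded (the deleted bases
#' trivially match their own reference). Best match = highest identity,
#' ties broken by smallest distance to the indel start.
#'
#' @param allele one-row allele table (large indel, `indel_len >= 15`).
#' @param ref a [ref_seq()].
#' @param window search half-width in bp (default 10000, the proximal
#'   region within which MDA chimeras act); clipped at contig ends.
#' @param min_identity minimum identity to call a match (default 0.9).
#' @param revcomp also search the reverse complement (default FALSE).
#' @return one-row data.frame: `key`, `matched`, `match_pos` (0-based),
#'   `distance`, `identity`.
#' @export
find_origin <- function(allele, ref, window = 10000L, min_identity = 0.9,
                        revcomp = FALSE) {
  stopifnot(nrow(allele) == 1L, allele$type != "SNV",
            allele$indel_len >= 15L)
  s <- if (allele$type == "insertion") substring(allele$alt, 2L)
       else substring(allele$ref, 2L)
  L <- nchar(s)
  start0 <- allele$pos                   # 0-based first affected base
  lo <- max(0L, start0 - as.integer(window))
  hi <- min(ref_length(ref), start0 + as.integer(window) + L)
  region <- ref_subseq(ref, lo, hi)

  cand <- origin_candidates(s, region, min_identity)
  if (revcomp)
    cand <- rbind(cand, origin_candidates(revcomp_seq(s), region,
                                          min_identity))
  if (nrow(cand)) {
    cand$pos0 <- lo + cand$start - 1L    # global 0-based match start
    if (allele$type == "deletion") {
      del_lo <- start0; del_hi <- start0 + L
      cand <- cand[cand$pos0 + L <= del_lo | cand$pos0 >= del_hi, ,
                   drop = FALSE]
    }
  }
  if (!nrow(cand)) {
    return(data.frame(key = allele_key(allele), matched = FALSE,
                      match_pos = NA_integer_, distance = NA_integer_,
                      identity = NA_real_, stringsAsFactors = FALSE))
  }
  cand$distance <- abs(cand$pos0 - start0)
  best <- cand[order(-cand$identity, cand$distance), ][1, ]
  data.frame(key = allele_key(allele), matched = TRUE,
             match_pos = best$pos0, distance = best$distance,
             identity = best$identity, stringsAsFactors = FALSE)
}

# Ungapped candidate matches of `s` in `region` at identity >= min_identity,
# via Biostrings mismatch-tolerant exact matching.
origin_candidates <- function(s, region, min_identity) {
  L <- nchar(s)
  max_mm <- floor((1 - min_identity) * L)
  m <- Biostrings::matchPattern(s, Biostrings::DNAString(region),
                                max.mismatch = max_mm)
  st <- Biostrings::start(m)
  if (!length(st))
    return(data.frame(start = integer(0), identity = numeric(0)))
  mm <- Biostrings::neditStartingAt(Biostrings::DNAString(s),
                                    Biostrings::DNAString(region),
                                    starting.at = st, with.indels = FALSE)
  data.frame(start = st, identity = 1 - mm / L)
}

revcomp_seq <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Copy-origin search over a set of large indels
#'
#' @param alleles allele table (rows with `indel_len >= 15` are
#'   searched; others are skipped with `matched = NA`).
#' @inheritParams find_origin
#' @return data.frame of [find_origin()] rows.
#' @export
find_origins <- function(alleles, ref, window = 10000L,
                         min_identity = 0.9, revcomp = FALSE) {
  rows <- lapply(seq_len(nrow(alleles)), function(i)
    find_origin(alleles[i, , drop = FALSE], ref, window = window,
                min_identity = min_identity, revcomp = revcomp))
  do.call(rbind, rows)
}

#' Summary of copy-origin distances
#'
#' Match rate, distance quantiles, and the fraction of matches within
#' 2 kb of the indel start, optionally split by an enrichment flag and
#' by insertion/deletion.
#'
#' @param hits output of [find_origins()].
#' @param split optional data.frame with columns `enriched` and
#'   `is_insertion` aligned with `hits`.
#' @return data.frame of per-stratum summaries.
#' @export
origin_distance_summary <- function(hits, split = NULL) {
  strata <- if (is.null(split)) list(all = seq_len(nrow(hits)))
  else split(seq_len(nrow(hits)),
             paste0(ifelse(split$enriched, "enriched", "non_enriched"), ".",
                    ifelse(split$is_insertion, "insertion", "deletion")))
  do.call(rbind, lapply(names(strata), function(nm) {
    h <- hits[strata[[nm]], , drop = FALSE]
    d <- h$distance[h$matched %in% TRUE]
    data.frame(stratum = nm, n = nrow(h),
               match_rate = if (nrow(h)) mean(h$matched %in% TRUE) else 0,
               d25 = if (length(d)) unname(stats::quantile(d, .25)) else NA_real_,
               d50 = if (length(d)) unname(stats::quantile(d, .50)) else NA_real_,
               d75 = if (length(d)) unname(stats::quantile(d, .75)) else NA_real_,
               frac_within_2kb = if (length(d)) mean(d <= 2000) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
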