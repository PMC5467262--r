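# Independent brute-force oracles. These deliberately avoid the code
# paths of the implementations they check: character-by-character scans,
# explicit table enumeration, and exhaustive sliding windows.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# naive run-length scan: walk the string character by character
oracle_scan_runs <- function(seq, min_run) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- list()
  i <- 1L
  while (i <= length(ch)) {
    j <- i
    while (j < length(ch) && ch[j + 1L] == ch[i]) j <- j + 1L
    if (j - i + 1L >= min_run)
      out[[length(out) + 1L]] <- data.frame(start = i - 1L,
                                            length = j - i + 1L,
                                            base = ch[i])
    i <- j + 1L
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(start = integer(0), length = integer(0),
                  base = character(0))
}

oracle_window_gc <- function(seq, pos, flank) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  w <- ch[max(1, pos + 1 - flank):min(length(ch), pos + 1 + flank)]
  sum(w %in% c("G", "C")) / length(w)
}

# one-sided Fisher p by explicit enumeration of all tables with the
# observed margins, summing hypergeometric counting weights
oracle_fisher_enum <- function(a, b, c, d) {
  K <- a + c; n <- a + b; N <- a + b + c + d
  if (N == 0) return(1)
  x <- max(a, K + n - N):min(K, n)
  x <- x[x >= a]
  sum(choose(K, x) * choose(N - K, n - x)) / choose(N, n)
}

# independent indel-context classification: explicit character scan
oracle_classify_indel <- function(pos, ref_allele, alt, refstr,
                                  min_run = 4L) {
  L <- abs(nchar(alt) - nchar(ref_allele))
  if (L >= 15L) return("LARGE")
  s <- if (nchar(alt) > nchar(ref_allele)) substring(alt, 2L)
       else substring(ref_allele, 2L)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(unique(ch)) != 1L) return("OTHER")
  b <- ch[1]
  rch <- strsplit(refstr, "", fixed = TRUE)[[1]]
  start0 <- pos            # 0-based first affected base
  for (s0 in (start0 - 1L):(start0 + 1L)) {
    if (s0 < 0L || s0 + min_run > length(rch)) next
    if (all(rch[(s0 + 1L):(s0 + min_run)] == b)) return("HOMOPOLYMER_PLUS")
  }
  "OTHER"
}

# exhaustive sliding-window origin scan over the search region
oracle_find_origin <- function(allele, refstr, window = 10000L,
                               min_identity = 0.9) {
  s <- if (allele$type == "insertion") substring(allele$alt, 2L)
       else substring(allele$ref, 2L)
  L <- nchar(s)
  sraw <- charToRaw(s)
  rraw <- charToRaw(refstr)
  start0 <- allele$pos
  lo <- max(0L, start0 - window)
  hi <- min(length(rraw), start0 + window + L)
  cand <- lo:(hi - L)                       # 0-based candidate starts
  mism <- integer(length(cand))
  for (i in seq_len(L))
    mism <- mism + as.integer(rraw[cand + i] != sraw[i])
  identity <- 1 - mism / L
  if (allele$type == "deletion") {
    keep <- cand + L <= start0 | cand >= start0 + L
    cand <- cand[keep]; identity <- identity[keep]
  }
  ok <- identity >= min_identity
  if (!any(ok)) return(list(matched = FALSE, match_pos = NA, identity = NA))
  cand <- cand[ok]; identity <- identity[ok]
  dist <- abs(cand - start0)
  best <- order(-identity, dist)[1]
  list(matched = TRUE, match_pos = cand[best], identity = identity[best])
}
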